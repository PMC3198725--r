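test_that("config invariants are enforced", {
  expect_error(postprocess_config(core_threshold = 1.2), "0, 1")
  expect_error(postprocess_config(relax_threshold = 0.99,
                                  core_threshold = 0.5), "relax")
  expect_error(postprocess_config(min_size_vox = 0), ">= 1")
  expect_error(postprocess_config(max_size_vox = 500), "exceed")
  expect_error(postprocess_config(connectivity = 8), "connectivity")
})

test_that("probability smoothing preserves constants and supports sigma 0", {
  p <- prob_from_synapse(array(0.3, dim = c(12, 12, 12)))
  s <- smooth_probability(p, "synapse", 5)
  expect_equal(max(abs(s$data - 0.3)), 0, tolerance = 1e-12)
  expect_error(smooth_probability(p, "nope", 5), "unknown class")
  im <- array(0, dim = c(33, 33, 33)); im[17, 17, 17] <- 1
  sp <- smooth_probability(prob_from_synapse(im), "synapse", 5)
  expect_lt(max(sp$data), 1)
  expect_equal(sum(sp$data), 1, tolerance = 1e-3)
  s0 <- smooth_probability(prob_from_synapse(im), "synapse", 0)
  expect_identical(s0$data, im)
})

test_that("the 1000-voxel size filter is inclusive at the boundary", {
  a <- array(0, dim = c(24, 40, 24))
  a[8:17, 3:12, 8:17] <- 0.99            # 10x10x10 = 1000 voxels
  a[8:17, 25:34, 8:17] <- 0.99
  a[17, 34, 17] <- 0                     # second blob: 999 voxels
  cores <- extract_cores(em_volume(a), postprocess_config(core_threshold = 0.98,
                                                          min_size_vox = 1000))
  expect_length(cores, 1L)
  expect_equal(nrow(cores[[1]]), 1000L)
})

test_that("core threshold is strict and counts components by connectivity", {
  a <- array(0, dim = c(12, 12, 12))
  a[3:6, 3:6, 3:6] <- 0.98  # exactly at threshold: excluded (strict >)
  cfg <- postprocess_config(core_threshold = 0.98, min_size_vox = 1)
  expect_length(extract_cores(em_volume(a), cfg), 0L)
  a[3:6, 3:6, 3:6] <- 0.981
  expect_length(extract_cores(em_volume(a), cfg), 1L)
})

test_that("corner-touching blobs merge under 26- but not 6-connectivity", {
  a <- array(0, dim = c(26, 26, 26))
  a[2:11, 2:13, 2:11] <- 0.99    # 10*12*10 = 1200
  a[12:21, 14:25, 12:21] <- 0.99 # touches only diagonally at a corner
  for (conn in c(26L, 6L)) {
    cores <- extract_cores(em_volume(a),
                           postprocess_config(min_size_vox = 1000,
                                              connectivity = conn))
    expect_length(cores, if (conn == 26L) 1L else 2L)
    oracle <- flood_fill_oracle(a > 0.98, conn)
    expect_equal(max(oracle), if (conn == 26L) 1L else 2L)
  }
})

test_that("components match the flood-fill oracle on random small masks", {
  set.seed(20)
  for (i in 1:6) {
    conn <- sample(c(6L, 18L, 26L), 1)
    a <- array(runif(10^3) < 0.35, dim = c(10, 10, 10))
    ours <- array(emsynapse:::label_components_cpp(a, dim(a), conn), dim(a))
    oracle <- flood_fill_oracle(a, conn)
    expect_true(same_partition(ours, oracle))
  }
})

test_that("hysteresis growth includes 0.5 and excludes below", {
  a <- array(0, dim = c(16, 16, 16))
  a[7:10, 7:10, 7:10] <- 0.99
  core <- list(box_vox(6:9, 6:9, 6:9))
  # shell strictly below the relax threshold: segment == core
  a[6, 6:11, 6:11] <- 0.49
  segs <- grow_segments(core, em_volume(a), postprocess_config())
  expect_equal(nrow(segs[[1]]$segment_voxels), 64L)
  # a voxel at exactly 0.5 adjacent to the core is included
  a[5:6, 8, 8] <- c(0.49, 0.5)
  segs <- grow_segments(core, em_volume(a), postprocess_config())
  expect_equal(nrow(segs[[1]]$segment_voxels), 65L)
  expect_true(any(segs[[1]]$segment_voxels[, 1] == 5 &
                  segs[[1]]$segment_voxels[, 2] == 7 &
                  segs[[1]]$segment_voxels[, 3] == 7))
})

test_that("hysteresis growth is transitive along supra-threshold paths", {
  a <- array(0, dim = c(8, 8, 24))
  a[3:5, 3:5, 3:5] <- 0.99
  a[4, 4, 6:15] <- 0.6  # one-voxel tail, ten voxels long
  core <- extract_cores(em_volume(a), postprocess_config(min_size_vox = 1))
  segs <- grow_segments(core, em_volume(a), postprocess_config())
  seg <- segs[[1]]$segment_voxels
  expect_equal(nrow(seg), 27L + 10L)
  expect_true(all(5:14 %in% seg[seg[, 1] == 3 & seg[, 2] == 3, 3]))
  expect_true(nrow(segs[[1]]$core_voxels) <= nrow(seg))
})

test_that("colliding segments split by distance to the nearest core", {
  a <- array(0, dim = c(5, 5, 21))
  a[2:4, 2:4, 2:4] <- 0.99    # core 1 around x = 2..4
  a[2:4, 2:4, 17:19] <- 0.99  # core 2 around x = 17..19
  a[3, 3, 5:16] <- 0.6        # bridge of eligible voxels
  cfg <- postprocess_config(min_size_vox = 1)
  cores <- extract_cores(em_volume(a), cfg)
  segs <- grow_segments(cores, em_volume(a), cfg)
  expect_length(segs, 2L)
  s1 <- segs[[1]]$segment_voxels; s2 <- segs[[2]]$segment_voxels
  # bridge voxels nearer core 1 go to core 1, nearer core 2 to core 2;
  # the midpoint tie goes to the lower core id
  b1 <- s1[s1[, 1] == 2 & s1[, 2] == 2, 3]
  b2 <- s2[s2[, 1] == 2 & s2[, 2] == 2, 3]
  expect_setequal(sort(intersect(4:15, b1)), 4:9)
  expect_setequal(sort(intersect(4:15, b2)), 10:15)
  expect_error(grow_segments(list(cores[[1]], cores[[1]]), em_volume(a), cfg),
               "disjoint")
})

test_that("hysteresis segments nest as the relax threshold rises", {
  set.seed(21)
  base <- gaussian_smooth(array(runif(20^3), dim = c(20, 20, 20)), 2)
  base <- (base - min(base)) / diff(range(base))
  cfg1 <- postprocess_config(core_threshold = 0.9, min_size_vox = 1,
                             relax_threshold = 0.5)
  cores <- extract_cores(em_volume(base), cfg1)
  if (length(cores)) {
    seg_lo <- grow_segments(cores, em_volume(base), cfg1)
    cfg2 <- cfg1; cfg2$relax_threshold <- 0.7
    seg_hi <- grow_segments(cores, em_volume(base), cfg2)
    for (i in seq_along(seg_lo)) {
      lo <- apply(seg_lo[[i]]$segment_voxels, 1, paste, collapse = ",")
      hi <- apply(seg_hi[[i]]$segment_voxels, 1, paste, collapse = ",")
      expect_true(all(hi %in% lo))
    }
  }
})

test_that("detect composes the chain, sorts by size and is monotone", {
  a <- array(0, dim = c(32, 32, 32))
  expect_length(detect_synapses(prob_from_synapse(a),
                                postprocess_config(smoothing_sigma_vox = 0,
                                                   min_size_vox = 1)), 0L)
  a[2:6, 2:6, 2:6] <- 0.99       # 125 voxels
  a[12:19, 12:19, 12:19] <- 0.99 # 512 voxels
  a[24:30, 24:30, 2:8] <- 0.95   # below the 0.98 core threshold
  cfg <- postprocess_config(smoothing_sigma_vox = 0, min_size_vox = 50)
  cands <- detect_synapses(prob_from_synapse(a), cfg)
  expect_length(cands, 2L)
  expect_equal(vapply(cands, function(c) c$id, integer(1)), 1:2)
  expect_true(cands[[1]]$size_vox >= cands[[2]]$size_vox)
  for (c in cands) {
    core_keys <- apply(c$core_voxels, 1, paste, collapse = ",")
    seg_keys <- apply(c$segment_voxels, 1, paste, collapse = ",")
    expect_true(all(core_keys %in% seg_keys))
  }
  cfg_lo <- postprocess_config(smoothing_sigma_vox = 0, min_size_vox = 50,
                               core_threshold = 0.9)
  expect_gte(length(detect_synapses(prob_from_synapse(a), cfg_lo)),
             length(cands))
})

test_that("candidate exports are consistent", {
  a <- array(0, dim = c(16, 16, 16))
  a[3:8, 3:8, 3:8] <- 0.99
  cfg <- postprocess_config(smoothing_sigma_vox = 0, min_size_vox = 10)
  cands <- detect_synapses(prob_from_synapse(a), cfg)
  df <- as.data.frame(cands)
  expect_equal(nrow(df), 1L)
  expect_equal(df$size_vox, 216L)
  lv <- candidates_label_volume(cands, c(16, 16, 16))
  expect_equal(sum(lv$data == 1), 216L)
  back <- candidates_from_label_volume(lv)
  expect_equal(back[[1]]$size_vox, 216L)
  balls <- candidates_to_balls(cands)
  expect_equal(balls$radius_vox, (3 * 216 / (4 * pi))^(1 / 3), tolerance = 1e-10)
  csv <- file.path(tempdir(), "cands.csv")
  write_candidates_csv(cands, csv)
  expect_equal(read.csv(csv)$size_vox, 216L)
})

test_that("the suggested minimum size rescales with voxel volume", {
  expect_equal(suggest_min_size(c(9, 5, 5)), 1000L)
  expect_equal(suggest_min_size(c(9, 10, 10)), 250L)
})
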