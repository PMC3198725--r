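test_that("border exclusion removes balls touching the critical faces", {
  shape <- c(100, 100, 100)
  balls <- ball_annotations(
    z = c(10, 0, 50, 97, 50),
    y = c(3, 50, 50, 50, 50),
    x = c(50, 50, 50, 50, 2),
    radius_vox = c(4, 5, 5, 4, 3))
  kept <- exclude_border(balls, shape)
  # ball 1 reaches y = -1 (top border), ball 2 has its center in the
  # first slice, ball 4 reaches the last slice, ball 5 reaches x = -1
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$z, 50)
})

test_that("ball/candidate overlap uses inclusive Euclidean distance", {
  cand <- fake_candidate(1L, box_vox(10, 10, 10))
  expect_true(ball_overlaps_candidate(
    list(z = 10, y = 10, x = 10, radius_vox = 3), cand))
  expect_false(ball_overlaps_candidate(
    list(z = 10, y = 10, x = 14, radius_vox = 3), cand))
  # boundary: nearest voxel at distance exactly the radius counts
  expect_true(ball_overlaps_candidate(
    list(z = 10, y = 10, x = 13, radius_vox = 3), cand))
  expect_true(ball_overlaps_candidate(
    list(z = 13, y = 14, x = 10, radius_vox = 5), cand))  # 3-4-5 triangle
})

test_that("matching implements one-to-one removal semantics", {
  b <- ball_annotations(z = 10, y = 10, x = 10, radius_vox = 5)
  c1 <- fake_candidate(1L, box_vox(8:12, 8:12, 8:12))
  ev <- match_candidates(structure(list(c1), class = "synapse_candidates"), b)
  expect_equal(c(ev$tp, ev$fp, ev$fn), c(1L, 0L, 0L))
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)

  # two candidates overlapping the same single ball: one tp, one fp
  c2 <- fake_candidate(2L, box_vox(9:11, 9:11, 9:11))
  ev2 <- match_candidates(structure(list(c1, c2),
                                    class = "synapse_candidates"), b)
  expect_equal(c(ev2$tp, ev2$fp, ev2$fn), c(1L, 1L, 0L))
  # the larger candidate claims the ball
  expect_equal(ev2$matches$candidate_id, 1L)

  # no candidates: precision reported as 1 but flagged undefined
  ev3 <- match_candidates(structure(list(), class = "synapse_candidates"),
                          ball_annotations(z = c(1, 2, 3), y = rep(10, 3),
                                           x = rep(10, 3),
                                           radius_vox = rep(2, 3)))
  expect_equal(c(ev3$tp, ev3$fn), c(0L, 3L))
  expect_equal(ev3$recall, 0)
  expect_equal(ev3$precision, 1)
  expect_false(ev3$precision_defined)
})

test_that("matching totals are conserved", {
  set.seed(30)
  for (i in 1:20) {
    nc <- sample(0:4, 1); nb <- sample(0:4, 1)
    cands <- lapply(seq_len(nc), function(j) {
      ctr <- sample(5:25, 3, TRUE)
      fake_candidate(j, box_vox(ctr[1] + (-1:1), ctr[2] + (-1:1),
                                ctr[3] + (-1:1)))
    })
    cands <- structure(cands, class = "synapse_candidates")
    balls <- ball_annotations(z = sample(5:25, nb, TRUE),
                              y = sample(5:25, nb, TRUE),
                              x = sample(5:25, nb, TRUE),
                              radius_vox = runif(nb, 1, 8))
    ev <- match_candidates(cands, balls)
    expect_equal(ev$tp + ev$fn, nb)
    expect_equal(ev$tp + ev$fp, nc)
    expect_equal(ev$tp, nrow(ev$matches))
    expect_true(all(!duplicated(ev$matches$candidate_id)))
    expect_true(all(!duplicated(ev$matches$ball_index)))
    expect_true(ev$precision >= 0 && ev$precision <= 1)
    expect_true(is.na(ev$recall) || (ev$recall >= 0 && ev$recall <= 1))
  }
})

test_that("greedy matching agrees with the sequential-rule oracle", {
  set.seed(31)
  for (i in 1:150) {
    nc <- sample(1:4, 1); nb <- sample(1:4, 1)
    sizes <- sample(10:500, nc)
    cands <- lapply(seq_len(nc), function(j) {
      ctr <- sample(4:20, 3, TRUE)
      n <- sizes[j]
      vox <- cbind(ctr[1] + sample(-2:2, n, TRUE),
                   ctr[2] + sample(-2:2, n, TRUE),
                   ctr[3] + sample(-2:2, n, TRUE))
      fake_candidate(j, unique(vox))
    })
    sizes_actual <- vapply(cands, function(c) c$size_vox, numeric(1))
    cands <- structure(cands, class = "synapse_candidates")
    balls <- ball_annotations(z = sample(4:20, nb, TRUE),
                              y = sample(4:20, nb, TRUE),
                              x = sample(4:20, nb, TRUE),
                              radius_vox = runif(nb, 1, 6))
    overlap <- t(vapply(seq_len(nc), function(ci)
      vapply(seq_len(nb), function(bi)
        ball_overlaps_candidate(balls[bi, ], cands[[ci]]), logical(1)),
      logical(nb)))
    dim(overlap) <- c(nc, nb)
    centroids <- t(vapply(cands, function(c) c$centroid, numeric(3)))
    oracle <- sequential_match_oracle(sizes_actual, centroids, overlap, balls)
    ev <- match_candidates(cands, balls)
    expect_equal(ev$tp, oracle$tp)
    expect_equal(ev$fp, oracle$fp)
    expect_equal(ev$fn, oracle$fn)
  }
})

test_that("precision and recall follow the counting formulas exactly", {
  # constructed counts: 3 candidates, 2 of which hit 2 of 4 balls
  balls <- ball_annotations(z = c(10, 30, 50, 70), y = rep(10, 4),
                            x = rep(10, 4), radius_vox = rep(3, 4))
  cands <- structure(list(
    fake_candidate(1L, box_vox(9:11, 9:11, 9:11)),
    fake_candidate(2L, box_vox(29:31, 9:11, 9:11)),
    fake_candidate(3L, box_vox(90:92, 9:11, 9:11))),
    class = "synapse_candidates")
  ev <- match_candidates(cands, balls)
  expect_equal(ev$tp, 2L)
  expect_equal(ev$precision, 2 / 3)  # tp / total candidates
  expect_equal(ev$recall, 2 / 4)     # tp / gold synapses
})

test_that("near-miss pairs are flagged for manual review", {
  balls <- ball_annotations(z = 10, y = 10, x = 18, radius_vox = 5)
  cand <- fake_candidate(1L, box_vox(9:11, 9:11, 9:11))
  ev <- match_candidates(structure(list(cand),
                                   class = "synapse_candidates"), balls)
  expect_equal(ev$tp, 0L)
  expect_equal(nrow(ev$near_misses), 1L)  # distance 8 < 2 * radius
})

test_that("pr_curve composes detect and match across thresholds", {
  set.seed(32)
  a <- array(0, dim = c(32, 32, 32))
  a[4:12, 4:12, 4:12] <- 0.95
  a[20:28, 20:28, 20:28] <- 0.7
  prob <- prob_from_synapse(a)
  balls <- ball_annotations(z = c(8, 24), y = c(8, 24), x = c(8, 24),
                            radius_vox = c(5, 5))
  cfg <- postprocess_config(smoothing_sigma_vox = 0, min_size_vox = 100)
  curve <- pr_curve(prob, balls, cfg, thresholds = c(0.5, 0.9))
  expect_s3_class(curve, "pr_curve")
  expect_true(all(diff(curve$n_candidates) <= 0))
  # single-threshold curve equals direct detect + match
  single <- pr_curve(prob, balls, cfg, thresholds = 0.9)
  cfg9 <- cfg; cfg9$core_threshold <- 0.9
  direct <- match_candidates(detect_synapses(prob, cfg9), balls)
  expect_equal(single$tp, direct$tp)
  expect_equal(single$precision, direct$precision)
  expect_error(pr_curve(prob, balls, cfg, thresholds = c(0, 0.5)),
               "0, 1")
  bt <- best_threshold(curve)
  expect_equal(nrow(bt), 1L)
})

test_that("evaluation results export to JSON", {
  b <- ball_annotations(z = 10, y = 10, x = 10, radius_vox = 5)
  cand <- fake_candidate(1L, box_vox(8:12, 8:12, 8:12))
  ev <- match_candidates(structure(list(cand),
                                   class = "synapse_candidates"), b)
  path <- file.path(tempdir(), "eval.json")
  write_eval_json(ev, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$tp, 1L)
  expect_equal(j$precision, 1)
})
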