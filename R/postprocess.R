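## Probability-map post-processing: smoothing, hysteresis thresholding,
## connected components, size filtering and core-relaxation
## segmentation of synapse candidates.

#' Post-processing configuration
#'
#' Parameters of the detection chain. Cores are connected components
#' of voxels whose smoothed synapse probability is strictly greater
#' than `core_threshold`; cores smaller than `min_size_vox` voxels
#' (about the volume of two synaptic vesicles at 5x5x9 nm) are
#' discarded. Segments then grow from each surviving core by hysteresis
#' to all reachable voxels with probability at least `relax_threshold`.
#'
#' @param smoothing_sigma_vox Gaussian sigma (voxels) for smoothing the
#'   probability map; 0 skips smoothing. Default 5.
#' @param core_threshold Core probability threshold, strict `>`.
#'   Default 0.98.
#' @param min_size_vox Minimum core size, inclusive. Default 1000.
#' @param max_size_vox Optional maximum core size; `NULL` (default)
#'   disables the upper bound. Useful against myelin-induced giant
#'   components.
#' @param relax_threshold Segmentation (relaxed) threshold, inclusive
#'   `>=`. Default 0.5. Must satisfy `relax_threshold <= core_threshold`.
#' @param connectivity Voxel connectivity: 6, 18 or 26 (default).
#' @param threshold_mode `"probability"` (default) thresholds the
#'   synapse-class probability; `"ratio"` thresholds
#'   `p_synapse / max(other classes)` rescaled through `p/(1+p)` to
#'   `[0, 1)`.
#' @return Object of class `postprocess_config`.
#' @export
postprocess_config <- function(smoothing_sigma_vox = 5,
                               core_threshold = 0.98,
                               min_size_vox = 1000L,
                               max_size_vox = NULL,
                               relax_threshold = 0.5,
                               connectivity = 26L,
                               threshold_mode = c("probability", "ratio")) {
  threshold_mode <- match.arg(threshold_mode)
  if (smoothing_sigma_vox < 0) stop("`smoothing_sigma_vox` must be >= 0")
  if (!(core_threshold > 0 && core_threshold < 1))
    stop("`core_threshold` must lie in (0, 1)")
  if (!(relax_threshold > 0 && relax_threshold <= core_threshold))
    stop("need 0 < relax_threshold <= core_threshold")
  min_size_vox <- as.integer(min_size_vox)
  if (min_size_vox < 1L) stop("`min_size_vox` must be >= 1")
  if (!is.null(max_size_vox)) {
    max_size_vox <- as.integer(max_size_vox)
    if (max_size_vox <= min_size_vox)
      stop("`max_size_vox` must exceed `min_size_vox`")
  }
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26")
  structure(list(smoothing_sigma_vox = smoothing_sigma_vox,
                 core_threshold = core_threshold,
                 min_size_vox = min_size_vox,
                 max_size_vox = max_size_vox,
                 relax_threshold = relax_threshold,
                 connectivity = as.integer(connectivity),
                 threshold_mode = threshold_mode),
            class = "postprocess_config")
}

#' Suggested minimum core size at another voxel resolution
#'
#' The default 1000-voxel floor corresponds to roughly two vesicles at
#' 5 x 5 x 9 nm voxels; this rescales it by voxel volume.
#'
#' @param spacing_nm Voxel size `(z, y, x)` in nm.
#' @return Suggested integer `min_size_vox`.
#' @export
suggest_min_size <- function(spacing_nm) {
  as.integer(round(1000 * (9 * 5 * 5) / prod(spacing_nm)))
}

#' Smooth one class's probability map
#'
#' Gaussian smoothing of the selected class map (to remove the local
#' discontinuities of voxel-wise predictions), clipped back to
#' `[0, 1]`. `sigma = 0` is the identity.
#'
#' @param prob A [probability_map].
#' @param class_name Class to smooth (default `"synapse"`).
#' @param sigma Smoothing sigma in voxels (default 5).
#' @return An [em_volume] of smoothed probabilities.
#' @export
smooth_probability <- function(prob, class_name = "synapse", sigma = 5) {
  v <- class_probability(prob, class_name)
  if (sigma == 0) return(v)
  s <- gaussian_smooth(v, sigma)
  s$data[s$data < 0] <- 0
  s$data[s$data > 1] <- 1
  s
}

# scalar map to threshold, honoring threshold_mode
threshold_map <- function(prob, cfg) {
  if (cfg$threshold_mode == "probability")
    return(class_probability(prob, "synapse"))
  k <- match("synapse", prob$class_names)
  if (is.na(k)) stop("probability map has no 'synapse' class")
  ps <- prob$data[, , , k, drop = TRUE]
  po <- do.call(pmax, c(lapply(setdiff(seq_along(prob$class_names), k),
                               function(j) prob$data[, , , j, drop = TRUE]),
                        list(1e-12)))
  r <- ps / po
  em_volume(r / (1 + r))
}

#' Extract synaptic cores from a smoothed probability map
#'
#' Connected components (under `cfg$connectivity`) of the voxels whose
#' value is strictly greater than `cfg$core_threshold`, keeping those
#' with at least `cfg$min_size_vox` voxels (and at most
#' `cfg$max_size_vox` when set).
#'
#' @param smoothed An [em_volume] (or 3D array) with values in `[0,1]`.
#' @param cfg A [postprocess_config].
#' @return List of 0-based `(z, y, x)` integer coordinate matrices,
#'   one per core, in component discovery order.
#' @export
extract_cores <- function(smoothed, cfg = postprocess_config()) {
  a <- as_vol_array(smoothed)
  d <- dim(a)
  lab <- label_components_cpp(a > cfg$core_threshold, d, cfg$connectivity)
  if (!any(lab > 0L)) return(list())
  sizes <- tabulate(lab)
  keep <- which(sizes >= cfg$min_size_vox &
                (if (is.null(cfg$max_size_vox)) TRUE
                 else sizes <= cfg$max_size_vox))
  lapply(keep, function(k) linear_to_coords(which(lab == k), d))
}

linear_to_coords <- function(idx, d) {
  i <- idx - 1L
  cbind(z = as.integer(i %% d[1]),
        y = as.integer((i %/% d[1]) %% d[2]),
        x = as.integer(i %/% (d[1] * d[2])))
}

coords_to_linear <- function(coords, d) {
  coords[, 1] + d[1] * (coords[, 2] + d[2] * coords[, 3]) + 1
}

#' Grow segments from cores by hysteresis relaxation
#'
#' Each segment is the transitive closure, under the configured
#' connectivity, of the voxels with value `>= cfg$relax_threshold`
#' reachable from its core (hysteresis thresholding). Where segments
#' would merge, contested voxels go to the core with the nearest core
#' voxel (Euclidean, ties to the lower core id). Candidate statistics
#' are computed over the grown segment.
#'
#' @param cores List of disjoint core coordinate matrices (0-based).
#' @param smoothed The same [em_volume] the cores were extracted from.
#' @param cfg A [postprocess_config].
#' @return List of `synapse_candidate` objects (ids in input order).
#' @export
grow_segments <- function(cores, smoothed, cfg = postprocess_config()) {
  a <- as_vol_array(smoothed)
  d <- dim(a)
  if (length(cores) == 0L) return(list())
  core_lab <- integer(prod(d))
  for (i in seq_along(cores)) {
    lin <- coords_to_linear(cores[[i]], d)
    if (any(core_lab[lin] != 0L)) stop("cores must be disjoint")
    core_lab[lin] <- i
  }
  seg <- grow_segments_cpp(core_lab, as.numeric(a), cfg$relax_threshold,
                           d, cfg$connectivity)
  lapply(seq_along(cores), function(i) {
    vox <- linear_to_coords(which(seg == i), d)
    p <- a[coords_to_linear(vox, d)]
    new_candidate(i, cores[[i]], vox, p)
  })
}

new_candidate <- function(id, core, segment, probs) {
  structure(list(id = as.integer(id),
                 core_voxels = core,
                 segment_voxels = segment,
                 size_vox = nrow(segment),
                 centroid = colMeans(segment),
                 bbox = rbind(min = apply(segment, 2, min),
                              max = apply(segment, 2, max)),
                 mean_prob = mean(probs),
                 max_prob = max(probs)),
            class = "synapse_candidate")
}

#' @export
print.synapse_candidate <- function(x, ...) {
  cat(sprintf("synapse_candidate #%d: %d voxels (core %d), centroid (%.1f, %.1f, %.1f), mean p %.3f, max p %.3f\n",
              x$id, x$size_vox, nrow(x$core_voxels),
              x$centroid[1], x$centroid[2], x$centroid[3],
              x$mean_prob, x$max_prob))
  invisible(x)
}

#' Detect synapse candidates in a probability map
#'
#' The full post-processing chain: smooth the synapse-class
#' probability, extract supra-threshold cores, size-filter them, and
#' grow each surviving core into a segment by hysteresis relaxation.
#' Candidates are returned sorted by descending segment size with ids
#' `1..n`.
#'
#' @param prob A [probability_map] containing a `"synapse"` class.
#' @param cfg A [postprocess_config].
#' @return Object of class `synapse_candidates` (a list of
#'   `synapse_candidate`), with the smoothed map retained in the
#'   `"smoothed"` attribute.
#' @export
detect_synapses <- function(prob, cfg = postprocess_config()) {
  smoothed <- smooth_detection_map(prob, cfg)
  cands <- detect_on_smoothed(smoothed, cfg)
  attr(cands, "smoothed") <- smoothed
  cands
}

smooth_detection_map <- function(prob, cfg) {
  m <- threshold_map(prob, cfg)
  if (cfg$smoothing_sigma_vox == 0) return(m)
  s <- gaussian_smooth(m, cfg$smoothing_sigma_vox)
  s$data[s$data < 0] <- 0
  s$data[s$data > 1] <- 1
  s
}

detect_on_smoothed <- function(smoothed, cfg) {
  cores <- extract_cores(smoothed, cfg)
  cands <- grow_segments(cores, smoothed, cfg)
  ord <- order(vapply(cands, function(c) c$size_vox, numeric(1)),
               decreasing = TRUE)
  cands <- cands[ord]
  for (i in seq_along(cands)) cands[[i]]$id <- i
  structure(cands, class = "synapse_candidates")
}

#' @export
print.synapse_candidates <- function(x, ...) {
  cat(sprintf("synapse_candidates: %d candidate(s)\n", length(x)))
  for (c in x) print(c)
  invisible(x)
}

#' Candidate list as a data frame
#'
#' @param x A `synapse_candidates` list.
#' @param row.names,optional,... Standard [as.data.frame()] arguments
#'   (unused).
#' @return Data frame with id, sizes, centroid, bounding box and
#'   probability statistics, one row per candidate.
#' @export
as.data.frame.synapse_candidates <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  if (length(x) == 0L)
    return(data.frame(id = integer(), size_vox = integer(),
                      core_size_vox = integer(),
                      centroid_z = numeric(), centroid_y = numeric(),
                      centroid_x = numeric(),
                      bbox_zmin = integer(), bbox_ymin = integer(),
                      bbox_xmin = integer(), bbox_zmax = integer(),
                      bbox_ymax = integer(), bbox_xmax = integer(),
                      mean_prob = numeric(), max_prob = numeric()))
  do.call(rbind, lapply(x, function(c) {
    data.frame(id = c$id, size_vox = c$size_vox,
               core_size_vox = nrow(c$core_voxels),
               centroid_z = c$centroid[1], centroid_y = c$centroid[2],
               centroid_x = c$centroid[3],
               bbox_zmin = c$bbox["min", 1], bbox_ymin = c$bbox["min", 2],
               bbox_xmin = c$bbox["min", 3], bbox_zmax = c$bbox["max", 1],
               bbox_ymax = c$bbox["max", 2], bbox_xmax = c$bbox["max", 3],
               mean_prob = c$mean_prob, max_prob = c$max_prob)
  }))
}

#' Write candidates to CSV
#' @param cands A `synapse_candidates` list.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_candidates_csv <- function(cands, path) {
  utils::write.csv(as.data.frame(cands), path, row.names = FALSE)
  invisible(path)
}

#' Candidate label volume
#'
#' @param cands A `synapse_candidates` list.
#' @param shape Volume shape `(nz, ny, nx)`.
#' @return An [em_volume] with 0 background and the candidate id at
#'   each segment voxel.
#' @export
candidates_label_volume <- function(cands, shape) {
  lab <- integer(prod(shape))
  for (c in cands) lab[coords_to_linear(c$segment_voxels, shape)] <- c$id
  em_volume(array(lab, dim = shape))
}

#' Rebuild candidates from a label volume
#'
#' Inverse of [candidates_label_volume()] up to the information a
#' label volume carries: segments are recovered per id; cores are not
#' stored, so each candidate's core is set to its segment, and
#' probability statistics are taken from `prob` when given (else NA).
#'
#' @param labvol An [em_volume] (or 3D array) of candidate ids, 0 =
#'   background.
#' @param prob Optional [em_volume] of synapse probabilities.
#' @return A `synapse_candidates` list.
#' @export
candidates_from_label_volume <- function(labvol, prob = NULL) {
  a <- as_vol_array(labvol)
  d <- dim(a)
  ids <- sort(unique(a[a > 0]))
  cands <- lapply(seq_along(ids), function(i) {
    vox <- linear_to_coords(which(a == ids[i]), d)
    p <- if (is.null(prob)) NA_real_
         else as_vol_array(prob)[coords_to_linear(vox, d)]
    new_candidate(ids[i], vox, vox, p)
  })
  structure(cands, class = "synapse_candidates")
}

#' Candidates as ball annotations
#'
#' Centroid plus equivalent-sphere radius (the radius of a sphere with
#' the segment's volume), for cross-evaluation against expert balls.
#'
#' @param cands A `synapse_candidates` list.
#' @return A [ball_annotations] data frame.
#' @export
candidates_to_balls <- function(cands) {
  if (length(cands) == 0L) return(ball_annotations())
  ball_annotations(
    z = vapply(cands, function(c) c$centroid[1], numeric(1)),
    y = vapply(cands, function(c) c$centroid[2], numeric(1)),
    x = vapply(cands, function(c) c$centroid[3], numeric(1)),
    radius_vox = vapply(cands, function(c) (3 * c$size_vox / (4 * pi))^(1 / 3),
                        numeric(1)))
}
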