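## Desk-scale end-to-end benchmarks on synthetic scenes: parameter
## recovery (precision/recall over a threshold sweep) and the
## orientation-invariance check.

#' End-to-end synapse recovery on a synthetic scene
#'
#' Generates a seeded scene, samples sparse brush-stroke labels,
#' trains the forest, predicts blockwise, sweeps detection thresholds
#' and evaluates against the scene's gold balls (border-excluded).
#' This is the package's desk-scale stand-in for a full-volume
#' benchmark: at the best F1 point of the curve the pipeline is
#' expected to recover planted synapses at high precision and recall.
#'
#' @param seed Integer seed driving scene, labels and forest.
#' @param scene_cfg A [scene_config]; default: 128 x 256 x 256 voxels
#'   with 20 synapses at mixed orientations and default distractors.
#' @param strokes_per_class Strokes per class for training (default
#'   10, i.e. 30 strokes in total).
#' @param thresholds Core thresholds to sweep.
#' @param block_shape Blockwise prediction block size.
#' @return List: `scene`, `model`, `curve` ([pr_curve()] result),
#'   `best` (best-F1 row), `eval` (the `synapse_eval` at the best
#'   threshold), `recall_by_orientation` (named vector over planted
#'   orientation classes at the best threshold).
#' @export
synthetic_recovery_benchmark <- function(seed = 0L,
                                         scene_cfg = scene_config(seed = seed),
                                         strokes_per_class = 10L,
                                         thresholds = c(0.25, 0.3, 0.35, 0.4,
                                                        0.45, 0.5, 0.6, 0.7,
                                                        0.8, 0.9, 0.95, 0.98),
                                         block_shape = c(128L, 128L, 128L)) {
  scene <- generate_scene(scene_cfg)
  labels <- make_training_labels(scene, strokes_per_class, seed = seed)
  model <- train_on_volume(scene$volume, labels,
                           cfg = forest_config(seed = seed))
  prob <- predict_blockwise(model, scene$volume,
                            block_shape = block_shape)
  balls <- exclude_border(scene$gold_balls, dim(scene$volume$data))
  curve <- pr_curve(prob, balls, thresholds = thresholds)
  best <- best_threshold(curve)
  ev <- attr(curve, "evals")[[which(curve$threshold == best$threshold)]]
  ori <- scene$placements$orientation
  rec <- vapply(unique(ori), function(o)
    mean(which(ori == o) %in% ev$matches$ball_index), numeric(1))
  names(rec) <- unique(ori)
  list(scene = scene, model = model, curve = curve, best = best,
       eval = ev, recall_by_orientation = rec)
}

#' Orientation-invariance check on matched-size scenes
#'
#' The 3D feature bank is isotropic, so detection should not depend on
#' the angle between a synapse's cleft plane and the imaging plane.
#' This check plants axis-aligned and oblique synapses of matched
#' sizes — radii drawn well above the detection floor set by the
#' probability smoothing and the minimum core size, so size
#' marginality does not confound the orientation comparison — and
#' pools per-orientation recall at each scene's best threshold.
#'
#' @param seed Integer seed; scene seeds are derived from it.
#' @param n_scenes Number of scenes to pool (default 2).
#' @param shape Scene shape (default 96 x 160 x 160).
#' @param n_synapses Synapses per scene (default 12, half per class).
#' @return List with `recall_axis`, `recall_oblique`, `gap`, and the
#'   pooled counts `n_axis`, `n_oblique`.
#' @export
orientation_invariance_check <- function(seed = 0L, n_scenes = 2L,
                                         shape = c(96L, 160L, 160L),
                                         n_synapses = 12L) {
  ax <- ob <- c(0, 0)
  for (k in seq_len(n_scenes)) {
    sseed <- seed + 101L * k
    res <- synthetic_recovery_benchmark(
      seed = sseed,
      scene_cfg = scene_config(shape = shape, n_synapses = n_synapses,
                               n_mitochondria = 4L, membrane_cells = 20L,
                               synapse_radius_vox = c(10, 14), seed = sseed))
    ori <- res$scene$placements$orientation
    m <- res$eval$matches$ball_index
    ax <- ax + c(sum(which(ori == "axis") %in% m), sum(ori == "axis"))
    ob <- ob + c(sum(which(ori == "oblique") %in% m), sum(ori == "oblique"))
    rm(res); gc(FALSE)
  }
  ra <- ax[1] / ax[2]; ro <- ob[1] / ob[2]
  list(recall_axis = ra, recall_oblique = ro, gap = abs(ra - ro),
       n_axis = ax[2], n_oblique = ob[2])
}
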