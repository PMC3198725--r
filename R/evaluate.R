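## Detection evaluation against expert "ball" annotations: border
## exclusions, one-to-one overlap matching with removal semantics, and
## precision/recall.

#' Exclude gold-standard balls near volume borders
#'
#' Drops balls whose sphere touches the left image border (x = 0), the
#' top border (y = 0) or the last slice (z = nz - 1), and balls whose
#' center lies in the first slice (z = 0) — the regions where boundary
#' effects degrade the feature computation.
#'
#' @param balls A [ball_annotations] data frame.
#' @param shape Volume shape `(nz, ny, nx)`.
#' @return The retained [ball_annotations], original order.
#' @export
exclude_border <- function(balls, shape) {
  if (nrow(balls) == 0L) return(balls)
  r <- balls$radius_vox
  drop <- (balls$x - r <= 0) |        # touches left border
          (balls$y - r <= 0) |        # touches top border
          (balls$z + r >= shape[1] - 1) |  # touches last slice
          (balls$z == 0)              # center in first slice
  balls[!drop, , drop = FALSE]
}

#' Does a ball overlap a candidate segment?
#'
#' True iff at least one segment voxel lies within Euclidean distance
#' `radius_vox` (inclusive) of the ball center — i.e. the voxelized
#' sphere and the segment share a voxel.
#'
#' @param ball One-row [ball_annotations] (or list with `z, y, x,
#'   radius_vox`).
#' @param cand A `synapse_candidate`.
#' @return Logical.
#' @export
ball_overlaps_candidate <- function(ball, cand) {
  v <- cand$segment_voxels
  if (nrow(v) == 0L) return(FALSE)
  d2 <- (v[, 1] - ball$z)^2 + (v[, 2] - ball$y)^2 + (v[, 3] - ball$x)^2
  any(d2 <= ball$radius_vox^2)
}

#' Match candidates to gold-standard balls
#'
#' Sequential one-to-one matching with removal semantics: candidates
#' are visited in descending segment size; each claims its nearest
#' (centroid-to-center, ties to the lower ball index) overlapping ball
#' that has not been claimed yet, and both leave the pool. Unmatched
#' candidates are false positives, unclaimed balls false negatives.
#' Recall is tp / (tp + fn), precision tp / (tp + fp); with no
#' candidates at all, precision is reported as 1 with
#' `precision_defined = FALSE`.
#'
#' @param cands A `synapse_candidates` list (border exclusions are the
#'   caller's responsibility for the balls).
#' @param balls [ball_annotations] already filtered by
#'   [exclude_border()].
#' @return Object of class `synapse_eval`: tp/fp/fn counts, precision,
#'   recall, the match pairs, unmatched ids, and near-miss pairs
#'   (centroid within `2 * radius` but no overlap) for proofreading.
#' @export
match_candidates <- function(cands, balls) {
  nb <- nrow(balls)
  ord <- order(vapply(cands, function(c) c$size_vox, numeric(1)),
               decreasing = TRUE)
  claimed <- logical(nb)
  matches <- data.frame(candidate_id = integer(), ball_index = integer())
  for (i in ord) {
    c <- cands[[i]]
    if (nb == 0L) break
    open <- which(!claimed)
    if (length(open) == 0L) break
    ov <- open[vapply(open, function(b)
      ball_overlaps_candidate(balls[b, ], c), logical(1))]
    if (length(ov) == 0L) next
    dd <- (balls$z[ov] - c$centroid[1])^2 + (balls$y[ov] - c$centroid[2])^2 +
          (balls$x[ov] - c$centroid[3])^2
    pick <- ov[which.min(dd)]  # which.min takes the first -> lower index
    claimed[pick] <- TRUE
    matches <- rbind(matches,
                     data.frame(candidate_id = c$id, ball_index = pick))
  }
  tp <- nrow(matches)
  fp <- length(cands) - tp
  fn <- nb - tp
  precision_defined <- (tp + fp) > 0
  precision <- if (precision_defined) tp / (tp + fp) else 1.0
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  near <- near_miss_pairs(cands, balls, matches)
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall,
                 precision_defined = precision_defined,
                 matches = matches,
                 unmatched_candidates = setdiff(
                   vapply(cands, function(c) c$id, integer(1)),
                   matches$candidate_id),
                 unmatched_balls = setdiff(seq_len(nb), matches$ball_index),
                 near_misses = near),
            class = "synapse_eval")
}

# candidate/ball pairs close enough to deserve manual re-verification:
# centroid-to-center distance below 2 * radius but no voxel overlap
near_miss_pairs <- function(cands, balls, matches) {
  out <- data.frame(candidate_id = integer(), ball_index = integer(),
                    centroid_distance = numeric())
  for (c in cands) {
    if (nrow(balls) == 0L) break
    d <- sqrt((balls$z - c$centroid[1])^2 + (balls$y - c$centroid[2])^2 +
              (balls$x - c$centroid[3])^2)
    for (b in which(d < 2 * balls$radius_vox)) {
      if (!ball_overlaps_candidate(balls[b, ], c))
        out <- rbind(out, data.frame(candidate_id = c$id, ball_index = b,
                                     centroid_distance = d[b]))
    }
  }
  out
}

#' @export
print.synapse_eval <- function(x, ...) {
  cat(sprintf("synapse_eval: tp=%d fp=%d fn=%d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  precision %.3f%s, recall %.3f\n", x$precision,
              if (x$precision_defined) "" else " (undefined: no candidates)",
              x$recall))
  if (nrow(x$near_misses))
    cat(sprintf("  %d near-miss pair(s) flagged for manual review\n",
                nrow(x$near_misses)))
  invisible(x)
}

#' Precision-recall curve over detection thresholds
#'
#' Runs the detection chain and the matching protocol at each core
#' threshold. The probability map is smoothed once; thresholding,
#' component extraction, growth and matching are repeated per
#' threshold. For thresholds below the configured relax threshold the
#' relax threshold is lowered to the core threshold so the hysteresis
#' invariant `relax <= core` holds.
#'
#' @param prob A [probability_map].
#' @param balls Gold [ball_annotations], already border-filtered.
#' @param cfg A [postprocess_config].
#' @param thresholds Core thresholds to sweep, each in (0, 1).
#' @return Object of class `pr_curve`: a data frame (threshold, tp,
#'   fp, fn, precision, recall, n_candidates) with the per-threshold
#'   `synapse_eval` objects in the `"evals"` attribute.
#' @export
pr_curve <- function(prob, balls, cfg = postprocess_config(),
                     thresholds = c(0.25, 0.3, 0.35, 0.4, 0.45, 0.5,
                                    0.6, 0.7, 0.8, 0.9, 0.95, 0.98)) {
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie in (0, 1)")
  thresholds <- sort(thresholds)
  smoothed <- smooth_detection_map(prob, cfg)
  evals <- vector("list", length(thresholds))
  rows <- vector("list", length(thresholds))
  for (i in seq_along(thresholds)) {
    t <- thresholds[i]
    cfg_t <- cfg
    cfg_t$core_threshold <- t
    cfg_t$relax_threshold <- min(cfg$relax_threshold, t)
    cands <- detect_on_smoothed(smoothed, cfg_t)
    ev <- match_candidates(cands, balls)
    evals[[i]] <- ev
    rows[[i]] <- data.frame(threshold = t, tp = ev$tp, fp = ev$fp,
                            fn = ev$fn, precision = ev$precision,
                            recall = ev$recall,
                            n_candidates = length(cands))
  }
  out <- do.call(rbind, rows)
  attr(out, "evals") <- evals
  class(out) <- c("pr_curve", "data.frame")
  out
}

#' Best operating point of a PR curve
#'
#' @param curve A [pr_curve()] result.
#' @return The row with the highest F1 score (harmonic mean of
#'   precision and recall); ties go to the higher threshold.
#' @export
best_threshold <- function(curve) {
  p <- curve$precision; r <- curve$recall
  f1 <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  f1[is.na(f1)] <- 0
  curve[max(which(f1 == max(f1))), , drop = FALSE]
}

#' Plot a precision-recall curve
#'
#' Recall on the x-axis, precision on the y-axis, threshold values
#' annotated next to the points.
#'
#' @param x A `pr_curve`.
#' @param ... Passed to [plot()].
#' @export
plot.pr_curve <- function(x, ...) {
  plot(x$recall, x$precision, type = "b", pch = 19,
       xlab = "Recall", ylab = "Precision", xlim = c(0, 1), ylim = c(0, 1),
       ...)
  graphics::text(x$recall, x$precision, labels = x$threshold,
                 pos = 1, cex = 0.7)
  invisible(x)
}

#' Export an evaluation result as JSON
#' @param eval A `synapse_eval`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_eval_json <- function(eval, path) {
  jsonlite::write_json(list(tp = eval$tp, fp = eval$fp, fn = eval$fn,
                            precision = eval$precision, recall = eval$recall,
                            precision_defined = eval$precision_defined,
                            matches = eval$matches,
                            near_misses = eval$near_misses),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
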