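## Random forest voxel classification.
##
## The classifier maps each voxel's feature vector to a distribution
## over the labelled classes. Probabilities are tree-vote fractions, so
## they sum to one per voxel by construction. Training is deterministic
## given the data and the seed.

#' Random forest configuration
#'
#' @param n_trees Number of trees in the ensemble (default 100). The
#'   forest is fairly robust to this choice.
#' @param mtry Features considered at each split; `NULL` (default)
#'   uses the square-root rule, `floor(sqrt(n_channels))`.
#' @param seed Integer RNG seed making training deterministic.
#' @return An object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 100L, mtry = NULL, seed = 0L) {
  n_trees <- as.integer(n_trees)
  if (is.na(n_trees) || n_trees < 1L) stop("`n_trees` must be >= 1")
  if (!is.null(mtry)) {
    mtry <- as.integer(mtry)
    if (is.na(mtry) || mtry < 1L) stop("`mtry` must be >= 1")
  }
  structure(list(n_trees = n_trees, mtry = mtry, seed = as.integer(seed)),
            class = "forest_config")
}

#' Assemble the training matrix from features at labelled voxels
#'
#' One row per labelled voxel (columns in channel order), with the
#' aligned class vector. Duplicate labels at one voxel with the same
#' class are deduplicated; the same voxel labelled with two different
#' classes is a contradiction and an error.
#'
#' @param stack A `feature_stack`.
#' @param labels A [sparse_labels] object; coordinates must lie inside
#'   the stack's volume.
#' @return List with `x` (matrix `n x n_channels`), `y` (factor of
#'   class names), `coords` (the deduplicated coordinates).
#' @export
extract_training_matrix <- function(stack, labels) {
  stopifnot(inherits(stack, "feature_stack"), inherits(labels, "sparse_labels"))
  labels <- dedup_labels(labels, stack$shape)
  d <- stack$shape
  lin <- labels$coords[, 1] + d[1] * (labels$coords[, 2] +
         d[2] * labels$coords[, 3]) + 1
  cls <- labels$class_id
  if (length(unique(cls)) < 2L)
    stop("training requires labels in at least 2 classes")
  x <- stack$values[lin, , drop = FALSE]
  colnames(x) <- stack$channel_names
  y <- factor(labels$class_names[cls], levels = labels$class_names)
  y <- droplevels(y)
  list(x = x, y = y, coords = labels$coords)
}

# deduplicate identical labels; error on contradictory ones
dedup_labels <- function(labels, shape) {
  validate_coords(labels$coords, shape)
  lin <- labels$coords[, 1] + shape[1] * (labels$coords[, 2] +
         shape[2] * labels$coords[, 3])
  if (anyDuplicated(lin)) {
    cls_by_voxel <- split(labels$class_id, lin)
    if (any(vapply(cls_by_voxel, function(v) length(unique(v)) > 1L, logical(1))))
      stop("contradictory labels: the same voxel is labelled with two classes")
  }
  keep <- !duplicated(lin)
  sparse_labels(labels$coords[keep, , drop = FALSE], labels$class_id[keep],
                labels$class_names)
}

#' Train the random forest voxel classifier
#'
#' Fits a bagged ensemble of randomized decision trees on the feature
#' vectors of the labelled voxels. Deterministic given the data and
#' `cfg$seed`; the out-of-bag accuracy estimate and per-class label
#' counts are stored in the returned model's metadata.
#'
#' @param stack A `feature_stack`.
#' @param labels A [sparse_labels] object.
#' @param cfg A [forest_config].
#' @return An object of class `voxel_classifier` with elements
#'   `forest`, `class_names`, `channel_names`, `meta`.
#' @export
train_voxel_classifier <- function(stack, labels, cfg = forest_config()) {
  tm <- extract_training_matrix(stack, labels)
  mtry <- cfg$mtry %||% max(1L, floor(sqrt(ncol(tm$x))))
  if (mtry > ncol(tm$x)) stop("`mtry` exceeds the channel count")
  set.seed(cfg$seed)
  forest <- randomForest::randomForest(x = tm$x, y = tm$y,
                                       ntree = cfg$n_trees, mtry = mtry)
  oob <- 1 - forest$err.rate[cfg$n_trees, "OOB"]
  structure(list(forest = forest,
                 class_names = levels(tm$y),
                 channel_names = colnames(tm$x),
                 meta = list(label_counts = table(tm$y),
                             oob_accuracy = unname(oob),
                             config = cfg)),
            class = "voxel_classifier")
}

#' @export
print.voxel_classifier <- function(x, ...) {
  cat("voxel_classifier (random forest)\n")
  cat(sprintf("  trees: %d, mtry: %d, seed: %d\n",
              x$meta$config$n_trees, x$forest$mtry, x$meta$config$seed))
  cat(sprintf("  classes: %s\n", paste(x$class_names, collapse = ", ")))
  cat(sprintf("  training voxels: %s\n",
              paste(sprintf("%s=%d", names(x$meta$label_counts),
                            as.integer(x$meta$label_counts)), collapse = ", ")))
  cat(sprintf("  out-of-bag accuracy: %.3f\n", x$meta$oob_accuracy))
  invisible(x)
}

#' Per-voxel class probability map
#'
#' @param data 4D array `(z, y, x, class)` of probabilities in
#'   `[0, 1]`, summing to 1 over classes at every voxel.
#' @param class_names Class names, one per channel.
#' @return Object of class `probability_map`.
#' @export
probability_map <- function(data, class_names) {
  if (length(dim(data)) != 4L) stop("`data` must be 4D (z, y, x, class)")
  if (dim(data)[4] != length(class_names))
    stop("class channel count does not match `class_names`")
  structure(list(data = data, class_names = as.character(class_names)),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("probability_map: %d x %d x %d voxels, classes: %s\n",
              d[1], d[2], d[3], paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' Extract one class's probability volume
#' @param prob A [probability_map].
#' @param class_name Class to extract.
#' @param spacing_nm Spacing for the returned volume.
#' @return An [em_volume] of that class's probabilities.
#' @export
class_probability <- function(prob, class_name, spacing_nm = c(9, 5, 5)) {
  k <- match(class_name, prob$class_names)
  if (is.na(k)) stop("unknown class: ", class_name)
  em_volume(prob$data[, , , k, drop = TRUE], spacing_nm)
}

#' Predict class probabilities for a feature stack
#'
#' Applies the trained forest to every voxel. The per-voxel class
#' distribution is the fraction of tree votes, so it sums to 1. The
#' stack's channels must match those the model was trained on, in the
#' same order.
#'
#' @param object A `voxel_classifier`.
#' @param stack A `feature_stack` (channel names must match training).
#' @param ... Unused.
#' @return A [probability_map].
#' @export
predict.voxel_classifier <- function(object, stack, ...) {
  if (!inherits(stack, "feature_stack"))
    stop("`stack` must be a feature_stack")
  if (!identical(stack$channel_names, object$channel_names))
    stop("feature channels do not match the model's training channels")
  n <- nrow(stack$values)
  nclass <- length(object$class_names)
  p <- matrix(0, n, nclass)
  # predict in bounded row chunks: randomForest copies its input, and
  # whole-volume feature matrices are large
  chunk <- 500000L
  for (s in seq.int(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    x <- stack$values[s:e, , drop = FALSE]
    colnames(x) <- stack$channel_names
    p[s:e, ] <- predict(object$forest, x, type = "prob")
  }
  probability_map(array(p, dim = c(stack$shape, nclass)),
                  object$class_names)
}

#' Blockwise prediction over a large volume
#'
#' Computes features and predicts probabilities block by block so that
#' the full feature stack never resides in memory. Blocks are expanded
#' by the filter-bank halo ([feature_halo()]: the maximum kernel reach,
#' including the structure tensor's two-stage cascade) on every side
#' before feature computation, so filter responses at block interiors
#' are identical to the whole-volume computation and the result
#' matches the non-blocked path to within numerical tolerance.
#'
#' @param model A `voxel_classifier`.
#' @param vol An [em_volume].
#' @param spec The [feature_spec] used at training time.
#' @param block_shape Block size `(z, y, x)`; each entry >= 1.
#' @return A [probability_map] for the whole volume.
#' @export
predict_blockwise <- function(model, vol, spec = default_feature_spec(),
                              block_shape = c(128L, 128L, 128L)) {
  stopifnot(inherits(model, "voxel_classifier"))
  block_shape <- pmax(1L, as.integer(block_shape))
  d <- dim(vol$data)
  halo <- feature_halo(spec)
  nclass <- length(model$class_names)
  out <- array(0, dim = c(d, nclass))
  starts <- function(n, b) seq.int(1L, n, by = b)
  for (z0 in starts(d[1], block_shape[1]))
    for (y0 in starts(d[2], block_shape[2]))
      for (x0 in starts(d[3], block_shape[3])) {
        z1 <- min(z0 + block_shape[1] - 1L, d[1])
        y1 <- min(y0 + block_shape[2] - 1L, d[2])
        x1 <- min(x0 + block_shape[3] - 1L, d[3])
        ez0 <- max(1L, z0 - halo); ez1 <- min(d[1], z1 + halo)
        ey0 <- max(1L, y0 - halo); ey1 <- min(d[2], y1 + halo)
        ex0 <- max(1L, x0 - halo); ex1 <- min(d[3], x1 + halo)
        sub <- vol$data[ez0:ez1, ey0:ey1, ex0:ex1, drop = FALSE]
        stk <- suppressWarnings(compute_feature_stack(
          em_volume(sub, vol$spacing_nm), spec))
        # predict only on the interior of the expanded block (== the
        # requested block); halo voxels are some other block's interior
        sd_ <- dim(sub)
        iz <- (z0 - ez0):(z1 - ez0); iy <- (y0 - ey0):(y1 - ey0)
        ix <- (x0 - ex0):(x1 - ex0)
        lin <- as.vector(outer(outer(iz, sd_[1] * iy, `+`),
                               sd_[1] * sd_[2] * ix, `+`)) + 1L
        nclass <- length(model$class_names)
        p <- matrix(0, length(lin), nclass)
        chunk <- 500000L  # bound the per-call copy randomForest makes
        for (s in seq.int(1L, length(lin), by = chunk)) {
          e <- min(s + chunk - 1L, length(lin))
          xx <- stk$values[lin[s:e], , drop = FALSE]
          colnames(xx) <- model$channel_names
          p[s:e, ] <- predict(model$forest, xx, type = "prob")
        }
        rm(stk)
        out[z0:z1, y0:y1, x0:x1, ] <-
          array(p, dim = c(z1 - z0 + 1L, y1 - y0 + 1L, x1 - x0 + 1L, nclass))
      }
  probability_map(out, model$class_names)
}

#' Compute feature rows only at selected voxels
#'
#' Training-time helper: computes the feature bank on the minimal set
#' of halo-padded blocks that cover the given voxels and returns the
#' feature matrix at exactly those voxels. Equivalent to computing the
#' full stack and indexing it, at a fraction of the cost when labels
#' are sparse.
#'
#' @param vol An [em_volume].
#' @param spec A [feature_spec].
#' @param coords `n x 3` matrix of 0-based `(z, y, x)` coordinates.
#' @param block_shape Internal block size; small blocks keep the
#'   halo'd patches tight around sparse labels.
#' @return Matrix `n x n_channels` with channel-name columns, rows
#'   aligned to `coords`.
#' @export
compute_features_at <- function(vol, spec, coords,
                                block_shape = c(16L, 16L, 16L)) {
  coords <- as.matrix(coords)
  validate_coords(coords, dim(vol$data))
  d <- dim(vol$data)
  halo <- feature_halo(spec)
  bi <- cbind(coords[, 1] %/% block_shape[1],
              coords[, 2] %/% block_shape[2],
              coords[, 3] %/% block_shape[3])
  key <- bi[, 1] + 10000 * bi[, 2] + 1e8 * bi[, 3]
  out <- matrix(0, nrow = nrow(coords), ncol = n_channels(spec))
  colnames(out) <- feature_channel_names(spec)
  for (k in unique(key)) {
    rows <- which(key == k)
    b <- bi[rows[1], ]
    z0 <- b[1] * block_shape[1] + 1L; z1 <- min(z0 + block_shape[1] - 1L, d[1])
    y0 <- b[2] * block_shape[2] + 1L; y1 <- min(y0 + block_shape[2] - 1L, d[2])
    x0 <- b[3] * block_shape[3] + 1L; x1 <- min(x0 + block_shape[3] - 1L, d[3])
    ez0 <- max(1L, z0 - halo); ez1 <- min(d[1], z1 + halo)
    ey0 <- max(1L, y0 - halo); ey1 <- min(d[2], y1 + halo)
    ex0 <- max(1L, x0 - halo); ex1 <- min(d[3], x1 + halo)
    sub <- vol$data[ez0:ez1, ey0:ey1, ex0:ex1, drop = FALSE]
    stk <- suppressWarnings(compute_feature_stack(
      em_volume(sub, vol$spacing_nm), spec))
    sd_ <- dim(sub)
    lz <- coords[rows, 1] - (ez0 - 1L)
    ly <- coords[rows, 2] - (ey0 - 1L)
    lx <- coords[rows, 3] - (ex0 - 1L)
    lin <- lz + sd_[1] * (ly + sd_[2] * lx) + 1
    out[rows, ] <- stk$values[lin, , drop = FALSE]
  }
  out
}

#' Train a classifier directly from a volume and sparse labels
#'
#' Convenience wrapper that computes features only around the labelled
#' voxels (see [compute_features_at()]) and trains the forest.
#'
#' @param vol An [em_volume].
#' @param labels A [sparse_labels] object.
#' @param spec A [feature_spec].
#' @param cfg A [forest_config].
#' @return A `voxel_classifier`.
#' @export
train_on_volume <- function(vol, labels, spec = default_feature_spec(),
                            cfg = forest_config()) {
  labels <- dedup_labels(labels, dim(vol$data))
  x <- compute_features_at(vol, spec, labels$coords)
  stack <- structure(list(values = x, shape = c(nrow(x), 1L, 1L),
                          channel_names = colnames(x)),
                     class = "feature_stack")
  # relabel coordinates to rows of the pseudo-stack
  lab <- sparse_labels(cbind(seq_len(nrow(x)) - 1L, 0L, 0L),
                       labels$class_id, labels$class_names)
  train_voxel_classifier(stack, lab, cfg)
}

#' Save a trained voxel classifier
#'
#' Single-file archive (RDS) containing the forest state, class and
#' channel names, training metadata and a versioned header.
#'
#' @param model A `voxel_classifier`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "voxel_classifier"))
  saveRDS(list(format = "emsynapse_model", version = 1L, model = model), path)
  invisible(path)
}

#' Load a trained voxel classifier saved by [save_model()]
#' @param path Model file.
#' @return A `voxel_classifier`.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "emsynapse_model"))
    stop("not an emsynapse model file: ", path)
  obj$model
}
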