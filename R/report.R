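## End-to-end pipeline driver and HTML proofreading report.

#' Pipeline configuration
#'
#' Composite configuration for [run_pipeline()]: input paths, the
#' feature spec, forest and post-processing settings, and the block
#' shape for blockwise prediction. Serializable to/from a YAML file.
#'
#' @param volume Path to the input volume (TIFF/HDF5/directory).
#' @param labels Path to sparse training labels (CSV or label volume);
#'   either this or `model` must be given.
#' @param model Path to a trained model file ([save_model()]).
#' @param balls Optional path to gold ball annotations for evaluation.
#' @param out_dir Output directory for artifacts.
#' @param feature_spec A [feature_spec].
#' @param forest A [forest_config].
#' @param postprocess A [postprocess_config].
#' @param block_shape Block shape for [predict_blockwise()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(volume = NULL, labels = NULL, model = NULL,
                            balls = NULL, out_dir = "emsynapse_out",
                            feature_spec = default_feature_spec(),
                            forest = forest_config(),
                            postprocess = postprocess_config(),
                            block_shape = c(128L, 128L, 128L)) {
  structure(list(volume = volume, labels = labels, model = model,
                 balls = balls, out_dir = out_dir,
                 feature_spec = feature_spec, forest = forest,
                 postprocess = postprocess,
                 block_shape = as.integer(block_shape)),
            class = "pipeline_config")
}

#' Read a pipeline config from YAML
#' @param path YAML file with fields matching [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (f in c("volume", "labels", "model", "balls", "out_dir"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  if (!is.null(y$feature_spec))
    args$feature_spec <- feature_spec_from_list(y$feature_spec)
  if (!is.null(y$forest))
    args$forest <- do.call(forest_config, y$forest)
  if (!is.null(y$postprocess))
    args$postprocess <- do.call(postprocess_config, y$postprocess)
  if (!is.null(y$block_shape)) args$block_shape <- y$block_shape
  do.call(pipeline_config, args)
}

#' Write a pipeline config to YAML
#' @param cfg A `pipeline_config`.
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
write_pipeline_config <- function(cfg, path) {
  y <- list(volume = cfg$volume, labels = cfg$labels, model = cfg$model,
            balls = cfg$balls, out_dir = cfg$out_dir,
            feature_spec = feature_spec_to_list(cfg$feature_spec),
            forest = unclass(cfg$forest),
            postprocess = unclass(cfg$postprocess),
            block_shape = cfg$block_shape)
  yaml::write_yaml(y[!vapply(y, is.null, logical(1))], path)
  invisible(path)
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[emsynapse:%s] %s", stage, sprintf(...)))
}

#' Run the full detection pipeline
#'
#' Features -> blockwise random-forest prediction -> smoothing,
#' thresholding, connected components, size filter, hysteresis
#' segmentation; optionally evaluation against gold balls. Writes the
#' candidate CSV, a candidate label volume, ball-style candidate CSV,
#' the HTML report and a JSON run summary (config echo, seed, stage
#' timings) into `cfg$out_dir`. Any stage error aborts with the stage
#' name.
#'
#' @param cfg A `pipeline_config` with `volume` and one of `labels` /
#'   `model` set.
#' @return Invisibly, a list with `candidates`, `prob`, `eval` (or
#'   `NULL`), and the artifact paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(cfg$volume)) stop("pipeline config: `volume` is missing")
  if (is.null(cfg$labels) && is.null(cfg$model))
    stop("pipeline config: one of `labels` or `model` is required")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[3]
    r <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[stage]] <<- round(proc.time()[3] - t0, 2)
    pipeline_log(stage, "done in %.1fs", timings[[stage]])
    r
  }
  vol <- tick("read_volume", read_volume(cfg$volume))
  model <- if (!is.null(cfg$model)) {
    tick("load_model", load_model(cfg$model))
  } else {
    labels <- tick("read_labels", read_labels(cfg$labels, vol))
    m <- tick("train", train_on_volume(vol, labels, cfg$feature_spec,
                                       cfg$forest))
    pipeline_log("train", "out-of-bag accuracy %.3f", m$meta$oob_accuracy)
    save_model(m, file.path(cfg$out_dir, "model.rds"))
    m
  }
  prob <- tick("predict", predict_blockwise(model, vol, cfg$feature_spec,
                                            cfg$block_shape))
  cands <- tick("detect", detect_synapses(prob, cfg$postprocess))
  pipeline_log("detect", "%d candidate(s)", length(cands))
  eval <- NULL
  if (!is.null(cfg$balls)) {
    balls <- exclude_border(read_balls(cfg$balls), dim(vol$data))
    eval <- tick("evaluate", match_candidates(cands, balls))
    write_eval_json(eval, file.path(cfg$out_dir, "evaluation.json"))
  }
  paths <- list(
    candidates_csv = file.path(cfg$out_dir, "candidates.csv"),
    candidate_balls_csv = file.path(cfg$out_dir, "candidate_balls.csv"),
    label_volume = file.path(cfg$out_dir, "candidate_labels.h5"),
    report = file.path(cfg$out_dir, "report.html"),
    summary = file.path(cfg$out_dir, "run_summary.json"))
  write_candidates_csv(cands, paths$candidates_csv)
  write_balls(candidates_to_balls(cands), paths$candidate_balls_csv)
  write_volume(candidates_label_volume(cands, dim(vol$data)),
               paths$label_volume)
  tick("report", render_report(cands, vol, cfg$out_dir,
                               eval = eval,
                               oob_accuracy = model$meta$oob_accuracy))
  summary <- list(package_version = as.character(utils::packageVersion("emsynapse")),
                  config = yaml::yaml.load(yaml::as.yaml(list(
                    feature_spec = feature_spec_to_list(cfg$feature_spec),
                    forest = unclass(cfg$forest),
                    postprocess = unclass(cfg$postprocess),
                    block_shape = cfg$block_shape))),
                  n_candidates = length(cands),
                  timings_s = timings)
  if (!is.null(eval))
    summary$evaluation <- list(tp = eval$tp, fp = eval$fp, fn = eval$fn,
                               precision = eval$precision,
                               recall = eval$recall)
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA)
  invisible(list(candidates = cands, prob = prob, eval = eval,
                 paths = paths))
}

# grayscale [0,255]-ish matrix -> PNG file, with optional outline mask
write_thumbnail <- function(img, path, outline = NULL) {
  rng <- range(img)
  g <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  rgb <- array(g, dim = c(dim(g), 3))
  if (!is.null(outline) && any(outline)) {
    r <- rgb[, , 1]; gg <- rgb[, , 2]; b <- rgb[, , 3]
    r[outline] <- 1; gg[outline] <- 0.1; b[outline] <- 0.1
    rgb[, , 1] <- r; rgb[, , 2] <- gg; rgb[, , 3] <- b
  }
  png::writePNG(rgb, path)
}

# boundary of a 2D logical mask (4-neighborhood)
mask_outline <- function(m) {
  if (!any(m)) return(m)
  sh <- function(mm, dr, dc) {
    out <- matrix(FALSE, nrow(mm), ncol(mm))
    rs <- seq_len(nrow(mm)) + dr; cs <- seq_len(ncol(mm)) + dc
    ok_r <- rs >= 1 & rs <= nrow(mm); ok_c <- cs >= 1 & cs <= ncol(mm)
    out[ok_r, ok_c] <- mm[rs[ok_r], cs[ok_c]]
    out
  }
  m & !(sh(m, 1, 0) & sh(m, -1, 0) & sh(m, 0, 1) & sh(m, 0, -1))
}

# fixed-size crop of a 2D plane centered near (r0, c0), padded at edges
crop_pad <- function(plane, r0, c0, size = 128L) {
  h <- size %/% 2L
  rows <- (r0 - h + 1L):(r0 + h)
  cols <- (c0 - h + 1L):(c0 + h)
  out <- matrix(mean(plane), size, size)
  okr <- rows >= 1 & rows <= nrow(plane)
  okc <- cols >= 1 & cols <= ncol(plane)
  out[which(okr), which(okc)] <- plane[rows[okr], cols[okc]]
  out
}

#' Render the HTML proofreading report
#'
#' One page listing every candidate with id, sizes, centroid,
#' mean/max probability and three orthogonal 128x128 crops (xy, xz,
#' yz) through the centroid with the segment outlined — the summary a
#' human uses to discard false positives in minutes. When an
#' evaluation is supplied, a near-miss section lists
#' candidate/gold-ball pairs that nearly touch, for manual
#' re-verification.
#'
#' @param cands A `synapse_candidates` list.
#' @param vol The source [em_volume].
#' @param out_dir Output directory; thumbnails go to
#'   `out_dir/thumbnails/`.
#' @param eval Optional `synapse_eval` whose near-misses are listed.
#' @param oob_accuracy Optional training OOB accuracy to display.
#' @return Invisibly, the path of the written `report.html`.
#' @export
render_report <- function(cands, vol, out_dir, eval = NULL,
                          oob_accuracy = NULL) {
  dir.create(file.path(out_dir, "thumbnails"), showWarnings = FALSE,
             recursive = TRUE)
  d <- dim(vol$data)
  rows <- character()
  ord <- order(vapply(cands, function(c) c$id, integer(1)))
  for (c in cands[ord]) {
    ctr <- pmin(pmax(round(c$centroid), 0), d - 1) + 1L  # 1-based
    seg <- c$segment_voxels + 1L
    views <- list(
      xy = list(img = vol$data[ctr[1], , ], r = ctr[2], cc = ctr[3],
                segm = seg[seg[, 1] == ctr[1], 2:3, drop = FALSE],
                pd = c(d[2], d[3])),
      xz = list(img = vol$data[, ctr[2], ], r = ctr[1], cc = ctr[3],
                segm = seg[seg[, 2] == ctr[2], c(1, 3), drop = FALSE],
                pd = c(d[1], d[3])),
      yz = list(img = vol$data[, , ctr[3]], r = ctr[1], cc = ctr[2],
                segm = seg[seg[, 3] == ctr[3], 1:2, drop = FALSE],
                pd = c(d[1], d[2])))
    imgs <- character()
    for (vn in names(views)) {
      v <- views[[vn]]
      m <- matrix(FALSE, v$pd[1], v$pd[2])
      if (nrow(v$segm)) m[v$segm] <- TRUE
      ol <- mask_outline(m)
      fn <- sprintf("thumbnails/cand%03d_%s.png", c$id, vn)
      write_thumbnail(crop_pad(v$img, v$r, v$cc),
                      file.path(out_dir, fn),
                      outline = crop_pad(ol, v$r, v$cc) > 0.5)
      imgs <- c(imgs, sprintf('<img src="%s" alt="%s" title="%s">',
                              fn, vn, vn))
    }
    rows <- c(rows, sprintf(
      '<tr><td>%d</td><td>%d</td><td>%d</td><td>(%.1f, %.1f, %.1f)</td><td>%.3f</td><td>%.3f</td><td>%s</td></tr>',
      c$id, c$size_vox, nrow(c$core_voxels),
      c$centroid[1], c$centroid[2], c$centroid[3],
      c$mean_prob, c$max_prob, paste(imgs, collapse = " ")))
  }
  near <- ""
  if (!is.null(eval) && nrow(eval$near_misses) > 0) {
    nm <- apply(eval$near_misses, 1, function(r) sprintf(
      "<tr><td>%d</td><td>%d</td><td>%.1f</td></tr>",
      as.integer(r["candidate_id"]), as.integer(r["ball_index"]),
      as.numeric(r["centroid_distance"])))
    near <- paste0(
      "<h2>Near misses (manual re-verification suggested)</h2>",
      "<table border='1'><tr><th>Candidate</th><th>Gold ball</th>",
      "<th>Centroid distance (vox)</th></tr>",
      paste(nm, collapse = "\n"), "</table>")
  }
  body <- if (length(cands) == 0L) {
    "<p><b>Zero synapse candidates detected.</b></p>"
  } else {
    paste0("<table border='1'><tr><th>Id</th><th>Size (vox)</th>",
           "<th>Core size</th><th>Centroid (z, y, x)</th>",
           "<th>Mean p</th><th>Max p</th><th>xy / xz / yz</th></tr>",
           paste(rows, collapse = "\n"), "</table>")
  }
  oob <- if (is.null(oob_accuracy)) "" else
    sprintf("<p>Training out-of-bag accuracy: %.3f</p>", oob_accuracy)
  html <- paste0(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>Synapse detection report</title>",
    "<style>img{width:128px;height:128px;image-rendering:pixelated}",
    "td{text-align:center;padding:4px}</style></head><body>",
    sprintf("<h1>Synapse detection report: %d candidate(s)</h1>",
            length(cands)),
    oob, body, near, "</body></html>")
  path <- file.path(out_dir, "report.html")
  writeLines(html, path)
  invisible(path)
}
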