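## Seeded synthetic EM-like volumes with known synapse ground truth.
##
## The generator emulates the structures that drive the real detection
## problem: dark sheet-like synaptic densities embedded in a membrane
## apposition, with an adjacent cluster of vesicle-like dots; dark
## Voronoi membrane surfaces partitioning the volume into cells;
## textured mitochondria-like blobs and optional multi-layered
## extra-dark "myelin" sheets (the classic false-positive sources); and
## Gaussian noise. Dark means stained, background is bright. Every
## scene carries dense masks and gold ball annotations so each pipeline
## stage can be tested without external data.

#' Synthetic scene configuration
#'
#' @param shape Volume shape `(z, y, x)`; each dimension of at least
#'   32 voxels is recommended.
#' @param n_synapses Number of synapses to plant.
#' @param n_mitochondria Number of mitochondria-like blobs.
#' @param membrane_cells Voronoi seed count for the membrane partition.
#' @param synapse_thickness_vox Range of disc thickness in voxels.
#' @param synapse_radius_vox Range of disc radius in voxels.
#' @param vesicle_count_range Vesicles per synapse.
#' @param axis_aligned_fraction Fraction of synapses whose disc normal
#'   is a coordinate axis; the rest get oblique random orientations.
#' @param background_mean,background_sd Background intensity model
#'   (8-bit-like grayscale).
#' @param membrane_intensity,synapse_intensity,vesicle_intensity
#'   Darkness of membranes, synaptic densities and vesicles.
#' @param mito_intensity Mitochondrion interior intensity (striations
#'   modulate around it).
#' @param myelin Add myelin-like multi-layer dark sheets (default
#'   `TRUE`).
#' @param noise_sigma Additive Gaussian noise standard deviation.
#' @param seed Integer RNG seed; the scene is deterministic given the
#'   config.
#' @return Object of class `scene_config`.
#' @export
scene_config <- function(shape = c(128L, 256L, 256L),
                         n_synapses = 20L,
                         n_mitochondria = 8L,
                         membrane_cells = 40L,
                         synapse_thickness_vox = c(3, 5),
                         synapse_radius_vox = c(8, 15),
                         vesicle_count_range = c(3L, 10L),
                         axis_aligned_fraction = 0.5,
                         background_mean = 200,
                         background_sd = 8,
                         membrane_intensity = 90,
                         synapse_intensity = 60,
                         vesicle_intensity = 70,
                         mito_intensity = 140,
                         myelin = TRUE,
                         noise_sigma = 10,
                         seed = 0L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("invalid `shape`")
  if (n_synapses < 0 || n_mitochondria < 0 || membrane_cells < 0)
    stop("counts must be >= 0")
  if (n_synapses > 0 && 1.8 * max(synapse_radius_vox) + 4 > (min(shape) - 1) / 2)
    stop("synapse geometry does not fit inside `shape`")
  structure(list(shape = shape,
                 n_synapses = as.integer(n_synapses),
                 n_mitochondria = as.integer(n_mitochondria),
                 membrane_cells = as.integer(membrane_cells),
                 synapse_thickness_vox = as.numeric(synapse_thickness_vox),
                 synapse_radius_vox = as.numeric(synapse_radius_vox),
                 vesicle_count_range = as.integer(vesicle_count_range),
                 axis_aligned_fraction = axis_aligned_fraction,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 membrane_intensity = membrane_intensity,
                 synapse_intensity = synapse_intensity,
                 vesicle_intensity = vesicle_intensity,
                 mito_intensity = mito_intensity,
                 myelin = isTRUE(myelin),
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# local coordinate grids for a bounding box (0-based global coords)
box_grid <- function(lo, hi) {
  nz <- hi[1] - lo[1] + 1L; ny <- hi[2] - lo[2] + 1L; nx <- hi[3] - lo[3] + 1L
  list(z = array(rep(lo[1]:hi[1], times = ny * nx), c(nz, ny, nx)),
       y = array(rep(rep(lo[2]:hi[2], each = nz), times = nx), c(nz, ny, nx)),
       x = array(rep(lo[3]:hi[3], each = nz * ny), c(nz, ny, nx)))
}

clamp_box <- function(center, half, shape) {
  lo <- pmax(0L, as.integer(floor(center - half)))
  hi <- pmin(shape - 1L, as.integer(ceiling(center + half)))
  list(lo = lo, hi = hi)
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

random_oblique_vector <- function() {
  repeat {
    v <- random_unit_vector()
    if (max(abs(v)) < 0.9) return(v)  # away from all axes
  }
}

#' Generate a synthetic EM scene
#'
#' Deterministic given `cfg$seed`. Builds, in order: a Voronoi membrane
#' partition (dark 1-2 voxel sheets); synapses as apposed pairs of
#' thickened dark density discs separated by a narrow cleft, at
#' controlled orientations, each embedded in a coplanar membrane
#' patch with a vesicle cluster offset to the presynaptic side
#' (the morphological criteria experts use: pre/post-synaptic
#' densities, visible cleft, nearby vesicles); mitochondria as
#' dark-rimmed ellipsoids with internal striations, plus optional
#' myelin-like triple sheets; and additive Gaussian noise. One gold
#' ball per synapse is placed at the disc centroid with the disc
#' radius. If a synapse cannot be placed within 100 retries the scene
#' is returned with fewer synapses and a warning; the gold list stays
#' consistent with what was placed.
#'
#' @param cfg A [scene_config].
#' @return Object of class `synthetic_scene`: `volume` ([em_volume]),
#'   `gold_balls` ([ball_annotations]), `synapse_mask`,
#'   `membrane_mask`, `distractor_mask`, `myelin_mask` (logical
#'   arrays), `placements` (data frame with orientation class per
#'   synapse), `config`.
#' @export
generate_scene <- function(cfg = scene_config()) {
  stopifnot(inherits(cfg, "scene_config"))
  set.seed(cfg$seed)
  d <- cfg$shape
  n <- prod(d)
  vol <- array(stats::rnorm(n, cfg$background_mean, cfg$background_sd), dim = d)
  synapse_mask <- array(FALSE, dim = d)
  distractor_mask <- array(FALSE, dim = d)

  # (1) Voronoi membranes: voxels nearly equidistant to the two
  # nearest cell seeds form dark sheets 1-2 voxels thick
  membrane_mask <- array(FALSE, dim = d)
  if (cfg$membrane_cells >= 2L) {
    seeds <- cbind(stats::runif(cfg$membrane_cells, 0, d[1] - 1),
                   stats::runif(cfg$membrane_cells, 0, d[2] - 1),
                   stats::runif(cfg$membrane_cells, 0, d[3] - 1))
    d12 <- voronoi_d12(d, seeds)
    membrane_mask <- array(d12[, 2] - d12[, 1] < 1.4, dim = d)
    vol[membrane_mask] <- cfg$membrane_intensity +
      stats::rnorm(sum(membrane_mask), 0, 3)
  }

  # (2) synapses: PSD disc + coplanar membrane patch + vesicle cluster.
  # Orientation classes are assigned in shuffled order so that synapse
  # index carries no orientation information.
  n_axis <- round(cfg$n_synapses * cfg$axis_aligned_fraction)
  ori_classes <- sample(rep(c("axis", "oblique"),
                            c(n_axis, cfg$n_synapses - n_axis)))
  placements <- NULL
  synapse_voxels <- list()
  centers <- matrix(numeric(0), ncol = 3)
  radii <- numeric(0)
  placed <- 0L
  for (i in seq_len(cfg$n_synapses)) {
    r <- stats::runif(1, cfg$synapse_radius_vox[1], cfg$synapse_radius_vox[2])
    th <- stats::runif(1, cfg$synapse_thickness_vox[1],
                       cfg$synapse_thickness_vox[2])
    orientation <- ori_classes[placed + 1L]
    nrm <- if (orientation == "axis") {
      ax <- sample(3, 1)
      v <- c(0, 0, 0); v[ax] <- 1; v
    } else random_oblique_vector()
    margin <- 1.8 * r + 4  # membrane patch + vesicle offset must fit
    ok <- FALSE
    for (try in seq_len(100L)) {
      ctr <- c(stats::runif(1, margin, d[1] - 1 - margin),
               stats::runif(1, margin, d[2] - 1 - margin),
               stats::runif(1, margin, d[3] - 1 - margin))
      if (nrow(centers) == 0L ||
          all(sqrt(rowSums(sweep(centers, 2, ctr)^2)) >
              r + radii + 16)) { ok <- TRUE; break }
    }
    if (!ok) next
    rm_ <- 1.8 * r
    bb <- clamp_box(ctr, rep(rm_ + 3, 3), d)
    g <- box_grid(bb$lo, bb$hi)
    pz <- g$z - ctr[1]; py <- g$y - ctr[2]; px <- g$x - ctr[3]
    t <- pz * nrm[1] + py * nrm[2] + px * nrm[3]
    l2 <- pmax(pz^2 + py^2 + px^2 - t^2, 0)
    sl <- (bb$lo[1]:bb$hi[1]) + 1L
    sy <- (bb$lo[2]:bb$hi[2]) + 1L
    sx <- (bb$lo[3]:bb$hi[3]) + 1L
    sub <- vol[sl, sy, sx, drop = FALSE]
    patch <- abs(t) <= 0.8 & l2 <= rm_^2
    sub[patch] <- cfg$membrane_intensity + stats::rnorm(sum(patch), 0, 3)
    # the synaptic complex: pre- and post-synaptic density sheets
    # apposed across a ~2 voxel cleft, the morphology experts look for
    cleft <- 1
    disc <- abs(t) >= cleft & abs(t) <= cleft + th & l2 <= r^2
    sub[disc] <- cfg$synapse_intensity + stats::rnorm(sum(disc), 0, 3)
    vol[sl, sy, sx] <- sub
    msk <- synapse_mask[sl, sy, sx, drop = FALSE]
    msk[disc] <- TRUE
    synapse_mask[sl, sy, sx] <- msk
    # vesicle cluster on one side of the complex
    nv <- sample(seq(cfg$vesicle_count_range[1], cfg$vesicle_count_range[2]), 1)
    ves_ctr <- ctr + nrm * (cleft + th + 5)
    for (v in seq_len(nv)) {
      tang <- random_unit_vector()
      tang <- tang - sum(tang * nrm) * nrm
      if (sqrt(sum(tang^2)) < 1e-6) tang <- c(nrm[2], -nrm[1], 0)
      tang <- tang / sqrt(sum(tang^2))
      vc <- ves_ctr + tang * stats::runif(1, 0, 0.7 * r) +
            nrm * stats::runif(1, 0, 3)
      vr <- stats::runif(1, 2, 3)
      vb <- clamp_box(vc, rep(vr + 1, 3), d)
      vg <- box_grid(vb$lo, vb$hi)
      inside <- (vg$z - vc[1])^2 + (vg$y - vc[2])^2 + (vg$x - vc[3])^2 <= vr^2
      vsl <- (vb$lo[1]:vb$hi[1]) + 1L
      vsy <- (vb$lo[2]:vb$hi[2]) + 1L
      vsx <- (vb$lo[3]:vb$hi[3]) + 1L
      vsub <- vol[vsl, vsy, vsx, drop = FALSE]
      vsub[inside] <- cfg$vesicle_intensity + stats::rnorm(sum(inside), 0, 3)
      vol[vsl, vsy, vsx] <- vsub
    }
    placed <- placed + 1L
    centers <- rbind(centers, ctr)
    radii <- c(radii, r)
    placements <- rbind(placements,
                        data.frame(z = ctr[1], y = ctr[2], x = ctr[3],
                                   radius_vox = r, thickness_vox = th,
                                   orientation = orientation,
                                   nz = nrm[1], ny = nrm[2], nx = nrm[3]))
    synapse_voxels[[placed]] <- {
      idx <- which(disc)
      cbind(z = g$z[idx], y = g$y[idx], x = g$x[idx])
    }
  }
  if (placed < cfg$n_synapses)
    warning("placed only ", placed, " of ", cfg$n_synapses,
            " synapses within the retry budget")

  # (3) mitochondria: rotated ellipsoids, dark rim, striated interior
  for (m in seq_len(cfg$n_mitochondria)) {
    ax <- c(stats::runif(1, 10, 18), stats::runif(1, 6, 12),
            stats::runif(1, 6, 12))
    ok <- FALSE
    for (try in seq_len(100L)) {
      ctr <- c(stats::runif(1, max(ax) + 2, d[1] - 3 - max(ax)),
               stats::runif(1, max(ax) + 2, d[2] - 3 - max(ax)),
               stats::runif(1, max(ax) + 2, d[3] - 3 - max(ax)))
      if (nrow(centers) == 0L ||
          min(sqrt(rowSums(sweep(centers, 2, ctr)^2))) >
            max(cfg$synapse_radius_vox) + max(ax) + 10) { ok <- TRUE; break }
    }
    if (!ok) next
    R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    bb <- clamp_box(ctr, rep(max(ax) + 1, 3), d)
    g <- box_grid(bb$lo, bb$hi)
    pz <- g$z - ctr[1]; py <- g$y - ctr[2]; px <- g$x - ctr[3]
    u <- R[1, 1] * pz + R[2, 1] * py + R[3, 1] * px
    v <- R[1, 2] * pz + R[2, 2] * py + R[3, 2] * px
    w <- R[1, 3] * pz + R[2, 3] * py + R[3, 3] * px
    q <- (u / ax[1])^2 + (v / ax[2])^2 + (w / ax[3])^2
    sl <- (bb$lo[1]:bb$hi[1]) + 1L
    sy <- (bb$lo[2]:bb$hi[2]) + 1L
    sx <- (bb$lo[3]:bb$hi[3]) + 1L
    sub <- vol[sl, sy, sx, drop = FALSE]
    interior <- q <= 0.85
    rim <- q > 0.85 & q <= 1
    sub[interior] <- cfg$mito_intensity +
      30 * sin(2 * pi * u[interior] / 5) +
      stats::rnorm(sum(interior), 0, 4)
    sub[rim] <- 100 + stats::rnorm(sum(rim), 0, 4)
    vol[sl, sy, sx] <- sub
    dm <- distractor_mask[sl, sy, sx, drop = FALSE]
    dm[interior | rim] <- TRUE
    distractor_mask[sl, sy, sx] <- dm
  }

  # myelin-like triple sheets: extra-dark layered membranes, tracked
  # separately so training can stratify "rest" strokes over them
  myelin_mask <- array(FALSE, dim = d)
  if (cfg$myelin) {
    for (m in 1:2) {
      nrm <- random_unit_vector()
      rr_max <- min(30, (min(d) - 15) / 2)
      if (rr_max < 8) break  # volume too small for myelin sheets
      rr <- stats::runif(1, min(20, rr_max - 2), rr_max)
      ok <- FALSE
      for (try in seq_len(100L)) {
        ctr <- c(stats::runif(1, rr + 6, d[1] - 7 - rr),
                 stats::runif(1, rr + 6, d[2] - 7 - rr),
                 stats::runif(1, rr + 6, d[3] - 7 - rr))
        if (nrow(centers) == 0L ||
            min(sqrt(rowSums(sweep(centers, 2, ctr)^2))) >
              max(cfg$synapse_radius_vox) + rr + 12) { ok <- TRUE; break }
      }
      if (!ok) next
      bb <- clamp_box(ctr, rep(rr + 5, 3), d)
      g <- box_grid(bb$lo, bb$hi)
      pz <- g$z - ctr[1]; py <- g$y - ctr[2]; px <- g$x - ctr[3]
      t <- pz * nrm[1] + py * nrm[2] + px * nrm[3]
      l2 <- pmax(pz^2 + py^2 + px^2 - t^2, 0)
      sheets <- (abs(t) <= 0.7 | abs(t - 2.2) <= 0.7 | abs(t + 2.2) <= 0.7) &
                l2 <= rr^2
      sl <- (bb$lo[1]:bb$hi[1]) + 1L
      sy <- (bb$lo[2]:bb$hi[2]) + 1L
      sx <- (bb$lo[3]:bb$hi[3]) + 1L
      sub <- vol[sl, sy, sx, drop = FALSE]
      sub[sheets] <- 40 + stats::rnorm(sum(sheets), 0, 3)
      vol[sl, sy, sx] <- sub
      dm <- distractor_mask[sl, sy, sx, drop = FALSE]
      dm[sheets] <- TRUE
      distractor_mask[sl, sy, sx] <- dm
      mm <- myelin_mask[sl, sy, sx, drop = FALSE]
      mm[sheets] <- TRUE
      myelin_mask[sl, sy, sx] <- mm
    }
  }

  # (4) noise, clamped to the 8-bit-like range
  vol <- vol + stats::rnorm(n, 0, cfg$noise_sigma)
  vol[vol < 0] <- 0
  vol[vol > 255] <- 255

  gold <- if (placed > 0L)
    ball_annotations(placements$z, placements$y, placements$x,
                     placements$radius_vox)
  else ball_annotations()
  structure(list(volume = em_volume(vol),
                 gold_balls = gold,
                 synapse_mask = synapse_mask,
                 membrane_mask = membrane_mask,
                 distractor_mask = distractor_mask,
                 myelin_mask = myelin_mask,
                 placements = placements %||%
                   data.frame(z = numeric(), y = numeric(), x = numeric(),
                              radius_vox = numeric(),
                              thickness_vox = numeric(),
                              orientation = character(),
                              nz = numeric(), ny = numeric(), nx = numeric()),
                 synapse_voxels = synapse_voxels,
                 config = cfg),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  d <- dim(x$volume$data)
  cat(sprintf("synthetic_scene: %d x %d x %d voxels, %d synapse(s), %d distractor voxel(s)\n",
              d[1], d[2], d[3], nrow(x$gold_balls), sum(x$distractor_mask)))
  invisible(x)
}

# compact brush stroke: up to `len` mask voxels in the slice of `seed`,
# nearest first (Chebyshev <= 4 in-plane)
stroke_from_mask <- function(mask_coords, seed_row, len = 8L) {
  sl <- mask_coords[mask_coords[, 1] == seed_row[1], , drop = FALSE]
  ch <- pmax(abs(sl[, 2] - seed_row[2]), abs(sl[, 3] - seed_row[3]))
  sl <- sl[ch <= 4, , drop = FALSE]
  sl[order(pmax(abs(sl[, 2] - seed_row[2]), abs(sl[, 3] - seed_row[3])))[
    seq_len(min(len, nrow(sl)))], , drop = FALSE]
}

#' Sample sparse brush-stroke training labels from a scene
#'
#' Emulates interactive labelling: short single-slice strokes of class
#' 1 inside synaptic densities (cycling through the planted synapses),
#' class 2 on membranes, and class 3 in the rest — stratified over
#' plain background, mitochondria interiors and myelin sheets, so the
#' classifier sees every known false-positive source as "rest". The
#' labelled fraction stays far below 1% of the volume.
#'
#' @param scene A `synthetic_scene` with at least one synapse.
#' @param strokes_per_class Strokes per class (default 7; each stroke
#'   has up to 8 voxels).
#' @param seed RNG seed; labels are deterministic given it.
#' @return A [sparse_labels] object.
#' @export
make_training_labels <- function(scene, strokes_per_class = 7L, seed = 0L) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (length(scene$synapse_voxels) == 0L)
    stop("scene has no synapses to sample class 1 from")
  set.seed(seed)
  d <- dim(scene$volume$data)
  coords <- NULL; cls <- integer()
  add <- function(stroke, k) {
    if (nrow(stroke) > 0L) {
      coords <<- rbind(coords, stroke)
      cls <<- c(cls, rep(k, nrow(stroke)))
    }
  }
  # class 1: synaptic densities, visiting synapses in random order so
  # the labelled subset is not biased toward any placement order
  syn_order <- sample(length(scene$synapse_voxels))
  for (j in seq_len(strokes_per_class)) {
    sv <- scene$synapse_voxels[[syn_order[((j - 1L) %% length(syn_order)) + 1L]]]
    add(stroke_from_mask(sv, sv[sample(nrow(sv), 1), ]), 1L)
  }
  # class 2: membranes (excluding synapse voxels)
  mem <- which(scene$membrane_mask & !scene$synapse_mask)
  if (length(mem) == 0L) stop("scene has no membrane voxels")
  memc <- linear_to_coords(mem, d)
  for (j in seq_len(strokes_per_class)) {
    add(stroke_from_mask(memc, memc[sample(nrow(memc), 1), ]), 2L)
  }
  # class 3: stratified over plain background, mitochondria interiors
  # and myelin sheets, so every known false-positive source is
  # represented in the "rest" class
  bg <- which(!scene$membrane_mask & !scene$synapse_mask &
              !scene$distractor_mask)
  bgc <- linear_to_coords(bg, d)
  myel <- scene$myelin_mask %||% array(FALSE, dim = d)
  mito <- which(scene$distractor_mask & !myel)
  mitoc <- if (length(mito)) linear_to_coords(mito, d) else NULL
  myelc <- if (any(myel)) linear_to_coords(which(myel), d) else NULL
  for (j in seq_len(strokes_per_class)) {
    pick <- j %% 3L
    if (pick == 2L && !is.null(mitoc)) {
      add(stroke_from_mask(mitoc, mitoc[sample(nrow(mitoc), 1), ]), 3L)
    } else if (pick == 0L && !is.null(myelc)) {
      add(stroke_from_mask(myelc, myelc[sample(nrow(myelc), 1), ]), 3L)
    } else {
      s <- bgc[sample(nrow(bgc), 1), ]
      run <- cbind(z = rep(s[1], 8L), y = rep(s[2], 8L),
                   x = pmin(s[3] + 0:7, d[3] - 1L))
      keep <- !scene$membrane_mask[cbind(run[, 1] + 1L, run[, 2] + 1L,
                                         run[, 3] + 1L)] &
              !scene$synapse_mask[cbind(run[, 1] + 1L, run[, 2] + 1L,
                                        run[, 3] + 1L)]
      add(unique(run[keep, , drop = FALSE]), 3L)
    }
  }
  keep <- !duplicated(coords)
  sparse_labels(coords[keep, , drop = FALSE], cls[keep])
}

#' Persist a scene to a directory
#'
#' Writes `volume.h5`, `gold_balls.csv`, `synapse_mask.h5`,
#' `membrane_mask.h5`, `distractor_mask.h5` and `config.yaml` (an
#' exact echo of the scene config).
#'
#' @param scene A `synthetic_scene`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(scene$volume, file.path(dir, "volume.h5"))
  write_balls(scene$gold_balls, file.path(dir, "gold_balls.csv"))
  for (nm in c("synapse_mask", "membrane_mask", "distractor_mask",
               "myelin_mask")) {
    m <- scene[[nm]]
    storage.mode(m) <- "integer"
    write_volume(em_volume(m), file.path(dir, paste0(nm, ".h5")))
  }
  cfg <- scene$config
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Load a scene directory written by [write_scene()]
#'
#' Per-synapse voxel lists are reconstructed from the synapse mask's
#' connected components.
#'
#' @param dir Scene directory.
#' @return A `synthetic_scene` (without the `placements` table, which
#'   is not persisted).
#' @export
read_scene <- function(dir) {
  vol <- read_volume(file.path(dir, "volume.h5"))
  gold <- read_balls(file.path(dir, "gold_balls.csv"))
  mask_names <- c("synapse_mask", "membrane_mask", "distractor_mask",
                  "myelin_mask")
  masks <- lapply(mask_names, function(nm) {
    f <- file.path(dir, paste0(nm, ".h5"))
    if (!file.exists(f)) return(NULL)
    m <- read_volume(f)$data
    array(m != 0, dim = dim(m))
  })
  names(masks) <- mask_names
  cfgl <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg <- do.call(scene_config, cfgl[names(cfgl) %in% names(formals(scene_config))])
  d <- dim(vol$data)
  # one synapse = pre + post density sheets, which voxelize as up to
  # two mask components; group components by nearest gold ball
  lab <- label_components_cpp(masks$synapse_mask, d, 26L)
  ncomp <- max(lab)
  synapse_voxels <- NULL
  if (ncomp > 0L && nrow(gold) > 0L) {
    comp_coords <- lapply(seq_len(ncomp),
                          function(k) linear_to_coords(which(lab == k), d))
    owner <- vapply(comp_coords, function(cc) {
      ctr <- colMeans(cc)
      which.min((gold$z - ctr[1])^2 + (gold$y - ctr[2])^2 +
                (gold$x - ctr[3])^2)
    }, integer(1))
    synapse_voxels <- lapply(seq_len(nrow(gold)), function(b)
      do.call(rbind, comp_coords[owner == b]))
    synapse_voxels <- synapse_voxels[
      !vapply(synapse_voxels, is.null, logical(1))]
  }
  structure(list(volume = vol, gold_balls = gold,
                 synapse_mask = masks$synapse_mask,
                 membrane_mask = masks$membrane_mask,
                 distractor_mask = masks$distractor_mask,
                 myelin_mask = masks$myelin_mask %||%
                   array(FALSE, dim = dim(vol$data)),
                 placements = NULL,
                 synapse_voxels = synapse_voxels %||% list(),
                 config = cfg),
            class = "synthetic_scene")
}
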