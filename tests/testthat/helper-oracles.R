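# Shared fixtures and independent oracles. Everything here is written
# deliberately naively (dense loops, repeated scans) so it cannot share
# a defect with the implementation it checks.

# coordinate ramp volumes, 0-based, (z, y, x) order
coord_arrays <- function(d) {
  list(z = array(rep(0:(d[1] - 1), times = d[2] * d[3]), d),
       y = array(rep(rep(0:(d[2] - 1), each = d[1]), times = d[3]), d),
       x = array(rep(0:(d[3] - 1), each = d[1] * d[2]), d))
}

# interior sub-array at least `m` voxels from every face (1-based)
interior <- function(a, m) {
  d <- dim(a)
  a[(m + 1):(d[1] - m), (m + 1):(d[2] - m), (m + 1):(d[3] - m)]
}

# dense direct 3D convolution with a separable Gaussian kernel,
# reflective boundary; O(n * k^3), for tiny volumes only
dense_gaussian_oracle <- function(a, sigma) {
  h <- max(1L, as.integer(ceiling(4 * sigma)))
  off <- -h:h
  k1 <- exp(-off^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  d <- dim(a)
  refl <- function(p, n) {
    while (p < 1 || p > n) p <- if (p < 1) 1 - p else 2 * n + 1 - p
    p
  }
  out <- array(0, d)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    s <- 0
    for (i in seq_along(off)) for (j in seq_along(off)) for (l in seq_along(off)) {
      s <- s + k1[i] * k1[j] * k1[l] *
        a[refl(z + off[i], d[1]), refl(y + off[j], d[2]), refl(x + off[l], d[3])]
    }
    out[z, y, x] <- s
  }
  out
}

# brute-force connected component labelling by breadth-first frontier
# expansion over an explicit neighbour table (vectorized per frontier)
flood_fill_oracle <- function(mask, connectivity) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0 &
               rowSums(abs(offs)) <= c("6" = 1, "18" = 2, "26" = 3)[
                 as.character(connectivity)], ]
  lin_of <- function(z, y, x) z + (y - 1) * d[1] + (x - 1) * d[1] * d[2]
  for (i in which(mask)) {
    if (lab[i] != 0L) next
    nxt <- nxt + 1L
    lab[i] <- nxt
    frontier <- i
    while (length(frontier)) {
      fz <- (frontier - 1) %% d[1] + 1
      fy <- ((frontier - 1) %/% d[1]) %% d[2] + 1
      fx <- (frontier - 1) %/% (d[1] * d[2]) + 1
      nbrs <- integer()
      for (r in seq_len(nrow(offs))) {
        nz <- fz + offs$dz[r]; ny <- fy + offs$dy[r]; nx <- fx + offs$dx[r]
        ok <- nz >= 1 & nz <= d[1] & ny >= 1 & ny <= d[2] &
              nx >= 1 & nx <= d[3]
        nbrs <- c(nbrs, lin_of(nz[ok], ny[ok], nx[ok]))
      }
      nbrs <- unique(nbrs[mask[nbrs] & lab[nbrs] == 0L])
      lab[nbrs] <- nxt
      frontier <- nbrs
    }
  }
  lab
}

# partition equality of two labellings (same components, any label ids)
same_partition <- function(a, b) {
  if (!identical(a > 0, b > 0)) return(FALSE)
  fg <- which(a > 0)
  length(unique(paste(a[fg], b[fg]))) ==
    length(unique(a[fg])) &&
    length(unique(a[fg])) == length(unique(b[fg]))
}

# independent implementation of the sequential matching protocol with
# removal semantics: candidates by descending size, nearest-centroid
# overlapping unclaimed ball, ties to the lower index
sequential_match_oracle <- function(sizes, centroids, overlap, balls) {
  claimed <- rep(FALSE, nrow(balls))
  tp <- 0L
  for (i in order(sizes, decreasing = TRUE)) {
    best <- NA; bestd <- Inf
    for (b in seq_len(nrow(balls))) {
      if (claimed[b] || !overlap[i, b]) next
      dd <- sum((centroids[i, ] - c(balls$z[b], balls$y[b], balls$x[b]))^2)
      if (dd < bestd) { bestd <- dd; best <- b }
    }
    if (!is.na(best)) { claimed[best] <- TRUE; tp <- tp + 1L }
  }
  list(tp = tp, fp = length(sizes) - tp, fn = nrow(balls) - tp)
}

# build a synapse_candidate directly from a voxel coordinate matrix
fake_candidate <- function(id, vox, core = vox, probs = rep(0.99, nrow(vox))) {
  emsynapse:::new_candidate(id, core, vox, probs)
}

# a small probability map with a synapse channel given as a 3D array
prob_from_synapse <- function(psyn) {
  probability_map(array(c(psyn, 1 - psyn), dim = c(dim(psyn), 2)),
                  c("synapse", "rest"))
}

# axis-aligned box of voxels as a 0-based coordinate matrix
box_vox <- function(z, y, x) {
  as.matrix(expand.grid(z = z, y = y, x = x))
}

small_scene_config <- function(seed = 7, ...) {
  scene_config(shape = c(48L, 96L, 96L), n_synapses = 3L,
               n_mitochondria = 2L, membrane_cells = 10L,
               synapse_radius_vox = c(7, 10), myelin = FALSE,
               seed = seed, ...)
}
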