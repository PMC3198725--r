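## 3D geometric feature bank.
##
## All filters are separable Gaussian(-derivative) convolutions with
## reflective boundary handling, applied with the same sigma (in voxel
## units) on all three axes: the near-isotropic z-resolution of FIB/SEM
## stacks lets the data be treated as one 3D volume. Kernels are
## truncated at 4*sigma and renormalized so that polynomial inputs give
## their analytic responses at interior voxels (sum 1 for smoothing,
## exact unit response to a ramp for first derivatives, exact response
## 2 to x^2 for second derivatives).

kernel_radius <- function(sigma) max(1L, as.integer(ceiling(4 * sigma)))

gaussian_kernel <- function(sigma) {
  h <- kernel_radius(sigma)
  d <- -h:h
  k <- exp(-d^2 / (2 * sigma^2))
  k / sum(k)
}

# first-derivative kernel: correlation weights, positive response to an
# increasing ramp; sum 0, sum(d * k) = 1
gaussian_deriv1_kernel <- function(sigma) {
  h <- kernel_radius(sigma)
  d <- -h:h
  k <- d * exp(-d^2 / (2 * sigma^2))
  k / sum(d * k)
}

# second-derivative kernel: sum 0 and sum(d^2 * k) = 2, so the response
# to f = x^2 is exactly 2 at interior voxels
gaussian_deriv2_kernel <- function(sigma) {
  h <- kernel_radius(sigma)
  d <- -h:h
  g <- exp(-d^2 / (2 * sigma^2))
  k <- (d^2 / sigma^2 - 1) * g
  k <- k - mean(k)
  k * (2 / sum(d^2 * k))
}

as_vol_array <- function(vol) {
  if (inherits(vol, "em_volume")) vol$data else vol
}

wrap_like <- function(result, vol) {
  if (inherits(vol, "em_volume")) em_volume(result, vol$spacing_nm) else result
}

# separable correlation: orders[a] in 0 (smooth), 1, 2 per axis (z,y,x)
sep_filter <- function(a, sigma, orders = c(0, 0, 0)) {
  d <- dim(a)
  out <- as.numeric(a)
  for (axis in 1:3) {
    k <- switch(orders[axis] + 1L,
                gaussian_kernel(sigma),
                gaussian_deriv1_kernel(sigma),
                gaussian_deriv2_kernel(sigma))
    out <- conv3d_axis(out, d, k, axis - 1L)
  }
  array(out, dim = d)
}

check_sigma <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("`sigma` must be a single positive number")
}

#' Gaussian smoothing of a volume
#'
#' Isotropic 3D Gaussian convolution at scale `sigma` (voxel units),
#' reflective boundaries, kernel truncated at `4*sigma`.
#'
#' @param vol An [em_volume] or 3D array.
#' @param sigma Standard deviation in voxels, > 0.
#' @return Smoothed volume of the same type and shape.
#' @export
gaussian_smooth <- function(vol, sigma) {
  check_sigma(sigma)
  wrap_like(sep_filter(as_vol_array(vol), sigma), vol)
}

#' Gradient magnitude at scale sigma
#'
#' Euclidean norm of the three Gaussian first-derivative responses.
#'
#' @inheritParams gaussian_smooth
#' @return Non-negative volume of the same shape.
#' @export
gradient_magnitude <- function(vol, sigma) {
  check_sigma(sigma)
  a <- as_vol_array(vol)
  gz <- sep_filter(a, sigma, c(1, 0, 0))
  gy <- sep_filter(a, sigma, c(0, 1, 0))
  gx <- sep_filter(a, sigma, c(0, 0, 1))
  wrap_like(sqrt(gz^2 + gy^2 + gx^2), vol)
}

#' Laplacian of Gaussian at scale sigma
#'
#' Sum of the three unmixed Gaussian second derivatives.
#'
#' @inheritParams gaussian_smooth
#' @return Volume of the same shape.
#' @export
laplacian_of_gaussian <- function(vol, sigma) {
  check_sigma(sigma)
  a <- as_vol_array(vol)
  r <- sep_filter(a, sigma, c(2, 0, 0)) +
       sep_filter(a, sigma, c(0, 2, 0)) +
       sep_filter(a, sigma, c(0, 0, 2))
  wrap_like(r, vol)
}

#' Difference of Gaussians at scale sigma
#'
#' `gaussian_smooth(vol, sigma) - gaussian_smooth(vol, 0.66 * sigma)`;
#' the second (narrower) sigma is fixed at `0.66 * sigma`.
#'
#' @inheritParams gaussian_smooth
#' @return Volume of the same shape.
#' @export
difference_of_gaussians <- function(vol, sigma) {
  check_sigma(sigma)
  a <- as_vol_array(vol)
  wrap_like(sep_filter(a, sigma) - sep_filter(a, 0.66 * sigma), vol)
}

#' Eigenvalues of the Hessian matrix at scale sigma
#'
#' Per voxel, the eigenvalues of the 3x3 matrix of Gaussian
#' second-derivative responses, sorted descending by signed value.
#'
#' @inheritParams gaussian_smooth
#' @return 4D array `(z, y, x, 3)`: channels are the sorted
#'   eigenvalues.
#' @export
hessian_eigenvalues <- function(vol, sigma) {
  check_sigma(sigma)
  a <- as_vol_array(vol)
  d <- dim(a)
  hzz <- sep_filter(a, sigma, c(2, 0, 0))
  hyy <- sep_filter(a, sigma, c(0, 2, 0))
  hxx <- sep_filter(a, sigma, c(0, 0, 2))
  hzy <- sep_filter(a, sigma, c(1, 1, 0))
  hzx <- sep_filter(a, sigma, c(1, 0, 1))
  hyx <- sep_filter(a, sigma, c(0, 1, 1))
  ev <- eig3_sym_desc(as.numeric(hzz), as.numeric(hyy), as.numeric(hxx),
                      as.numeric(hzy), as.numeric(hzx), as.numeric(hyx))
  array(ev, dim = c(d, 3L))
}

#' Eigenvalues of the structure tensor at scale sigma
#'
#' The gradient is taken at the inner scale `sigma / 2`; its outer
#' product is then smoothed component-wise at the listed (outer,
#' integration) scale `sigma`. Eigenvalues are sorted descending and
#' are non-negative up to numerical tolerance (the tensor is positive
#' semidefinite).
#'
#' @inheritParams gaussian_smooth
#' @return 4D array `(z, y, x, 3)`.
#' @export
structure_tensor_eigenvalues <- function(vol, sigma) {
  check_sigma(sigma)
  a <- as_vol_array(vol)
  d <- dim(a)
  si <- sigma / 2
  gz <- sep_filter(a, si, c(1, 0, 0))
  gy <- sep_filter(a, si, c(0, 1, 0))
  gx <- sep_filter(a, si, c(0, 0, 1))
  tzz <- sep_filter(gz * gz, sigma)
  tyy <- sep_filter(gy * gy, sigma)
  txx <- sep_filter(gx * gx, sigma)
  tzy <- sep_filter(gz * gy, sigma)
  tzx <- sep_filter(gz * gx, sigma)
  tyx <- sep_filter(gy * gx, sigma)
  ev <- eig3_sym_desc(as.numeric(tzz), as.numeric(tyy), as.numeric(txx),
                      as.numeric(tzy), as.numeric(tzx), as.numeric(tyx))
  ev[ev < 0] <- 0  # PSD by construction; negatives are rounding error
  array(ev, dim = c(d, 3L))
}

# spatial reach of a filter's kernels in voxels: single-stage filters
# truncate at 4*sigma; the structure tensor cascades a gradient at
# sigma/2 (reach 2*sigma) into a smoothing at sigma (reach 4*sigma)
filter_reach <- function(filter_name, sigma) {
  if (filter_name == "structure_tensor_eigenvalues")
    ceiling(4 * sigma + 4 * sigma / 2)
  else ceiling(4 * sigma)
}

#' Halo width needed for exact blockwise feature computation
#' @param spec A [feature_spec].
#' @return Integer halo in voxels: the maximum spatial reach over all
#'   filters, so block-interior responses equal the whole-volume ones.
#' @export
feature_halo <- function(spec) {
  as.integer(max(mapply(filter_reach, spec$filter, spec$sigma)))
}

filter_channels <- function(filter_name) {
  if (filter_name %in% c("hessian_eigenvalues",
                         "structure_tensor_eigenvalues")) 3L else 1L
}

FILTER_NAMES <- c("gaussian", "gradient_magnitude", "laplacian",
                  "difference_of_gaussians", "hessian_eigenvalues",
                  "structure_tensor_eigenvalues")

#' Feature bank specification
#'
#' An ordered list of `(filter, sigma)` pairs defining the per-voxel
#' feature channels. The eigenvalue filters contribute 3 channels each,
#' all others 1. Derived-scale rules are fixed: the structure tensor's
#' second (inner) scale is `sigma/2` and the difference-of-Gaussians
#' second sigma is `0.66*sigma`.
#'
#' @param filter Character vector of filter names, each one of
#'   gaussian, gradient_magnitude, laplacian, difference_of_gaussians,
#'   hessian_eigenvalues, structure_tensor_eigenvalues.
#' @param sigma Numeric vector of scales (voxel units), same length.
#' @return A `data.frame` of class `feature_spec` with columns
#'   `filter`, `sigma`.
#' @export
feature_spec <- function(filter, sigma) {
  filter <- as.character(filter)
  sigma <- as.numeric(sigma)
  if (length(filter) == 0L) stop("feature spec must not be empty")
  if (length(filter) != length(sigma)) stop("filter/sigma length mismatch")
  bad <- setdiff(filter, FILTER_NAMES)
  if (length(bad)) stop("unknown filter(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("all sigmas must be positive")
  structure(data.frame(filter = filter, sigma = sigma,
                       stringsAsFactors = FALSE),
            class = c("feature_spec", "data.frame"))
}

#' Default 38-channel feature specification
#'
#' The standard bank: Hessian eigenvalues and structure-tensor
#' eigenvalues at sigma 1, 1.6, 3.5, 5 (3 channels each), Gaussian
#' intensity at 0.7, 1, 1.6, 3.5, 5, and gradient magnitude, Laplacian
#' and difference of Gaussians at 1.6, 3.5, 5 — 38 channels in total.
#'
#' @return A [feature_spec] with 24 entries / 38 channels.
#' @export
default_feature_spec <- function() {
  s4 <- c(1, 1.6, 3.5, 5)
  s5 <- c(0.7, 1, 1.6, 3.5, 5)
  s3 <- c(1.6, 3.5, 5)
  feature_spec(
    filter = c(rep("hessian_eigenvalues", 4),
               rep("structure_tensor_eigenvalues", 4),
               rep("gaussian", 5),
               rep("gradient_magnitude", 3),
               rep("laplacian", 3),
               rep("difference_of_gaussians", 3)),
    sigma  = c(s4, s4, s5, s3, s3, s3))
}

#' Total channel count of a feature spec
#' @param spec A [feature_spec].
#' @return Integer channel count (38 for the default spec).
#' @export
n_channels <- function(spec) {
  sum(vapply(spec$filter, filter_channels, integer(1)))
}

#' Channel names of a feature spec
#' @param spec A [feature_spec].
#' @return Character vector, one name per channel, encoding filter,
#'   sigma and (for eigenvalue filters) the eigenvalue index.
#' @export
feature_channel_names <- function(spec) {
  unlist(lapply(seq_len(nrow(spec)), function(i) {
    f <- spec$filter[i]; s <- spec$sigma[i]
    if (filter_channels(f) == 3L) sprintf("%s_s%g_ev%d", f, s, 1:3)
    else sprintf("%s_s%g", f, s)
  }), use.names = FALSE)
}

apply_filter <- function(vol, filter, sigma) {
  switch(filter,
         gaussian = as_vol_array(gaussian_smooth(vol, sigma)),
         gradient_magnitude = as_vol_array(gradient_magnitude(vol, sigma)),
         laplacian = as_vol_array(laplacian_of_gaussian(vol, sigma)),
         difference_of_gaussians = as_vol_array(difference_of_gaussians(vol, sigma)),
         hessian_eigenvalues = hessian_eigenvalues(vol, sigma),
         structure_tensor_eigenvalues = structure_tensor_eigenvalues(vol, sigma),
         stop("unknown filter: ", filter))
}

#' Compute the per-voxel feature stack
#'
#' Applies every filter of the spec to the volume and assembles a
#' voxel-major feature matrix (one row per voxel in array order, one
#' column per channel), in spec order. Filters act independently; there
#' is no cross-channel coupling. A warning is issued when any spatial
#' dimension is smaller than `4 * max(sigma) + 1`, where boundary
#' reflection degrades the features of every voxel.
#'
#' @param vol An [em_volume] or 3D array.
#' @param spec A [feature_spec]; default [default_feature_spec()].
#' @return An object of class `feature_stack`: list with `values`
#'   (`n_voxels x n_channels` matrix), `shape`, `channel_names`.
#' @export
compute_feature_stack <- function(vol, spec = default_feature_spec()) {
  if (!inherits(spec, "feature_spec") || nrow(spec) == 0L)
    stop("`spec` must be a non-empty feature_spec")
  a <- as_vol_array(vol)
  d <- dim(a)
  mind <- 4 * max(spec$sigma) + 1
  if (any(d < mind))
    warning("volume dimensions ", paste(d, collapse = "x"),
            " are below the recommended ", ceiling(mind),
            " for max sigma ", max(spec$sigma),
            "; boundary reflection affects all voxels")
  nch <- n_channels(spec)
  values <- matrix(0, nrow = prod(d), ncol = nch)
  col <- 1L
  for (i in seq_len(nrow(spec))) {
    r <- apply_filter(a, spec$filter[i], spec$sigma[i])
    k <- filter_channels(spec$filter[i])
    if (k == 1L) {
      values[, col] <- as.numeric(r)
    } else {
      nv <- prod(d)
      rm_ <- matrix(as.numeric(r), nrow = nv, ncol = 3L)
      values[, col:(col + 2L)] <- rm_
    }
    col <- col + k
  }
  if (any(!is.finite(values))) stop("non-finite feature values produced")
  structure(list(values = values, shape = d,
                 channel_names = feature_channel_names(spec)),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("feature_stack: %d channels over %s voxels (shape %s)\n",
              ncol(x$values), format(nrow(x$values), big.mark = ","),
              paste(x$shape, collapse = " x ")))
  invisible(x)
}

#' Extract one feature channel as a 3D array
#' @param stack A `feature_stack`.
#' @param channel Channel name or index.
#' @return 3D array of the channel, in volume shape.
#' @export
feature_channel <- function(stack, channel) {
  if (is.character(channel)) channel <- match(channel, stack$channel_names)
  if (is.na(channel) || channel < 1 || channel > ncol(stack$values))
    stop("unknown channel")
  array(stack$values[, channel], dim = stack$shape)
}

#' Save a feature stack to HDF5
#' @param stack A `feature_stack`.
#' @param path Output `.h5` path.
#' @return Invisibly, `path`.
#' @export
write_feature_stack <- function(stack, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(stack$values, path, "features")
  rhdf5::h5write(as.integer(stack$shape), path, "shape")
  rhdf5::h5write(stack$channel_names, path, "channel_names")
  invisible(path)
}

#' Load a feature stack from HDF5
#' @param path `.h5` file written by [write_feature_stack()].
#' @return A `feature_stack`.
#' @export
read_feature_stack <- function(path) {
  structure(list(values = rhdf5::h5read(path, "features"),
                 shape = as.integer(rhdf5::h5read(path, "shape")),
                 channel_names = as.character(rhdf5::h5read(path, "channel_names"))),
            class = "feature_stack")
}

#' Serialize a feature spec to a plain list (for YAML configs)
#' @param spec A [feature_spec].
#' @return List of `{filter, sigma}` records.
#' @export
feature_spec_to_list <- function(spec) {
  lapply(seq_len(nrow(spec)),
         function(i) list(filter = spec$filter[i], sigma = spec$sigma[i]))
}

#' Deserialize a feature spec from a plain list
#' @param x List of `{filter, sigma}` records.
#' @return A [feature_spec].
#' @export
feature_spec_from_list <- function(x) {
  feature_spec(vapply(x, function(e) e$filter, character(1)),
               vapply(x, function(e) as.numeric(e$sigma), numeric(1)))
}
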