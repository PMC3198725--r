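d33 <- c(33L, 33L, 33L)

test_that("the default feature spec reproduces the 38-channel bank", {
  spec <- default_feature_spec()
  expect_equal(n_channels(spec), 38L)
  nms <- feature_channel_names(spec)
  expect_length(nms, 38L)
  # first 12 channels: Hessian eigenvalues, 3 per sigma over 4 sigmas
  expect_true(all(grepl("^hessian_eigenvalues", nms[1:12])))
  expect_true(all(grepl("^structure_tensor_eigenvalues", nms[13:24])))
  expect_true(all(grepl("^gaussian_s", nms[25:29])))
  expect_equal(spec$sigma[spec$filter == "gaussian"], c(0.7, 1, 1.6, 3.5, 5))
})

test_that("constant volumes map to themselves (gaussian) or zero (others)", {
  cv <- array(7, dim = c(16, 16, 16))
  expect_equal(max(abs(gaussian_smooth(cv, 1.6) - 7)), 0, tolerance = 1e-12)
  expect_equal(max(abs(gradient_magnitude(cv, 1.6))), 0, tolerance = 1e-12)
  expect_equal(max(abs(laplacian_of_gaussian(cv, 1.6))), 0, tolerance = 1e-12)
  expect_equal(max(abs(difference_of_gaussians(cv, 1.6))), 0, tolerance = 1e-10)
  expect_equal(max(abs(hessian_eigenvalues(cv, 1.6))), 0, tolerance = 1e-11)
  expect_equal(max(abs(structure_tensor_eigenvalues(cv, 1.6))), 0,
               tolerance = 1e-12)
})

test_that("gaussian smoothing preserves kernel mass and affine ramps", {
  im <- array(0, d33); im[17, 17, 17] <- 1
  expect_equal(sum(gaussian_smooth(im, 1.6)), 1, tolerance = 1e-6)
  g <- coord_arrays(d33)
  sm <- gaussian_smooth(3 * g$x, 1)
  expect_equal(interior(sm, 8), interior(3 * g$x, 8), tolerance = 1e-4)
})

test_that("gradient magnitude matches analytic ramps", {
  g <- coord_arrays(d33)
  gm <- gradient_magnitude(2 * g$x, 1.6)
  expect_equal(max(abs(interior(gm, 10) - 2)), 0, tolerance = 1e-3)
  gm2 <- gradient_magnitude(2 * g$x + 2 * g$y, 1.6)
  expect_equal(max(abs(interior(gm2, 10) - 2 * sqrt(2))), 0, tolerance = 1e-3)
})

test_that("laplacian of gaussian matches analytic quadratics", {
  g <- coord_arrays(d33)
  lg <- laplacian_of_gaussian(g$x^2, 2)
  expect_equal(max(abs(interior(lg, 11) - 2)), 0, tolerance = 1e-3)
  lg3 <- laplacian_of_gaussian(g$x^2 + g$y^2 + g$z^2, 2)
  expect_equal(max(abs(interior(lg3, 11) - 6)), 0, tolerance = 1e-2)
})

test_that("difference of gaussians is the definitional subtraction", {
  set.seed(3)
  a <- array(rnorm(16^3), dim = c(16, 16, 16))
  expect_equal(difference_of_gaussians(a, 3.5),
               gaussian_smooth(a, 3.5) - gaussian_smooth(a, 0.66 * 3.5),
               tolerance = 1e-10)
  im <- array(0, d33); im[17, 17, 17] <- 1
  dg <- difference_of_gaussians(im, 3.5)
  expect_lt(dg[17, 17, 17], 0)  # narrower kernel has the higher peak
})

test_that("hessian eigenvalues match the analytic quadratic and sort descending", {
  g <- coord_arrays(d33)
  ev <- hessian_eigenvalues(g$x^2 + 2 * g$y^2 + 3 * g$z^2, 2)
  ctr <- ev[17, 17, 17, ]
  expect_equal(ctr, c(6, 4, 2), tolerance = 1e-2)
  expect_true(all(ev[, , , 1] >= ev[, , , 2] - 1e-12))
  expect_true(all(ev[, , , 2] >= ev[, , , 3] - 1e-12))
})

test_that("eigenvalue channels are equivariant under axis permutation", {
  set.seed(4)
  a <- array(rnorm(14^3), dim = c(14, 14, 14))
  p <- aperm(a, c(2, 3, 1))
  for (f in c(hessian_eigenvalues, structure_tensor_eigenvalues)) {
    ev_a <- f(a, 1.6)
    ev_p <- f(p, 1.6)
    for (k in 1:3)
      expect_equal(aperm(ev_a[, , , k], c(2, 3, 1)), ev_p[, , , k],
                   tolerance = 1e-8)
  }
})

test_that("structure tensor of a ramp is rank one and PSD", {
  g <- coord_arrays(d33)
  a <- 3
  ev <- structure_tensor_eigenvalues(a * g$x, 2)
  ctr <- interior(ev[, , , 1], 12)
  expect_equal(max(abs(ctr - a^2)), 0, tolerance = 1e-3 * a^2)
  expect_equal(max(abs(interior(ev[, , , 2], 12))), 0, tolerance = 1e-3 * a^2)
  set.seed(5)
  r <- array(rnorm(12^3), dim = c(12, 12, 12))
  expect_true(min(structure_tensor_eigenvalues(r, 1.6)) >= 0)
})

test_that("separable filtering matches a dense convolution oracle", {
  set.seed(6)
  a <- array(rnorm(12^3), dim = c(12, 12, 12))
  sep <- gaussian_smooth(a, 1.2)
  dense <- dense_gaussian_oracle(a, 1.2)
  expect_equal(sep, dense, tolerance = 1e-6)
})

test_that("compute_feature_stack assembles channels independently and in order", {
  set.seed(7)
  vol <- em_volume(array(rnorm(32^3, 128, 30), dim = c(32, 32, 32)))
  stack <- compute_feature_stack(vol)
  expect_equal(ncol(stack$values), 38L)
  expect_equal(stack$shape, c(32L, 32L, 32L))
  expect_true(all(is.finite(stack$values)))
  # single-entry spec equals the filter applied directly
  s1 <- compute_feature_stack(vol, feature_spec("gaussian", 1))
  expect_equal(array(s1$values[, 1], dim = stack$shape),
               gaussian_smooth(vol, 1)$data)
  # an eigenvalue entry occupies three aligned columns
  sh <- compute_feature_stack(vol, feature_spec("hessian_eigenvalues", 1.6))
  hev <- hessian_eigenvalues(vol, 1.6)
  for (k in 1:3)
    expect_equal(array(sh$values[, k], dim = stack$shape), hev[, , , k])
})

test_that("feature stacks round-trip through HDF5", {
  set.seed(8)
  vol <- em_volume(array(rnorm(8^3), dim = c(8, 8, 8)))
  stack <- compute_feature_stack(vol, feature_spec(c("gaussian", "laplacian"),
                                                   c(1, 1.6)))
  path <- file.path(tempdir(), "stack.h5")
  write_feature_stack(stack, path)
  back <- read_feature_stack(path)
  expect_equal(back$values, stack$values, ignore_attr = TRUE)
  expect_identical(back$channel_names, stack$channel_names)
})

test_that("invalid scales and specs are rejected", {
  a <- array(0, dim = c(4, 4, 4))
  expect_error(gaussian_smooth(a, 0), "positive")
  expect_error(gradient_magnitude(a, -1), "positive")
  expect_error(feature_spec(character(), numeric()), "empty")
  expect_error(feature_spec("gaussian", 0), "positive")
  expect_error(feature_spec("unknown_filter", 1), "unknown")
})

test_that("feature specs serialize to plain lists and back", {
  spec <- default_feature_spec()
  expect_equal(feature_spec_from_list(feature_spec_to_list(spec)), spec)
})
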