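# two well-separated gaussian clusters in feature space, laid out as a
# pseudo-volume so stacks and labels can address them by coordinate
make_cluster_stack <- function(n_per = 100, n_feat = 6, sep = 10, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * n_feat, 0, 1), n_per),
             matrix(rnorm(n_per * n_feat, sep, 1), n_per))
  stack <- structure(list(values = x, shape = c(2L * n_per, 1L, 1L),
                          channel_names = paste0("f", seq_len(n_feat))),
                     class = "feature_stack")
  labels <- sparse_labels(cbind(0:(2 * n_per - 1), 0L, 0L),
                          rep(1:2, each = n_per),
                          class_names = c("synapse", "rest"))
  list(stack = stack, labels = labels)
}

test_that("the training matrix aligns rows with labelled voxels", {
  set.seed(9)
  vol <- em_volume(array(rnorm(16^3), dim = c(16, 16, 16)))
  stack <- compute_feature_stack(vol, feature_spec(c("gaussian", "laplacian"),
                                                   c(1, 1)))
  lab <- sparse_labels(cbind(sample(0:15, 20, TRUE), sample(0:15, 20, TRUE),
                             sample(0:15, 20, TRUE)),
                       rep(1:3, length.out = 20))
  lab$coords <- unique(lab$coords)
  lab$class_id <- lab$class_id[seq_len(nrow(lab$coords))]
  tm <- extract_training_matrix(stack, lab)
  expect_equal(dim(tm$x), c(nrow(lab$coords), 2L))
  i <- 5L
  lin <- lab$coords[i, 1] + 16 * (lab$coords[i, 2] + 16 * lab$coords[i, 3]) + 1
  expect_equal(unname(tm$x[i, ]), unname(stack$values[lin, ]))
})

test_that("duplicate labels deduplicate and contradictions error", {
  cs <- make_cluster_stack()
  lab2 <- sparse_labels(rbind(cs$labels$coords, cs$labels$coords[1, ]),
                        c(cs$labels$class_id, 1L),
                        class_names = cs$labels$class_names)
  tm <- extract_training_matrix(cs$stack, lab2)
  expect_equal(nrow(tm$x), 200L)  # deduplicated
  bad <- sparse_labels(rbind(cs$labels$coords, cs$labels$coords[1, ]),
                       c(cs$labels$class_id, 2L),
                       class_names = cs$labels$class_names)
  expect_error(extract_training_matrix(cs$stack, bad), "contradictory")
})

test_that("training on separable clusters reaches near-oracle accuracy", {
  cs <- make_cluster_stack()
  model <- train_voxel_classifier(cs$stack, cs$labels,
                                  forest_config(seed = 0))
  # nearest-centroid oracle is essentially perfect on this geometry
  mu1 <- colMeans(cs$stack$values[1:100, ])
  mu2 <- colMeans(cs$stack$values[101:200, ])
  pred_oracle <- apply(cs$stack$values, 1, function(r)
    if (sum((r - mu1)^2) < sum((r - mu2)^2)) 1L else 2L)
  expect_gte(mean(pred_oracle == rep(1:2, each = 100)), 0.999)
  expect_gte(model$meta$oob_accuracy, 0.95)
  # probing a training voxel recovers its label with high confidence
  pm <- predict(model, cs$stack)
  expect_gte(pm$data[1, 1, 1, 1], 0.9)
  expect_gte(pm$data[150, 1, 1, 2], 0.9)
})

test_that("training and prediction are deterministic given the seed", {
  cs <- make_cluster_stack()
  m1 <- train_voxel_classifier(cs$stack, cs$labels, forest_config(seed = 3))
  m2 <- train_voxel_classifier(cs$stack, cs$labels, forest_config(seed = 3))
  expect_identical(predict(m1, cs$stack)$data, predict(m2, cs$stack)$data)
})

test_that("adding consistent training data does not degrade accuracy much", {
  small <- make_cluster_stack(n_per = 60, seed = 11)
  big <- make_cluster_stack(n_per = 120, seed = 11)
  m_small <- train_voxel_classifier(small$stack, small$labels,
                                    forest_config(seed = 1))
  m_big <- train_voxel_classifier(big$stack, big$labels,
                                  forest_config(seed = 1))
  expect_gte(m_big$meta$oob_accuracy, m_small$meta$oob_accuracy - 0.05)
})

test_that("degenerate training inputs error clearly", {
  cs <- make_cluster_stack()
  one <- sparse_labels(cs$labels$coords, rep(1L, 200),
                       class_names = c("synapse", "rest"))
  expect_error(train_voxel_classifier(cs$stack, one, forest_config()),
               "2 classes")
  expect_error(forest_config(n_trees = 0), ">= 1")
  expect_error(train_voxel_classifier(cs$stack, cs$labels,
                                      forest_config(mtry = 99)),
               "channel count")
})

test_that("prediction requires matching channels and normalizes votes", {
  cs <- make_cluster_stack()
  model <- train_voxel_classifier(cs$stack, cs$labels, forest_config(seed = 0))
  pm <- predict(model, cs$stack)
  sums <- apply(pm$data, 1:3, sum)
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-6)
  permuted <- cs$stack
  permuted$values <- permuted$values[, c(2, 1, 3:6)]
  permuted$channel_names <- permuted$channel_names[c(2, 1, 3:6)]
  expect_error(predict(model, permuted), "channels do not match")
})

test_that("models survive a save/load round trip", {
  cs <- make_cluster_stack()
  model <- train_voxel_classifier(cs$stack, cs$labels, forest_config(seed = 5))
  path <- file.path(tempdir(), "model.rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(predict(back, cs$stack)$data, predict(model, cs$stack)$data)
  expect_equal(back$meta$oob_accuracy, model$meta$oob_accuracy)
  saveRDS(list(format = "other"), path)
  expect_error(load_model(path), "not an emsynapse model")
})

test_that("blockwise prediction equals the whole-volume path", {
  set.seed(12)
  vol <- em_volume(array(rnorm(40^3, 128, 25), dim = c(40, 40, 40)))
  spec <- feature_spec(c("gaussian", "hessian_eigenvalues",
                         "structure_tensor_eigenvalues"), c(1, 1.6, 1.6))
  lab <- sparse_labels(cbind(sample(0:39, 60, TRUE), sample(0:39, 60, TRUE),
                             sample(0:39, 60, TRUE)),
                       rep(1:2, 30), class_names = c("synapse", "rest"))
  lab$coords <- lab$coords[!duplicated(lab$coords), ]
  lab$class_id <- lab$class_id[seq_len(nrow(lab$coords))]
  stack <- compute_feature_stack(vol, spec)
  model <- train_voxel_classifier(stack, lab, forest_config(seed = 2))
  whole <- predict(model, stack)
  for (bs in list(c(20, 20, 20), c(16, 16, 16), c(64, 64, 64))) {
    blocked <- predict_blockwise(model, vol, spec, bs)
    expect_equal(blocked$data, whole$data, tolerance = 1e-6)
  }
})

test_that("features computed at sparse coordinates match the full stack", {
  set.seed(13)
  vol <- em_volume(array(rnorm(24^3), dim = c(24, 24, 24)))
  spec <- feature_spec(c("gaussian", "structure_tensor_eigenvalues"),
                       c(1.6, 1))
  coords <- cbind(sample(0:23, 30, TRUE), sample(0:23, 30, TRUE),
                  sample(0:23, 30, TRUE))
  at <- compute_features_at(vol, spec, coords, block_shape = c(8, 8, 8))
  stack <- compute_feature_stack(vol, spec)
  lin <- coords[, 1] + 24 * (coords[, 2] + 24 * coords[, 3]) + 1
  expect_equal(unname(at), unname(stack$values[lin, ]), tolerance = 1e-10)
})
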