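test_that("brain-route binarization thresholds at the across-node average", {
  # one dominant node: mean = 2, only it exceeds the threshold
  row <- matrix(c(rep(1, 8), 10), nrow = 1)
  expect_equal(unname(as.matrix(binarize_brain_route(row))),
               matrix(c(rep(-1, 8), 1), nrow = 1))

  # all nodes identical at a time point: strict inequality gives all -1
  expect_equal(unname(as.matrix(binarize_brain_route(matrix(4, 1, 9)))),
               matrix(-1, 1, 9))

  # invariant to common positive rescaling of all columns
  X <- matrix(rnorm(20 * 9), 20, 9)
  expect_equal(binarize_brain_route(X), binarize_brain_route(3.7 * X))

  # per-node temporal-mean mode thresholds each column at its own mean
  Xc <- cbind(c(1, 3), matrix(0, 2, 8))
  alt <- binarize_brain_route(Xc, threshold_mode = "per_node_temporal_mean")
  expect_equal(alt[[1]], c(-1, 1))

  expect_error(binarize_brain_route(matrix(0, 5, 8)), "9 columns")
  bad <- matrix(0, 3, 9); bad[2, 4] <- NaN
  expect_error(binarize_brain_route(bad), "rows \\{2\\}, columns \\{4\\}")
})

test_that("brain route recovers latent states from low-noise observations", {
  latent <- as.matrix(sample_mem_series(random_params(9, seed = 4, range = 0.3),
                                        500, seed = 15))
  obs <- emit_continuous_observations(
    latent, nodes_per_cluster = 1, noise_sd = 0.1, seed = 16,
    gain_range = c(1, 1), offset_range = c(0, 0)
  )
  rec <- as.matrix(binarize_brain_route(obs$series))
  expect_gt(mean(rec == latent), 0.95)
})

test_that("iteration-window selection keeps the half-open range", {
  X <- matrix(seq_len(2e5 * 2), ncol = 2)
  w <- select_iteration_window(X, 1e4, 6e4)
  expect_equal(nrow(w), 5e4)
  expect_equal(w[[1]][1], X[1e4 + 1, 1])  # 0-based start is row 10001
  expect_equal(w[[1]][5e4], X[6e4, 1])

  Y <- matrix(rnorm(30), 10, 3)
  expect_equal(as.matrix(select_iteration_window(Y, 0, 10)), Y,
               ignore_attr = TRUE)
  expect_equal(nrow(select_iteration_window(Y, 4, 5)), 1)
  expect_error(select_iteration_window(Y, 5, 12), "within")
  expect_error(select_iteration_window(Y, 5, 5), "within")
})

test_that("k-means node clustering recovers the true column-to-cluster map", {
  latent <- as.matrix(sample_mem_series(make_regime_params("uniform_shallow", seed = 5),
                                        400, seed = 17))
  obs <- emit_continuous_observations(latent, nodes_per_cluster = 12,
                                      noise_sd = 0.1, seed = 18)
  cl <- cluster_nodes(obs$series, k = 9, seed = 19, restarts = 10)
  expect_equal(attr(cl, "k"), 9L)
  expect_equal(sort(unique(cl$cluster)), 1:9)
  m <- match_clusters(cl, obs$cluster_map$cluster)
  expect_gt(m$agreement, 0.95)

  # permuting the columns permutes the partition but not its structure
  perm <- withr::with_seed(20, sample(ncol(obs$series)))
  cl_p <- cluster_nodes(as.matrix(obs$series)[, perm], k = 9, seed = 19,
                        restarts = 10)
  agree <- match_clusters(cl_p$cluster, cl$cluster[perm])
  expect_equal(agree$agreement, 1)

  expect_error(cluster_nodes(matrix(rnorm(40), 10, 4), k = 9), "at least k")
  const <- cbind(matrix(rnorm(200), 20), rep(2, 20))
  expect_message(cluster_nodes(const, k = 3, seed = 1), "constant")
})

test_that("cluster reduction binarizes cluster means at their temporal average", {
  # a cluster with mean course (1, 2, 3): temporal average 2 -> (-1, -1, +1)
  X <- cbind(c(1, 2, 3), c(1, 2, 3), c(5, 5, 5))
  cl <- tibble::tibble(column = paste0("c", 1:3), cluster = c(1L, 1L, 2L))
  b <- reduce_and_binarize(X, cl)
  expect_equal(b$node_1, c(-1, -1, 1))
  # constant cluster course: strict inequality gives all -1
  expect_equal(b$node_2, c(-1, -1, -1))
  expect_equal(dim(as.matrix(b)), c(3L, 2L))
  expect_true(all(as.matrix(b) %in% c(-1, 1)))

  # invariant to positive rescaling of a cluster's columns
  X2 <- X; X2[, cl$cluster == 1] <- X2[, cl$cluster == 1] * 10
  expect_equal(reduce_and_binarize(X2, cl), b)

  expect_error(
    reduce_and_binarize(X, tibble::tibble(cluster = c(1L, 3L, 3L))), "1..k"
  )
})

test_that("noiseless emission composed with the hidden-state route is exact", {
  latent <- as.matrix(sample_mem_series(make_regime_params("polarized", seed = 6),
                                        300, seed = 21))
  obs <- emit_continuous_observations(
    latent, nodes_per_cluster = 4, noise_sd = 0, seed = 22,
    gain_range = c(1, 1), offset_range = c(0, 0)
  )
  cl <- cluster_nodes(obs$series, k = 9, seed = 23)
  b <- as.matrix(reduce_and_binarize(obs$series, cl))
  m <- match_clusters(cl, obs$cluster_map$cluster)
  expect_equal(m$agreement, 1)
  # reorder recovered nodes to latent order via the label mapping
  reorder <- order(m$mapping)
  expect_equal(unname(b[, reorder]), unname(latent))
})

test_that("per-layer preprocessing excludes layer 1 and annotates the rest", {
  latent <- as.matrix(sample_mem_series(make_regime_params("uniform_shallow", seed = 7),
                                        120, seed = 24))
  make_layer <- function(s) {
    emit_continuous_observations(latent, nodes_per_cluster = 3,
                                 noise_sd = 0.05, seed = s)$series
  }
  layers12 <- lapply(1:12, make_layer)
  out <- per_layer_series(layers12, k = 9, seed = 30)
  expect_length(out, 11)
  expect_equal(unname(sapply(out, attr, "layer")), 2:12)
  expect_named(out, paste0("layer_", 2:12))
  expect_true(all(sapply(out, function(b) all(as.matrix(b) %in% c(-1, 1)))))

  out2 <- per_layer_series(lapply(1:2, make_layer), k = 9, seed = 31)
  expect_length(out2, 1)
  expect_error(per_layer_series(layers12[1], k = 9), "at least 2 layers")
})
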