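test_that("size factors follow the geometric-mean formula exactly", {
  set.seed(4)
  M <- matrix(rlnorm(60 * 5, 5, 1), 60, 5,
              dimnames = list(NULL, paste0("m", 1:5)))
  norm <- size_factor_normalize(M)
  # direct formula recomputation
  tot <- rowSums(M)
  f_oracle <- tot / exp(mean(log(tot)))
  expect_equal(norm$factors, f_oracle, tolerance = 1e-12)
  expect_equal(norm$matrix, log1p(M / f_oracle), tolerance = 1e-12)
  # geometric mean of factors is 1 (exact)
  expect_equal(exp(mean(log(norm$factors))), 1, tolerance = 1e-12)
})

test_that("normalization is scale invariant and handles degenerate rows", {
  M <- matrix(rep(c(10, 20, 30), each = 8), 8, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  norm <- size_factor_normalize(M)
  expect_equal(norm$factors, rep(1, 8))
  expect_equal(norm$matrix, log1p(M), tolerance = 1e-12)

  # doubling one particle's markers raises its own factor by 2^((n-1)/n)
  # and every other factor by 2^(-1/n) (the geometric mean shifts); the
  # particle's normalized profile shape is unchanged (all markers scaled by
  # one common constant)
  M2 <- M; M2[3, ] <- 2 * M[3, ]
  n2 <- size_factor_normalize(M2)
  expect_equal(n2$factors[3] / norm$factors[3], 2^(7 / 8),
               tolerance = 1e-12)
  expect_equal(n2$factors[-3] / norm$factors[-3], rep(2^(-1 / 8), 7),
               tolerance = 1e-12)
  ratio <- expm1(n2$matrix[3, ]) / expm1(norm$matrix[3, ])
  expect_equal(unname(ratio), rep(2^(1 / 8), 3), tolerance = 1e-12)
  # global rescaling leaves the size factors unchanged (they are relative
  # to the geometric-mean total), so normalized values follow the formula
  # with the same factors
  n3 <- size_factor_normalize(M * 37)
  expect_equal(n3$factors, norm$factors, tolerance = 1e-12)
  expect_equal(n3$matrix, log1p(37 * M / norm$factors), tolerance = 1e-12)

  Mz <- rbind(M, 0)
  expect_warning(nz <- size_factor_normalize(Mz), "all-zero")
  expect_identical(nz$kept, 1:8)
})

test_that("PCA step matches an eigendecomposition oracle on a toy matrix", {
  X <- matrix(c(1, 2, 4, 2, 3, 7), 3, 2)
  model <- suppressWarnings(
    embed_landscape(X, n_neighbors = 2, seed = 0))
  # oracle: eigenvectors of the covariance matrix
  ev <- eigen(stats::cov(X))
  scores_oracle <- sweep(X, 2, colMeans(X)) %*% ev$vectors
  # same subspace: scores agree up to per-component sign
  pcs_raw <- sweep(X, 2, model$center) %*% model$rotation
  for (j in 1:2)
    expect_true(isTRUE(all.equal(pcs_raw[, j], scores_oracle[, j],
                                 tolerance = 1e-9)) ||
                isTRUE(all.equal(pcs_raw[, j], -scores_oracle[, j],
                                 tolerance = 1e-9)))
})

test_that("the batch aligner removes a constant batch offset exactly", {
  set.seed(9)
  base <- matrix(rnorm(200 * 4, 8, 1), 200, 4)
  shifted <- rbind(base, sweep(base, 2, c(2, -1, 0.5, 3), `+`))
  batch <- rep(1:2, each = 200)
  model <- embed_landscape(shifted, batch = batch, seed = 0)
  c1 <- colMeans(model$pcs[batch == 1, ])
  c2 <- colMeans(model$pcs[batch == 2, ])
  expect_lt(max(abs(c1 - c2)), 1e-9)
})

test_that("two separated blobs stay separated in the embedding", {
  set.seed(5)
  X <- rbind(matrix(rnorm(300 * 4, 0, 0.5), 300, 4),
             matrix(rnorm(300 * 4, 10, 0.5), 300, 4))
  model <- embed_landscape(X, seed = 0)
  lab <- rep(1:2, each = 300)
  mu1 <- colMeans(model$embedding[lab == 1, ])
  mu2 <- colMeans(model$embedding[lab == 2, ])
  between <- sqrt(sum((mu1 - mu2)^2))
  within <- mean(c(sqrt(rowSums(sweep(model$embedding[lab == 1, ], 2,
                                      mu1)^2)),
                   sqrt(rowSums(sweep(model$embedding[lab == 2, ], 2,
                                      mu2)^2))))
  expect_gt(between / within, 5)
  # and clustering finds exactly the two blobs
  model <- cluster_landscape(model, k = 20, seed = 0)
  expect_identical(length(unique(model$cluster)), 2L)
  expect_equal(mclust::adjustedRandIndex(model$cluster, lab), 1)
})

test_that("a single Gaussian blob is one cluster", {
  set.seed(6)
  X <- matrix(rnorm(400 * 4, 5, 1), 400, 4)
  model <- cluster_landscape(embed_landscape(X, seed = 0), k = 20, seed = 0)
  expect_identical(length(unique(model$cluster)), 1L)
  expect_error(cluster_landscape(embed_landscape(X, seed = 0), k = 400),
               "smaller")
})

test_that("clustering is invariant to particle order (up to relabeling)", {
  tab <- small_organelle_table(n = 900, seed = 3)
  fit1 <- fit_landscape(tab, k = 20, seed = 0)
  perm <- sample(nrow(tab))
  tab2 <- particle_table(as.data.frame(tab)[perm, ], markers = markers(tab))
  fit2 <- fit_landscape(tab2, k = 20, seed = 0)
  expect_equal(mclust::adjustedRandIndex(fit1$model$cluster[perm],
                                         fit2$model$cluster), 1)
})

test_that("embedding inputs are validated", {
  expect_error(embed_landscape(matrix(1, 1, 3)), "at least 2")
  X <- matrix(rnorm(40), 10, 4); X[1, 1] <- NA
  expect_error(embed_landscape(X), "non-finite")
  expect_error(embed_landscape(matrix(rnorm(40), 10, 4),
                               batch = 1:3), "batch labels")
})

test_that("manual cluster merging follows the given groups", {
  labels <- rep(1:9, times = 9:1)
  merged <- merge_clusters(labels, list(er = c(1, 3, 5, 7, 9)))
  expect_identical(length(unique(merged)), 5L)       # 9 -> 5 clusters
  expect_true(all(merged[labels %in% c(1, 3, 5, 7, 9)] == "er"))
  expect_identical(merge_clusters(labels, list()), labels)
  expect_identical(length(unique(merge_clusters(labels, list(1:9)))), 1L)
  expect_error(merge_clusters(labels, list(c(1, 42))), "unknown")
  expect_error(merge_clusters(labels, list(c(1, 2), c(2, 3))), "overlap")
})

test_that("query projection is self-consistent and transfers labels", {
  tab <- small_organelle_table(n = 2100, seed = 0)
  fit <- fit_landscape(tab, k = 60, seed = 0)
  expect_identical(length(unique(fit$model$cluster)), 7L)

  # self-query: transferred labels match the reference's own labels
  qp <- map_query(fit$model, tab)
  expect_gte(mean(qp$cluster == fit$model$cluster), 0.99)

  # held-out particles from the same generative classes
  tab2 <- small_organelle_table(n = 700, seed = 77)
  qp2 <- map_query(fit$model, tab2)
  cls <- cluster_to_class(fit$model$cluster, tab$true_class)
  expect_gte(mean(cls[qp2$cluster] == tab2$true_class), 0.95)

  expect_error(map_query(fit$model, matrix(1, 5, 3)), "markers")
})

test_that("novel query classes land far from the reference", {
  tab <- small_organelle_table(n = 2100, seed = 0)
  fit <- fit_landscape(tab, k = 60, seed = 0)
  # novel class: bright in two markers never combined in the reference
  novel <- organelle_class_profiles()
  novel <- rbind(novel, novel["ER", ])
  rownames(novel)[8] <- "novel"
  novel["novel", ] <- log(30)
  novel["novel", c("GS27", "LAMP1", "NHS")] <- log(5000)
  scq <- sim_config(n_particles = 600, class_profiles = novel,
                    weights = c(rep(0.9 / 7, 7), 0.1), seed = 5)
  gtq <- sample_particles(scq, nonoverlap = FALSE)
  tabq <- make_feature_matrix(gtq, scq)
  qp <- map_query(fit$model, tabq)
  # self-distance scale of the reference: each reference particle's
  # distance to its nearest neighbor in aligned PC space
  cut <- stats::quantile(FNN::get.knn(fit$model$pcs, k = 1)$nn.dist[, 1],
                         0.99)
  is_novel <- tabq$true_class == "novel"
  expect_gte(mean(qp$nn_dist[is_novel] > cut), 0.9)
  expect_lt(mean(qp$nn_dist[!is_novel] > cut), 0.1)
})
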