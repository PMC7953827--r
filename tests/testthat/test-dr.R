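# shared small fixture: 60 spectra, 7600 bins
dr_fixture <- local({
  sim <- generate_spectra(synth_config(n_patients_per_class = 2, seed = 3),
                          "positive")
  preprocess_synth(sim)
})

test_that("PCA agrees with a dense eigendecomposition oracle", {
  ds <- dr_fixture[1:10]
  emb <- fit_reduce(ds, "pca", n_components = 3)
  xc <- scale(ds$values, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(xc) / (nrow(xc) - 1), symmetric = TRUE)
  # per-component reconstruction error matches the eigenvalue tail
  for (k in 1:3) {
    recon <- emb$coordinates[, 1:k, drop = FALSE] %*%
      emb$loadings[1:k, , drop = FALSE]
    expect_equal(sum((xc - recon)^2),
                 sum(ev$values[(k + 1):length(ev$values)]) * (nrow(xc) - 1),
                 tolerance = 1e-8)
  }
  # orthonormal loadings, non-increasing explained variance
  expect_equal(unname(tcrossprod(emb$loadings)), diag(3), tolerance = 1e-10)
  expect_true(all(diff(emb$provenance$sdev[1:3]) <= 1e-12))
  expect_equal(glance(emb)$method, "pca")
})

test_that("Isomap recovers a 1-D arc embedded in 7600-dimensional space", {
  set.seed(42)
  t_par <- sort(runif(200, 0, pi))
  basis <- qr.Q(qr(matrix(rnorm(7600 * 2), 7600, 2)))
  arc <- cbind(cos(t_par), sin(t_par)) %*% t(basis) * 10 +
    matrix(rnorm(200 * 7600, 0, 0.01), 200)
  ads <- spectra_dataset(arc, make_meta(200, ids = sprintf("a%03d", 1:200)),
                         grid = bin_grid(), allow_negative = TRUE)
  emb <- fit_reduce(ads, "isomap", n_components = 2, n_neighbors = 5)
  rho <- cor(emb$coordinates[, 1], t_par, method = "spearman")
  expect_gt(abs(rho), 0.95)
})

test_that("Isomap embedding distances agree with an independent implementation", {
  skip_if_not_installed("vegan")
  # a fixture whose kNN graph is connected, so both implementations see the
  # same geodesics
  set.seed(12)
  t_par <- sort(runif(100, 0, 2))
  x <- cbind(t_par, sin(2 * t_par), cos(3 * t_par)) %*%
    matrix(rnorm(3 * 50), 3, 50) + matrix(rnorm(100 * 50, 0, 0.02), 100)
  ds <- spectra_dataset(x, make_meta(100, ids = sprintf("v%03d", 1:100)),
                        grid = NULL, allow_negative = TRUE)
  emb <- fit_reduce(ds, "isomap", n_components = 3, n_neighbors = 7)
  ref <- vegan::isomap(dist(x), ndim = 3, k = 7)
  expect_gt(cor(as.vector(dist(emb$coordinates)),
                as.vector(dist(ref$points))), 0.99)
})

test_that("NNMF factors are nonnegative with a non-increasing objective", {
  emb <- fit_reduce(dr_fixture, "nnmf", n_components = 3, seed = 5)
  expect_true(all(emb$coordinates >= 0))
  expect_true(all(emb$loadings >= 0))
  obj <- emb$provenance$objective
  expect_true(all(diff(obj) <= 1e-6 * obj[1]))
  x <- dr_fixture$values
  rel <- sqrt(sum((x - emb$coordinates %*% emb$loadings)^2)) / sqrt(sum(x^2))
  expect_lt(rel, 1)
  expect_equal(glance(emb)$fit_quality, tail(obj, 1) / sqrt(sum(x^2)))
})

test_that("stochastic methods are reproducible under a fixed seed", {
  for (m in c("umap", "nnmf")) {
    e1 <- fit_reduce(dr_fixture, m, n_components = 3, seed = 11)
    e2 <- fit_reduce(dr_fixture, m, n_components = 3, seed = 11)
    expect_identical(e1$coordinates, e2$coordinates)
  }
  # the cosine UMAP variant runs and differs from the Euclidean one
  ec <- fit_reduce(dr_fixture, "umap", n_components = 3, seed = 11,
                   metric = "cosine")
  expect_equal(dim(ec$coordinates), c(60L, 3L))
  expect_equal(ec$provenance$metric, "cosine")
})

test_that("every method honors the out-of-sample transform contract", {
  idx <- c(1, 15, 40)
  dup <- dr_fixture[idx]
  for (m in dr_methods()) {
    emb <- fit_reduce(dr_fixture, m, n_components = 3, seed = 7)
    expect_equal(dim(emb$coordinates), c(60L, 3L))
    tr <- predict(emb, dup, seed = 7)
    expect_equal(dim(tr), c(3L, 3L))
    ref <- emb$coordinates[idx, , drop = FALSE]
    if (m == "umap") {
      # stochastic refinement: duplicates land close to their originals
      # relative to the embedding's size
      diam <- max(dist(emb$coordinates))
      expect_lt(max(sqrt(rowSums((tr - ref)^2))) / diam, 0.2)
    } else {
      expect_equal(unname(tr), unname(ref), tolerance = 1e-6)
    }
    # feature-count mismatch is rejected
    shrunk <- spectra_dataset(dup$values[, 1:100], dup$meta, grid = NULL,
                              allow_negative = TRUE)
    expect_error(predict(emb, shrunk), class = "ssmdr_validation_error")
  }
})

test_that("transform on the training data reproduces PCA fit coordinates", {
  emb <- fit_reduce(dr_fixture, "pca", n_components = 5)
  tr <- predict(emb, dr_fixture)
  expect_equal(unname(tr), unname(emb$coordinates), tolerance = 1e-8)
})

test_that("the harness validates its inputs", {
  expect_error(fit_reduce(dr_fixture, "pca", n_components = 60),
               class = "ssmdr_validation_error")
  expect_error(fit_reduce(dr_fixture, "isomap", n_components = 3,
                          n_neighbors = 60),
               class = "ssmdr_validation_error")
  # plsda is supervised
  ds_nolab <- dr_fixture
  ds_nolab$meta$diagnosis <- "same"
  expect_error(fit_reduce(ds_nolab, "plsda", n_components = 3),
               class = "ssmdr_validation_error")
  nn <- dr_fixture
  v <- nn$values; v[1, 1] <- -1
  neg <- spectra_dataset(v, nn$meta, nn$grid, allow_negative = TRUE)
  expect_error(fit_reduce(neg, "nnmf", n_components = 3),
               class = "ssmdr_validation_error")
})

test_that("embeddings feed back into the similarity stage", {
  emb <- fit_reduce(dr_fixture, "pca", n_components = 7)
  ds <- embedding_to_dataset(emb)
  expect_equal(dim(ds$values), c(60L, 7L))
  expect_equal(ds$meta$spectrum_id, dr_fixture$meta$spectrum_id)
  s <- compute_ssm(ds)
  expect_true(all(s$values >= -1 - 1e-12 & s$values <= 1 + 1e-12))
  # tidy carries metadata next to coordinates
  td <- tidy(emb)
  expect_true(all(c("spectrum_id", ".dim1", ".dim7") %in% names(td)))
})
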