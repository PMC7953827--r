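test_that("cosine SSM matches closed forms and the double-loop oracle", {
  g <- tiny_grid(3)
  m <- rbind(c(1, 1, 0), c(1, 1, 0))
  s <- compute_ssm(spectra_dataset(m, make_meta(2), g))
  expect_equal(s$values, matrix(1, 2, 2), ignore_attr = TRUE)

  m2 <- rbind(c(1, 0, 0), c(0, 1, 0))
  s2 <- compute_ssm(spectra_dataset(m2, make_meta(2), g))
  expect_equal(s2$values[1, 2], 0)

  m3 <- rbind(c(1, 1, 0), c(1, 0, 0))
  s3 <- compute_ssm(spectra_dataset(m3, make_meta(2), g))
  expect_equal(s3$values[1, 2], sqrt(2) / 2, tolerance = 1e-12)

  # random matrices up to 50 x 200 against the brute-force double loop
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(5:50, 1); p <- sample(20:200, 1)
    x <- matrix(rnorm(n * p), n, p)
    ds <- spectra_dataset(x, make_meta(n), grid = NULL, allow_negative = TRUE)
    got <- unname(compute_ssm(ds)$values)
    expect_lt(max(abs(got - cosine_oracle(x))), 1e-10)
    expect_lt(max(abs(got - t(got))), 1e-12)
    expect_true(all(got >= -1 - 1e-12 & got <= 1 + 1e-12))
    expect_equal(unname(diag(got)), rep(1, n))
  }
})

test_that("cosine SSM is invariant to per-spectrum rescaling and flags zero norms", {
  ds <- random_dataset(8, 60, seed = 2)
  s1 <- compute_ssm(ds)$values
  scaled <- ds$values * runif(8, 0.1, 50)
  s2 <- compute_ssm(spectra_dataset(scaled, ds$meta, ds$grid))$values
  expect_equal(s1, s2, tolerance = 1e-12)

  z <- ds$values; z[3, ] <- 0
  expect_warning(sz <- compute_ssm(spectra_dataset(z, ds$meta, ds$grid)),
                 regexp = "zero-norm")
  expect_equal(unname(sz$values[3, ]), rep(0, 8))
  expect_equal(unname(sz$values[, 3]), rep(0, 8))
  expect_error(compute_ssm(spectra_dataset(matrix(0, 0, 60), make_meta(0),
                                           tiny_grid(60))),
               class = "ssmdr_validation_error")
})

test_that("ordering strategies sort stably with deterministic boundaries", {
  meta <- make_meta(3, ids = c("x1", "x2", "x3"),
                    diagnosis = c("glioblastoma", "astrocytoma", "astrocytoma"),
                    dates = as.Date(c("2020-01-03", "2020-01-01", "2020-01-02")))
  byd <- order_spectra(meta, "by_date")
  expect_equal(byd$order, c(2, 3, 1))
  expect_length(byd$boundaries, 0)

  byc <- order_spectra(meta, "by_class_then_date")
  # lexicographic: astrocytoma block first, dates ascending within
  expect_equal(byc$order, c(2, 3, 1))
  expect_equal(byc$boundaries, 2L)

  one <- order_spectra(make_meta(1), "by_class_then_date")
  expect_equal(one$order, 1L)
  expect_length(one$boundaries, 0)

  meta_bad <- meta
  meta_bad$acquisition_date[2] <- NA
  expect_error(order_spectra(meta_bad, "by_date"), regexp = "x2",
               class = "ssmdr_validation_error")
})

test_that("block contrast matches its definition and its permutation null", {
  g <- tiny_grid(4)
  ssm_of <- function(vals, labs) {
    n <- nrow(vals)
    s <- structure(list(values = vals, meta = make_meta(n, diagnosis = labs),
                        order = seq_len(n), boundaries = integer(0),
                        strategy = "none", measure = "cosine"), class = "ssm")
    s
  }
  labs <- c("a", "a", "b", "b")
  ones <- ssm_of(matrix(1, 4, 4), labs)
  expect_equal(block_contrast(ones, labs, n_perm = 0)$contrast, 0)

  bd <- matrix(0, 4, 4); bd[1:2, 1:2] <- 1; bd[3:4, 3:4] <- 1
  expect_equal(block_contrast(ssm_of(bd, labs), labs, n_perm = 0)$contrast, 1)

  # p-value estimator never reports zero and detects block structure when
  # the permutation space is large enough
  labs20 <- rep(c("a", "b"), each = 10)
  bd20 <- matrix(0, 20, 20); bd20[1:10, 1:10] <- 1; bd20[11:20, 11:20] <- 1
  bc <- block_contrast(ssm_of(bd20, labs20), labs20, n_perm = 99, seed = 4)
  expect_gt(bc$p_value, 0)
  expect_lte(bc$p_value, 0.05)

  # permutation oracle: random symmetric matrix, random labels -> mean
  # contrast over shuffles is ~0 within 3 standard errors
  set.seed(11)
  r <- matrix(rnorm(20^2), 20, 20); r <- (r + t(r)) / 2; diag(r) <- 1
  srand <- ssm_of(r, rep(c("a", "b"), 10))
  shuffles <- replicate(1000, {
    block_contrast(srand, sample(rep(c("a", "b"), 10)), n_perm = 0)$contrast
  })
  expect_lt(abs(mean(shuffles)), 3 * sd(shuffles) / sqrt(length(shuffles)))

  # contrast is a function of labels only, not of the display permutation
  ds <- random_dataset(10, 40, seed = 5)
  s_date <- compute_ssm(ds, order = "by_date")
  s_cls <- compute_ssm(ds, order = "by_class_then_date")
  c1 <- block_contrast(s_date, as.character(s_date$meta$diagnosis), n_perm = 0)
  c2 <- block_contrast(s_cls, as.character(s_cls$meta$diagnosis), n_perm = 0)
  expect_equal(c1$contrast, c2$contrast, tolerance = 1e-12)

  # small groups are excluded from the within mean with a warning
  expect_warning(block_contrast(ssm_of(bd, c("a", "a", "b", "c")),
                                c("a", "a", "b", "c"), n_perm = 0),
                 regexp = "< 2 members")
})

test_that("SSM rendering writes an image, boundary lines and a sidecar", {
  ds <- random_dataset(6, 30, seed = 8)
  s <- compute_ssm(ds, order = "by_class_then_date")
  p <- autoplot(s, color_limits = c(0, 1))
  layer_geoms <- vapply(p$layers, function(l) class(l$geom)[1], character(1))
  expect_true("GeomHline" %in% layer_geoms && "GeomVline" %in% layer_geoms)

  out <- withr::local_tempfile(fileext = ".png")
  render_ssm(s, out, color_limits = c(0, 1))
  expect_true(file.exists(out) && file.size(out) > 0)
  sidecar <- jsonlite::read_json(paste0(out, ".json"), simplifyVector = TRUE)
  expect_equal(sidecar$color_limits, c(0, 1))
  expect_equal(sidecar$ordering, "by_class_then_date")
  expect_equal(sidecar$spectrum_order, s$meta$spectrum_id)
})
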