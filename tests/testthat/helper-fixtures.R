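# shared fixtures and independent brute-force oracles

make_meta <- function(n, ids = sprintf("s%02d", seq_len(n)),
                      diagnosis = rep(c("astrocytoma", "glioblastoma"),
                                      length.out = n),
                      polarity = "positive",
                      dates = as.Date("2020-01-01") + seq_len(n) - 1) {
  tibble::tibble(spectrum_id = ids,
                 sample_id = paste0(ids, "_smp"),
                 patient_id = paste0("pt", seq_len(n)),
                 diagnosis = diagnosis,
                 polarity = polarity,
                 acquisition_date = dates)
}

tiny_grid <- function(n_bins = 100) bin_grid(100, 100 + 0.25 * n_bins, 0.25)

random_dataset <- function(n, p, seed = 1, grid = tiny_grid(p)) {
  set.seed(seed)
  values <- matrix(rexp(n * p), n, p)
  spectra_dataset(values, make_meta(n), grid)
}

# O(n^2 p) double-loop cosine oracle
cosine_oracle <- function(x) {
  n <- nrow(x)
  s <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ni <- sqrt(sum(x[i, ]^2)); nj <- sqrt(sum(x[j, ]^2))
      s[i, j] <- if (ni == 0 || nj == 0) 0 else sum(x[i, ] * x[j, ]) / (ni * nj)
    }
  }
  s
}

# union-of-supports oracle for effective dimensionality
support_union_oracle <- function(x) {
  supp <- logical(ncol(x))
  for (i in seq_len(nrow(x))) supp <- supp | (x[i, ] > 0)
  sum(supp)
}

# brute-force block median (step == window)
block_median_oracle <- function(x, window) {
  out <- numeric(length(x))
  starts <- seq(1, length(x), by = window)
  for (s in starts) {
    e <- min(s + window - 1, length(x))
    out[s:e] <- median(x[s:e])
  }
  out
}

# brute-force rolling min + centered moving average baseline oracle
baseline_oracle <- function(x, window) {
  n <- length(x)
  h_l <- (window - 1) %/% 2
  h_r <- window - 1 - h_l
  rmin <- vapply(seq_len(n), function(i) {
    min(x[max(1, i - h_l):min(n, i + h_r)])
  }, numeric(1))
  bl <- vapply(seq_len(n), function(i) {
    mean(rmin[max(1, i - h_l):min(n, i + h_r)])
  }, numeric(1))
  pmax(x - bl, 0)
}

# mean pairwise Jaccard overlap of per-spectrum top-n bin sets
mean_top_jaccard <- function(dataset, n = 5) {
  tops <- apply(dataset$values, 1, function(r) order(-r, seq_along(r))[seq_len(n)])
  ind <- matrix(0L, ncol(tops), ncol(dataset$values))
  for (i in seq_len(ncol(tops))) ind[i, tops[, i]] <- 1L
  inter <- tcrossprod(ind)
  jac <- inter / (2 * n - inter)
  mean(jac[upper.tri(jac)])
}

# raw-dataset preprocessing used throughout: the synthetic generator emits
# sparse centroid-like peaks, so only baseline subtraction is applied
preprocess_synth <- function(sim) {
  preprocess_spectra(sim$dataset, median_filter = FALSE)
}
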