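#' Top-N peak thresholding of one spectrum
#'
#' Keeps the `n` highest-intensity bins and zeroes the rest — the naive
#' dimensionality reduction in which the retained high-intensity bins form
#' the projection space.  If the spectrum has `n` or fewer non-zero bins it
#' is returned unchanged.  Ties at the cutoff are broken toward the lower
#' bin index, so results are deterministic.
#'
#' @param x Numeric nonnegative vector (one binned spectrum).
#' @param n Number of bins to keep, >= 1.
#' @return Vector like `x` with at most `n` non-zero bins.
#' @examples
#' top_n_threshold(c(5, 3, 1, 0), 2) # 5 3 0 0
#' @export
top_n_threshold <- function(x, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1) {
    abort("`n` must be an integer >= 1.", class = "ssmdr_validation_error")
  }
  nz <- sum(x > 0)
  if (nz <= n) return(x)
  # order(-x, seq_along(x)) ranks by intensity, lower index first on ties
  keep <- order(-x, seq_along(x))[seq_len(n)]
  out <- numeric(length(x))
  out[keep] <- x[keep]
  out
}

#' Threshold every spectrum of a dataset
#'
#' @param dataset A [spectra_dataset()].
#' @param n Peaks to keep per spectrum (see [top_n_threshold()]).
#' @return A `spectra_dataset` of identical shape.
#' @export
threshold_dataset <- function(dataset, n) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  values <- t(apply(dataset$values, 1, top_n_threshold, n = n))
  if (nrow(dataset$values) == 1) values <- matrix(values, 1)
  spectra_dataset(values, dataset$meta, dataset$grid)
}

#' Effective dimensionality of a dataset
#'
#' The number of bins whose value in the arithmetic mean spectrum is
#' non-zero.  For nonnegative data this equals the size of the union of
#' per-spectrum supports.
#'
#' @param dataset A non-empty [spectra_dataset()].
#' @return Integer count of occupied bins.
#' @export
effective_dimensionality <- function(dataset) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  if (nrow(dataset$values) == 0) {
    abort("dataset is empty.", class = "ssmdr_validation_error")
  }
  sum(colMeans(dataset$values) > 0)
}

#' Occupancy curve: effective dimensionality vs. threshold level
#'
#' For each top-N level, thresholds every spectrum and counts the non-zero
#' bins of the average spectrum; an unthresholded row (level = number of
#' bins) is appended so the curve ends at the raw occupancy.
#'
#' @param dataset A non-empty [spectra_dataset()].
#' @param levels Integer vector of top-N levels (default the study grid
#'   5, 10, 25, 75, 200).
#' @return A tibble with columns `n_peaks`, `polarity`, `effective_dim`.
#' @export
occupancy_curve <- function(dataset, levels = c(5L, 10L, 25L, 75L, 200L)) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  if (!length(levels) || any(levels < 1)) {
    abort("`levels` must be a non-empty vector of integers >= 1.",
          class = "ssmdr_validation_error")
  }
  pol <- paste(unique(as.character(dataset$meta$polarity)), collapse = "/")
  levels <- sort(unique(as.integer(levels)))
  rows <- map(levels, function(n) {
    tibble(n_peaks = n, polarity = pol,
           effective_dim = effective_dimensionality(threshold_dataset(dataset, n)))
  })
  raw <- tibble(n_peaks = ncol(dataset$values), polarity = pol,
                effective_dim = effective_dimensionality(dataset))
  bind_rows(rows, raw)
}

#' Line plot of occupancy curves
#'
#' @param report Output of [occupancy_curve()], possibly row-bound across
#'   polarities.
#' @return A ggplot object (log-log axes).
#' @export
plot_occupancy <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data$n_peaks, y = .data$effective_dim,
                                       colour = .data$polarity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "peaks kept per spectrum (top-N)",
                  y = "non-zero bins in the average spectrum",
                  colour = "polarity") +
    ggplot2::theme_minimal()
}
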