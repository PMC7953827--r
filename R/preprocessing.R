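#' Bin one centroided spectrum onto a fixed m/z grid
#'
#' Each peak's intensity is added to the half-open bin
#' `[start + i*width, start + (i+1)*width)` containing its m/z
#' (`i = floor((mz - start)/width)`); peaks sharing a bin are summed.
#' Peaks outside the grid (including an m/z exactly at `stop`) are dropped
#' and their count reported via a message, consistent with clipping to the
#' instrument's acquisition range.
#'
#' @param mz,intensity Numeric vectors of equal length; intensities >= 0.
#' @param grid A [bin_grid()].
#' @return Numeric vector of length `grid$n_bins`.
#' @examples
#' v <- bin_spectrum(c(150.05, 150.20), c(1, 2))
#' v[201] # both peaks fall in bin index 200 (0-based): 3
#' @export
bin_spectrum <- function(mz, intensity, grid = bin_grid()) {
  if (length(mz) != length(intensity)) {
    abort("`mz` and `intensity` must have equal length.",
          class = "ssmdr_validation_error")
  }
  if (length(intensity) && any(intensity < 0)) {
    abort("intensities must be >= 0.", class = "ssmdr_validation_error")
  }
  out <- numeric(grid$n_bins)
  keep <- mz >= grid$start & mz < grid$stop
  if (!all(keep)) {
    inform(sprintf("dropped %d peak(s) outside [%g, %g) Th",
                   sum(!keep), grid$start, grid$stop))
  }
  if (any(keep)) {
    idx <- floor((mz[keep] - grid$start) / grid$width) + 1L
    add <- rowsum(intensity[keep], idx)
    out[as.integer(rownames(add))] <- add[, 1]
  }
  out
}

#' Bin a long peak table into a spectra dataset
#'
#' @param peaks Tibble with columns `spectrum_id`, `mz`, `intensity`
#'   (as returned by [read_peaklist_csv()] or [as_peaklist()]).
#' @param meta Metadata tibble, one row per distinct `spectrum_id`
#'   (see [spectra_dataset()]). Row order of the result follows `meta`.
#' @param grid A [bin_grid()].
#' @return A [spectra_dataset()].
#' @export
bin_peaklist <- function(peaks, meta, grid = bin_grid()) {
  meta <- validate_meta(meta)
  missing <- setdiff(unique(peaks$spectrum_id), meta$spectrum_id)
  if (length(missing)) {
    abort(paste0("peaks reference spectrum id(s) absent from `meta`: ",
                 paste(head(missing, 5), collapse = ", ")),
          class = "ssmdr_validation_error")
  }
  values <- matrix(0, nrow(meta), grid$n_bins)
  rows <- split(seq_len(nrow(peaks)), factor(peaks$spectrum_id, levels = meta$spectrum_id))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r)) {
      values[i, ] <- suppressMessages(bin_spectrum(peaks$mz[r], peaks$intensity[r], grid))
    }
  }
  spectra_dataset(values, meta, grid)
}

#' Moving median filter along the m/z axis
#'
#' With `step == window` (the default, window 51) the vector is partitioned
#' into consecutive blocks of `window` bins (the last block may be shorter)
#' and every bin in a block is replaced by the block median, so the output
#' keeps the input length and the downstream bin grid stays valid.  With
#' `step == 1` a classic centered sliding median is applied, edge windows
#' truncated.
#'
#' @param x Numeric vector (one binned spectrum).
#' @param window Integer window width in bins, >= 1 (odd when `step == 1`).
#' @param step Either `window` (block mode) or 1 (sliding mode).
#' @return Filtered vector, same length as `x`.
#' @export
moving_median_filter <- function(x, window = 51L, step = window) {
  window <- as.integer(window)
  if (is.na(window) || window < 1) {
    abort("`window` must be an integer >= 1.", class = "ssmdr_validation_error")
  }
  if (window == 1L) return(x)
  n <- length(x)
  if (n < 1) return(x)
  if (step == window) {
    blocks <- (seq_len(n) - 1L) %/% window
    meds <- vapply(split(x, blocks), median, numeric(1))
    unname(meds[as.character(blocks)])
  } else if (step == 1L) {
    if (window %% 2L == 0L) {
      abort("`window` must be odd when `step == 1`.", class = "ssmdr_validation_error")
    }
    if (window >= n) return(rep(median(x), n))
    as.numeric(stats::runmed(x, k = window, endrule = "median"))
  } else {
    abort("`step` must equal `window` (block mode) or 1 (sliding mode).",
          class = "ssmdr_validation_error")
  }
}

#' Baseline estimation and subtraction
#'
#' The baseline is estimated by a centered rolling minimum over `window`
#' bins followed by a centered moving average with the same window (a
#' morphological-opening analogue), then subtracted with clipping at zero.
#' On any region that is flat over at least a window, adding a constant
#' offset to the input leaves the output unchanged.
#'
#' @param x Numeric vector (one binned spectrum).
#' @param window Integer window in bins (default 400, i.e. 100 Th on the
#'   default grid); must satisfy `1 <= window <= length(x)`.
#' @return Nonnegative vector, same length as `x`.
#' @export
subtract_baseline <- function(x, window = 400L) {
  window <- as.integer(window)
  if (is.na(window) || window < 1) {
    abort("`window` must be an integer >= 1.", class = "ssmdr_validation_error")
  }
  if (window > length(x)) {
    abort("`window` exceeds the vector length.", class = "ssmdr_validation_error")
  }
  baseline <- .roll_mean_center(.roll_min_center(x, window), window)
  pmax(x - baseline, 0)
}

#' Apply the standard preprocessing chain
#'
#' Composition, per spectrum, of (1) binning onto the grid, (2) the moving
#' median filter, (3) baseline subtraction — in that order.  Accepts either
#' a long peak table plus metadata (in which case binning runs first) or an
#' already-binned [spectra_dataset()] (binning skipped).  The applied
#' parameters are recorded in the result's `provenance` attribute.
#'
#' The width-51 block median is appropriate for dense, profile-like
#' low-resolution spectra; on sparse centroided data it suppresses isolated
#' peaks, so it can be disabled with `median_filter = FALSE`.
#'
#' @param x A peak tibble (`spectrum_id`, `mz`, `intensity`) or a
#'   `spectra_dataset`.
#' @param meta Metadata tibble (required when `x` is a peak tibble).
#' @param grid A [bin_grid()].
#' @param median_filter,baseline Logical switches for the two denoising steps.
#' @param median_window,median_step See [moving_median_filter()].
#' @param baseline_window See [subtract_baseline()].
#' @return A [spectra_dataset()] with a `provenance` attribute listing the
#'   applied parameters.
#' @export
preprocess_spectra <- function(x, meta = NULL, grid = bin_grid(),
                               median_filter = TRUE, median_window = 51L,
                               median_step = median_window,
                               baseline = TRUE, baseline_window = 400L) {
  if (inherits(x, "spectra_dataset")) {
    ds <- x
    grid <- ds$grid %||% grid
  } else {
    if (is.null(meta)) {
      abort("`meta` is required when `x` is a peak table.",
            class = "ssmdr_validation_error")
    }
    if (nrow(x) == 0 && nrow(meta) == 0) {
      abort("empty input: no spectra to preprocess.", class = "ssmdr_validation_error")
    }
    ds <- bin_peaklist(x, meta, grid)
  }
  values <- ds$values
  if (median_filter) {
    values <- t(apply(values, 1, moving_median_filter,
                      window = median_window, step = median_step))
  }
  if (baseline) {
    values <- t(apply(values, 1, subtract_baseline, window = baseline_window))
  }
  if (nrow(values) == 0) values <- matrix(0, 0, grid$n_bins)
  out <- spectra_dataset(values, ds$meta, grid)
  attr(out, "provenance") <- list(
    median_filter = median_filter,
    median_window = if (median_filter) as.integer(median_window) else NA_integer_,
    median_step = if (median_filter) as.integer(median_step) else NA_integer_,
    baseline = baseline,
    baseline_window = if (baseline) as.integer(baseline_window) else NA_integer_
  )
  out
}
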