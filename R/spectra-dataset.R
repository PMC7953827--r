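#' Define an m/z bin grid
#'
#' The working representation of every spectrum is a fixed-length vector of
#' intensities on a regular grid of half-open m/z intervals
#' `[start + i*width, start + (i+1)*width)`, `i = 0, ..., n_bins - 1`.
#' The defaults (100--2000 Th at 0.25 Th) give 7600 bins, the acquisition
#' range of low-resolution ambient-ionization profiling on linear ion traps.
#'
#' @param start,stop Grid limits in Thomson. `stop - start` must be an exact
#'   multiple of `width`.
#' @param width Bin width in Thomson, > 0.
#' @return A `bin_grid` object (list with `start`, `stop`, `width`, `n_bins`).
#' @examples
#' g <- bin_grid()
#' g$n_bins # 7600
#' @export
bin_grid <- function(start = 100, stop = 2000, width = 0.25) {
  if (!is.numeric(width) || length(width) != 1 || width <= 0) {
    abort("`width` must be a single positive number.", class = "ssmdr_validation_error")
  }
  if (stop <= start) {
    abort("`stop` must exceed `start`.", class = "ssmdr_validation_error")
  }
  n <- (stop - start) / width
  if (abs(n - round(n)) > 1e-9) {
    abort("(stop - start) must be an exact multiple of `width`.",
          class = "ssmdr_validation_error")
  }
  structure(list(start = start, stop = stop, width = width, n_bins = as.integer(round(n))),
            class = "bin_grid")
}

#' @export
#' @method print bin_grid
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> [%g, %g) Th, width %g Th, %d bins\n",
              x$start, x$stop, x$width, x$n_bins))
  invisible(x)
}

grid_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a)[c("start", "stop", "width")],
                   unclass(b)[c("start", "stop", "width")])) &&
    a$n_bins == b$n_bins
}

#' Per-spectrum metadata columns required by the pipeline
#' @noRd
meta_required_cols <- c("spectrum_id", "sample_id", "patient_id",
                        "diagnosis", "polarity", "acquisition_date")

validate_meta <- function(meta, n = NULL) {
  if (!is.data.frame(meta)) {
    abort("`meta` must be a data frame.", class = "ssmdr_validation_error")
  }
  meta <- as_tibble(meta)
  missing <- setdiff(meta_required_cols, names(meta))
  if (length(missing)) {
    abort(paste0("`meta` is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "ssmdr_format_error")
  }
  if (anyDuplicated(meta$spectrum_id)) {
    abort("`spectrum_id` must be unique within a dataset.",
          class = "ssmdr_validation_error")
  }
  bad_pol <- setdiff(unique(as.character(meta$polarity)), c("positive", "negative"))
  if (length(bad_pol)) {
    abort(paste0("`polarity` must be 'positive' or 'negative'; found: ",
                 paste(bad_pol, collapse = ", ")),
          class = "ssmdr_validation_error")
  }
  if (!inherits(meta$acquisition_date, "Date")) {
    meta$acquisition_date <- as.Date(meta$acquisition_date)
  }
  if (!is.null(n) && nrow(meta) != n) {
    abort(sprintf("metadata has %d rows but the matrix has %d spectra.",
                  nrow(meta), n),
          class = "ssmdr_validation_error")
  }
  meta
}

#' Bundle a binned intensity matrix with row-aligned spectrum metadata
#'
#' A `spectra_dataset` is the pipeline's working object: a nonnegative
#' `n_spectra x n_bins` intensity matrix plus one metadata record per row
#' (spectrum id, sample and patient ids, diagnosis label, ionization
#' polarity, acquisition date, optional batch id).
#'
#' @param values Numeric matrix, spectra in rows, bins in columns; all
#'   entries must be >= 0 and the column count must equal `grid$n_bins`.
#' @param meta Data frame with columns `spectrum_id`, `sample_id`,
#'   `patient_id`, `diagnosis`, `polarity` (`"positive"`/`"negative"`),
#'   `acquisition_date` (coerced to `Date`), optionally `batch_id`;
#'   one row per matrix row, in matrix row order.
#' @param grid A [bin_grid()]. For already-reduced feature sets (e.g. an
#'   embedding fed back into the similarity stage) pass `grid = NULL`.
#' @param allow_negative Permit negative feature values (used internally for
#'   embeddings, whose coordinates may be negative; raw intensities never are).
#' @return A `spectra_dataset`.
#' @seealso [bin_peaklist()], [generate_spectra()], [compute_ssm()]
#' @export
spectra_dataset <- function(values, meta, grid = bin_grid(), allow_negative = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.", class = "ssmdr_validation_error")
  }
  meta <- validate_meta(meta, n = nrow(values))
  if (!allow_negative && nrow(values) && any(values < 0)) {
    abort("intensity matrix contains negative entries.",
          class = "ssmdr_validation_error")
  }
  if (!is.null(grid)) {
    if (!inherits(grid, "bin_grid")) {
      abort("`grid` must be a bin_grid or NULL.", class = "ssmdr_validation_error")
    }
    if (ncol(values) != grid$n_bins) {
      abort(sprintf("matrix has %d columns but the grid defines %d bins.",
                    ncol(values), grid$n_bins),
            class = "ssmdr_validation_error")
    }
  }
  rownames(values) <- meta$spectrum_id
  structure(list(values = values, meta = meta, grid = grid),
            class = "spectra_dataset")
}

#' @export
#' @method print spectra_dataset
print.spectra_dataset <- function(x, ...) {
  cat(sprintf("<spectra_dataset> %d spectra x %d features\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$grid)) {
    cat(sprintf("  grid: [%g, %g) Th @ %g Th\n", x$grid$start, x$grid$stop, x$grid$width))
  }
  if (nrow(x$meta)) {
    cat(sprintf("  polarity: %s | diagnoses: %s\n",
                paste(unique(x$meta$polarity), collapse = "/"),
                paste(unique(as.character(x$meta$diagnosis)), collapse = ", ")))
    cat(sprintf("  dates: %s .. %s\n",
                min(x$meta$acquisition_date), max(x$meta$acquisition_date)))
  }
  invisible(x)
}

#' @export
dim.spectra_dataset <- function(x) dim(x$values)

n_spectra <- function(x) nrow(x$values)

#' Subset a spectra dataset by row
#'
#' @param x A `spectra_dataset`.
#' @param i Row indices (integer, logical, or spectrum ids).
#' @param ... Unused.
#' @return A `spectra_dataset` with the selected spectra, metadata re-aligned.
#' @export
`[.spectra_dataset` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$meta$spectrum_id)
  spectra_dataset(x$values[i, , drop = FALSE], x$meta[i, , drop = FALSE],
                  grid = x$grid, allow_negative = TRUE)
}

#' Convert a spectra dataset to a long peak tibble
#'
#' Emits one row per non-zero bin, with `mz` at the bin center.  The inverse
#' of [bin_peaklist()] for data whose peaks already sit on the grid.
#'
#' @param dataset A `spectra_dataset` with a grid.
#' @return A tibble with columns `spectrum_id`, `mz`, `intensity`.
#' @export
as_peaklist <- function(dataset) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  if (is.null(dataset$grid)) {
    abort("dataset has no bin grid; cannot assign m/z values.",
          class = "ssmdr_validation_error")
  }
  g <- dataset$grid
  centers <- g$start + (seq_len(g$n_bins) - 0.5) * g$width
  idx <- which(dataset$values != 0, arr.ind = TRUE)
  out <- tibble(
    spectrum_id = dataset$meta$spectrum_id[idx[, 1]],
    mz = centers[idx[, 2]],
    intensity = dataset$values[idx]
  )
  arrange(out, match(.data$spectrum_id, dataset$meta$spectrum_id), .data$mz)
}

#' @export
as_tibble.spectra_dataset <- function(x, ...) {
  vals <- as_tibble(x$values, .name_repair = "minimal")
  names(vals) <- colnames(x$values) %||% paste0("bin", seq_len(ncol(x$values)))
  dplyr::bind_cols(x$meta, vals)
}
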