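#' Read a CSV/TSV peak list (one row per peak)
#'
#' Expects columns `spectrum_id`, `mz`, `intensity`; any further columns are
#' ignored.  Metadata may be supplied inline (extra columns named as in
#' [spectra_dataset()] metadata, constant within a spectrum) or as a sidecar
#' CSV via `meta`.
#'
#' @param path Peak-list CSV/TSV path (delimiter auto-detected by extension).
#' @param meta Optional path to a metadata CSV with one row per spectrum, or
#'   a data frame.  When `NULL`, metadata columns are looked up inline.
#' @return A list with `peaks` (tibble `spectrum_id`, `mz`, `intensity`,
#'   sorted by spectrum then m/z) and `meta` (tibble, one row per spectrum;
#'   `NULL` when no metadata was found).
#' @export
read_peaklist_csv <- function(path, meta = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "ssmdr_io_error")
  }
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  peaks <- reader(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("spectrum_id", "mz", "intensity")) {
    if (!col %in% names(peaks)) {
      abort(paste0("peak list is missing required column: ", col),
            class = "ssmdr_format_error")
    }
  }
  bad <- which(peaks$intensity < 0)
  if (length(bad)) {
    abort(sprintf("negative intensity at row %d of %s", bad[1], path),
          class = "ssmdr_validation_error")
  }
  inline_meta <- intersect(setdiff(meta_required_cols, "spectrum_id"), names(peaks))
  meta_tbl <- NULL
  if (!is.null(meta)) {
    meta_tbl <- if (is.data.frame(meta)) as_tibble(meta) else {
      readr::read_csv(meta, show_col_types = FALSE, progress = FALSE)
    }
    meta_tbl <- validate_meta(meta_tbl)
  } else if (length(inline_meta) == length(meta_required_cols) - 1L) {
    meta_tbl <- validate_meta(dplyr::distinct(
      peaks[, c("spectrum_id", inline_meta)]))
  }
  peaks <- arrange(peaks[, c("spectrum_id", "mz", "intensity")],
                   .data$spectrum_id, .data$mz)
  list(peaks = peaks, meta = meta_tbl)
}

#' Read centroided MS1 spectra from an mzML file
#'
#' Uses the Bioconductor `mzR` parser.  Peaks outside the grid's m/z range
#' are clipped (with a message reporting the retained count), scan order is
#' preserved as `scan_index` 0, 1, ..., per-spectrum polarity is read from
#' the file when present, and the run's start timestamp (when recorded)
#' becomes the acquisition date.
#'
#' @param path mzML file path.
#' @param polarity Optional override (`"positive"`/`"negative"`) used when
#'   the file does not record polarity; if the file lacks polarity and no
#'   override is given, an error is raised.
#' @param sample_id,patient_id,diagnosis Metadata not representable in mzML;
#'   defaults derive from the file name.
#' @param grid [bin_grid()] defining the retained m/z range.
#' @return A list with `peaks` and `meta` tibbles as in [read_peaklist_csv()].
#' @export
read_mzml <- function(path, polarity = NULL, sample_id = NULL,
                      patient_id = NULL, diagnosis = NA_character_,
                      grid = bin_grid()) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("package 'mzR' is required to read mzML files.",
          class = "ssmdr_io_error")
  }
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "ssmdr_io_error")
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  ms1 <- which(hdr$msLevel == 1L)
  stem <- tools::file_path_sans_ext(basename(path))
  sample_id <- sample_id %||% stem
  patient_id <- patient_id %||% stem

  pol_code <- hdr$polarity[ms1]
  pol <- dplyr::case_when(pol_code > 0 ~ "positive",
                          pol_code < 0 ~ "negative",
                          TRUE ~ NA_character_)
  if (anyNA(pol)) {
    if (is.null(polarity)) {
      abort("mzML file does not record polarity; pass `polarity=`.",
            class = "ssmdr_format_error")
    }
    warn("polarity unreadable from mzML; using the supplied override.")
    pol[is.na(pol)] <- polarity
  }

  run <- tryCatch(mzR::runInfo(handle), error = function(e) list())
  ts <- run$startTimeStamp
  acq_date <- if (!is.null(ts) && !is.na(ts) && nzchar(ts)) {
    as.Date(substr(ts, 1, 10))
  } else as.Date(NA)

  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  total <- 0L
  kept <- 0L
  rows <- vector("list", length(ms1))
  ids <- sprintf("%s_sc%d", sample_id, seq_along(ms1) - 1L)
  for (j in seq_along(ms1)) {
    m <- pk[[ms1[j]]]
    total <- total + nrow(m)
    keep <- m[, 1] >= grid$start & m[, 1] < grid$stop
    kept <- kept + sum(keep)
    m <- m[keep, , drop = FALSE]
    m <- m[order(m[, 1]), , drop = FALSE]
    rows[[j]] <- tibble(spectrum_id = ids[j], mz = as.vector(m[, 1]),
                        intensity = as.vector(m[, 2]))
  }
  if (kept < total) {
    inform(sprintf("retained %d of %d peaks within [%g, %g) Th",
                   kept, total, grid$start, grid$stop))
  }
  meta <- tibble(spectrum_id = ids, sample_id = sample_id,
                 patient_id = patient_id, diagnosis = diagnosis,
                 polarity = pol, acquisition_date = acq_date,
                 scan_index = seq_along(ms1) - 1L)
  list(peaks = list_rbind(rows), meta = meta)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a spectra dataset in the package's native text format
#'
#' One plain-text file: a header (grid definition, counts, storage mode),
#' the metadata block as embedded TSV, and the intensity payload — dense
#' rows, or sparse `row TAB col TAB value` triplets chosen automatically
#' when more than 90% of entries are zero (thresholded matrices are
#' extremely sparse).  Values are serialized with 17 significant digits so
#' the round trip is bit-exact for doubles.
#'
#' @param dataset A [spectra_dataset()].
#' @param path Output file path.
#' @return `write_spectra` returns `path` invisibly; `read_spectra` returns
#'   the reconstructed `spectra_dataset`.
#' @export
write_spectra <- function(dataset, path) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  v <- dataset$values
  sparse <- length(v) > 0 && mean(v == 0) > 0.9
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(paste0("cannot open for writing: ", path), class = "ssmdr_io_error")
  })
  on.exit(close(con), add = TRUE)
  g <- dataset$grid
  writeLines(c("#ssmdr_matrix 1",
               sprintf("#grid %s %s %s %d",
                       fmt_num(g$start), fmt_num(g$stop), fmt_num(g$width), g$n_bins),
               sprintf("#n_spectra %d", nrow(v)),
               sprintf("#storage %s", if (sparse) "sparse" else "dense"),
               "#meta"), con)
  meta <- dataset$meta
  meta$acquisition_date <- format(meta$acquisition_date, "%Y-%m-%d")
  writeLines(paste(names(meta), collapse = "\t"), con)
  if (nrow(meta)) {
    writeLines(do.call(paste, c(lapply(meta, as.character), sep = "\t")), con)
  }
  writeLines("#values", con)
  if (sparse) {
    idx <- which(v != 0, arr.ind = TRUE)
    writeLines(sprintf("%d\t%d\t%s", idx[, 1], idx[, 2], fmt_num(v[idx])), con)
  } else if (nrow(v)) {
    writeLines(apply(v, 1, function(r) paste(fmt_num(r), collapse = "\t")), con)
  }
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "ssmdr_io_error")
  }
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#ssmdr_matrix")) {
    abort("not an ssmdr native matrix file.", class = "ssmdr_format_error")
  }
  gl <- strsplit(sub("^#grid ", "", lines[2]), " ")[[1]]
  grid <- bin_grid(as.numeric(gl[1]), as.numeric(gl[2]), as.numeric(gl[3]))
  n_spec <- as.integer(sub("^#n_spectra ", "", lines[3]))
  storage <- sub("^#storage ", "", lines[4])
  stopifnot(lines[5] == "#meta")
  vstart <- which(lines == "#values")[1]
  meta_lines <- lines[6:(vstart - 1L)]
  meta <- readr::read_tsv(I(paste(meta_lines, collapse = "\n")),
                          show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  meta$acquisition_date <- as.Date(meta$acquisition_date)
  for (col in intersect(c("scan_index", "fragment"), names(meta))) {
    meta[[col]] <- as.integer(meta[[col]])
  }
  payload <- if (vstart < length(lines)) lines[(vstart + 1L):length(lines)] else character(0)
  values <- matrix(0, n_spec, grid$n_bins)
  if (storage == "sparse") {
    if (length(payload)) {
      trip <- utils::read.table(text = payload, sep = "\t",
                                colClasses = c("integer", "integer", "numeric"))
      values[cbind(trip[[1]], trip[[2]])] <- trip[[3]]
    }
  } else {
    if (length(payload) != n_spec) {
      abort("dense payload row count does not match header.",
            class = "ssmdr_format_error")
    }
    if (n_spec) {
      values <- do.call(rbind, lapply(payload, function(l) {
        as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])
      }))
    }
  }
  spectra_dataset(values, meta, grid)
}
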