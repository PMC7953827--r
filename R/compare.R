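#' Define a comparison plan
#'
#' The full evaluation grid: top-N thresholding levels and DR methods at
#' several target dimensions, per polarity, each summarized by SSM block
#' contrast under both display orderings (`by_date` paired with the
#' batch grouping, `by_class_then_date` with the diagnosis grouping).
#'
#' @param threshold_levels Top-N levels (default 5, 10, 25, 75, 200).
#' @param dr_methods DR methods to run (default all six).
#' @param dims Target dimensions for the DR methods (default 3, 5, 7).
#' @param orderings SSM orderings (default both).
#' @param polarities Which polarity datasets to analyze (default both).
#' @param include_raw Include the unreduced-spectra baseline cells.
#' @param n_neighbors Neighborhood size for Isomap/UMAP (default 5).
#' @param n_perm Permutations per block-contrast p-value (default 199 across
#'   the grid; [block_contrast()] alone defaults to 999).
#' @param seed Base seed; every stochastic stage derives its own seed from
#'   it (`derive_seed(seed, cell_index)`), so a plan is reproducible
#'   row-for-row.
#' @return A `comparison_plan`.
#' @export
comparison_plan <- function(threshold_levels = c(5L, 10L, 25L, 75L, 200L),
                            dr_methods = c("pca", "plsda", "nnmf", "isomap",
                                           "umap", "diffusion_map"),
                            dims = c(3L, 5L, 7L),
                            orderings = c("by_date", "by_class_then_date"),
                            polarities = c("positive", "negative"),
                            include_raw = TRUE,
                            n_neighbors = 5L,
                            n_perm = 199L,
                            seed = 1L) {
  if (!length(threshold_levels) && !length(dr_methods) && !include_raw) {
    abort("empty plan.", class = "ssmdr_validation_error")
  }
  if (length(dr_methods) && !length(dims)) {
    abort("`dims` must be non-empty when DR methods are planned.",
          class = "ssmdr_validation_error")
  }
  dr_methods <- vapply(dr_methods, function(m) match.arg(m, .dr_methods),
                       character(1))
  structure(list(threshold_levels = as.integer(threshold_levels),
                 dr_methods = unname(dr_methods), dims = as.integer(dims),
                 orderings = match.arg(orderings,
                                       c("by_date", "by_class_then_date"),
                                       several.ok = TRUE),
                 polarities = match.arg(polarities,
                                        c("positive", "negative"),
                                        several.ok = TRUE),
                 include_raw = isTRUE(include_raw),
                 n_neighbors = as.integer(n_neighbors),
                 n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "comparison_plan")
}

#' Methods known to the DR harness
#' @return Character vector of method names.
#' @export
dr_methods <- function() {
  .dr_methods
}

plan_cells <- function(plan) {
  cells <- list()
  if (plan$include_raw) {
    cells <- c(cells, list(list(reduction = "raw", dim = NA_integer_)))
  }
  for (lv in plan$threshold_levels) {
    cells <- c(cells, list(list(reduction = "threshold", dim = lv)))
  }
  for (m in plan$dr_methods) for (k in plan$dims) {
    cells <- c(cells, list(list(reduction = m, dim = k)))
  }
  cells
}

grouping_for <- function(ordering) {
  if (ordering == "by_date") "batch" else "diagnosis"
}

batch_labels <- function(meta) {
  if ("batch_id" %in% names(meta) && !anyNA(meta$batch_id)) {
    as.character(meta$batch_id)
  } else {
    # acquisition-date grouping proxy when no explicit batch is recorded
    format(meta$acquisition_date, "%Y-%m")
  }
}

#' Run the full comparison grid
#'
#' For every plan cell (raw baseline, each thresholding level in spectrum
#' space, each DR method at each target dimension) and polarity: reduce,
#' compute the cosine SSM once, and report the block contrast for each
#' planned ordering against its grouping (acquisition-date ordering against
#' batch labels, diagnosis ordering against diagnosis labels).  Failing
#' cells are recorded as failed rows and the run continues.
#'
#' @param datasets A named list `list(positive = ..., negative = ...)` of
#'   [spectra_dataset()]s (a single unnamed dataset is treated as its
#'   metadata's polarity).
#' @param plan A [comparison_plan()].
#' @param out_dir Optional run directory; when given, writes `result.csv`,
#'   per-cell SSM CSVs (and PNGs with `render_png = TRUE`), and a
#'   `manifest.json` listing every artifact with its MD5 content hash.
#' @param render_png Also render SSM heatmap PNGs (slower).
#' @return A tibble, one row per (cell, ordering): `polarity`, `reduction`,
#'   `dim`, `ordering`, `grouping_key`, `within_mean`, `between_mean`,
#'   `contrast`, `p_value`, `status`, `error`, artifact paths.
#' @export
run_comparison <- function(datasets, plan = comparison_plan(), out_dir = NULL,
                           render_png = FALSE) {
  if (inherits(datasets, "spectra_dataset")) {
    datasets <- setNames(list(datasets),
                         unique(as.character(datasets$meta$polarity))[1])
  }
  stopifnot(length(datasets) >= 1, !is.null(names(datasets)))
  pols <- intersect(plan$polarities, names(datasets))
  if (!length(pols)) {
    abort("no planned polarity found among the supplied datasets.",
          class = "ssmdr_validation_error")
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cells <- plan_cells(plan)
  rows <- list()
  artifacts <- character(0)
  cell_index <- 0L

  for (pol in pols) {
    ds <- datasets[[pol]]
    for (cell in cells) {
      cell_index <- cell_index + 1L
      cell_seed <- derive_seed(plan$seed, cell_index)
      tag <- if (cell$reduction == "raw") "raw"
             else if (cell$reduction == "threshold") paste0("top", cell$dim)
             else paste0(cell$reduction, "_k", cell$dim)
      feat <- tryCatch({
        switch(cell$reduction,
               raw = ds,
               threshold = threshold_dataset(ds, cell$dim),
               embedding_to_dataset(fit_reduce(
                 ds, dr_spec(cell$reduction, cell$dim,
                             n_neighbors = plan$n_neighbors),
                 seed = cell_seed)))
      }, error = function(e) e)

      for (ordering in plan$orderings) {
        grouping <- grouping_for(ordering)
        base_row <- tibble(polarity = pol, reduction = cell$reduction,
                           label = tag, dim = cell$dim, ordering = ordering,
                           grouping_key = grouping)
        if (inherits(feat, "error")) {
          rows <- c(rows, list(mutate(base_row, within_mean = NA_real_,
                                      between_mean = NA_real_,
                                      contrast = NA_real_, p_value = NA_real_,
                                      status = "failed",
                                      error = conditionMessage(feat),
                                      ssm_csv = NA_character_,
                                      ssm_png = NA_character_)))
          next
        }
        res <- tryCatch({
          ssm <- suppressWarnings(compute_ssm(feat, order = ordering))
          labels <- if (grouping == "batch") batch_labels(ssm$meta)
                    else as.character(ssm$meta$diagnosis)
          bc <- suppressWarnings(
            block_contrast(ssm, labels, n_perm = plan$n_perm, seed = cell_seed))
          csv_path <- png_path <- NA_character_
          if (!is.null(out_dir)) {
            stub <- file.path(out_dir, sprintf("ssm_%s_%s_%s", pol, tag, ordering))
            csv_path <- paste0(stub, ".csv")
            write_ssm_csv(ssm, csv_path)
            artifacts <- c(artifacts, csv_path)
            if (render_png) {
              png_path <- paste0(stub, ".png")
              render_ssm(ssm, png_path)
              artifacts <- c(artifacts, png_path, paste0(png_path, ".json"))
            }
          }
          mutate(base_row, within_mean = bc$within_mean,
                 between_mean = bc$between_mean, contrast = bc$contrast,
                 p_value = bc$p_value, status = "ok", error = NA_character_,
                 ssm_csv = csv_path, ssm_png = png_path)
        }, error = function(e) {
          mutate(base_row, within_mean = NA_real_, between_mean = NA_real_,
                 contrast = NA_real_, p_value = NA_real_, status = "failed",
                 error = conditionMessage(e), ssm_csv = NA_character_,
                 ssm_png = NA_character_)
        })
        rows <- c(rows, list(res))
      }
    }
  }

  result <- list_rbind(rows)
  if (!is.null(out_dir)) {
    result_path <- file.path(out_dir, "result.csv")
    # artifact paths are stored relative to the run directory so the file's
    # content (and its manifest hash) does not depend on where the run lives
    rel <- mutate(result,
                  ssm_csv = ifelse(is.na(.data$ssm_csv), .data$ssm_csv,
                                   basename(.data$ssm_csv)),
                  ssm_png = ifelse(is.na(.data$ssm_png), .data$ssm_png,
                                   basename(.data$ssm_png)))
    readr::write_csv(rel, result_path, progress = FALSE)
    artifacts <- c(artifacts, result_path)
    manifest <- list(
      plan = unclass(plan),
      artifacts = lapply(artifacts, function(p) {
        list(path = basename(p), md5 = unname(tools::md5sum(p)))
      }))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  result
}

#' Rank reductions by block contrast
#'
#' Sorts comparison rows by contrast (descending) within
#' `(polarity, grouping_key, dim)`, breaking ties by permutation p-value and
#' then by reduction name.  No rows are dropped; a `rank` column is added
#' (failed cells rank last).
#'
#' @param result Output of [run_comparison()].
#' @param key Optionally restrict the ranking to one grouping key
#'   (`"diagnosis"` or `"batch"`) before sorting; `NULL` keeps all rows.
#' @return The ranked tibble.
#' @export
rank_methods <- function(result, key = NULL) {
  if (!nrow(result)) {
    abort("`result` is empty.", class = "ssmdr_validation_error")
  }
  if (!is.null(key)) result <- filter(result, .data$grouping_key == key)
  result <- arrange(result, .data$polarity, .data$grouping_key, .data$dim,
                    desc(.data$contrast), .data$p_value, .data$label)
  result <- group_by(result, .data$polarity, .data$grouping_key, .data$dim)
  result <- mutate(result, rank = row_number())
  ungroup(result)
}
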