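#' Order spectra for SSM display
#'
#' The two orderings used for visual QC of a spectra similarity matrix:
#' `by_date` (acquisition order — batch effects appear as diagonal blocks)
#' and `by_class_then_date` (diagnosis blocks first, date within class —
#' class structure appears as diagonal blocks separated by the returned
#' boundaries).  Sorting is stable with `(date, spectrum_id)` tie-breaks;
#' class blocks are ordered lexicographically.
#'
#' @param meta Metadata tibble (see [spectra_dataset()]).
#' @param strategy `"by_date"` or `"by_class_then_date"`.
#' @return List with `order` (integer permutation of rows) and `boundaries`
#'   (indices after which the primary key changes; empty for `by_date`).
#' @export
order_spectra <- function(meta, strategy = c("by_date", "by_class_then_date")) {
  strategy <- match.arg(strategy)
  meta <- validate_meta(meta)
  if (anyNA(meta$acquisition_date)) {
    bad <- meta$spectrum_id[which(is.na(meta$acquisition_date))[1]]
    abort(paste0("missing acquisition_date for spectrum ", bad),
          class = "ssmdr_validation_error")
  }
  if (strategy == "by_date") {
    ord <- order(meta$acquisition_date, meta$spectrum_id)
    boundaries <- integer(0)
  } else {
    cls <- as.character(meta$diagnosis)
    ord <- order(cls, meta$acquisition_date, meta$spectrum_id)
    sizes <- table(cls)
    boundaries <- as.integer(head(cumsum(sizes), -1L))
  }
  list(order = ord, boundaries = boundaries, strategy = strategy)
}

#' Cosine spectra similarity matrix (SSM)
#'
#' Every cell holds the cosine similarity
#' `dot(x_i, x_j) / (|x_i| |x_j|)` between two spectra.  Cosine is
#' scale-invariant per spectrum, so no intensity normalization is needed
#' upstream.  Zero-norm spectra (possible after aggressive thresholding)
#' get similarity 0 to everything, with a warning.
#'
#' @param dataset A [spectra_dataset()] (raw, thresholded, or an embedding
#'   fed back via [embedding_to_dataset()]).
#' @param order `NULL` (keep row order), an ordering strategy name accepted
#'   by [order_spectra()], or the list it returns.
#' @return An `ssm` object: `values` (n x n symmetric, diagonal 1 for
#'   non-degenerate spectra), `meta` (row-aligned, permuted), `order`,
#'   `boundaries`, `measure = "cosine"`.
#' @export
compute_ssm <- function(dataset, order = NULL) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  n <- nrow(dataset$values)
  if (n == 0) {
    abort("dataset is empty.", class = "ssmdr_validation_error")
  }
  ordering <- if (is.null(order)) {
    list(order = seq_len(n), boundaries = integer(0), strategy = "none")
  } else if (is.character(order)) {
    order_spectra(dataset$meta, order)
  } else {
    order
  }
  x <- dataset$values[ordering$order, , drop = FALSE]
  meta <- dataset$meta[ordering$order, , drop = FALSE]
  nrm <- sqrt(rowSums(x^2))
  zero <- nrm == 0
  if (any(zero)) {
    warn(sprintf("%d zero-norm spectrum/spectra: similarity set to 0 (%s%s)",
                 sum(zero), paste(head(meta$spectrum_id[zero], 3), collapse = ", "),
                 if (sum(zero) > 3) ", ..." else ""))
  }
  nrm[zero] <- 1
  xn <- x / nrm
  s <- tcrossprod(xn)
  s[zero, ] <- 0
  s[, zero] <- 0
  s <- pmin(pmax(s, -1), 1)
  s <- (s + t(s)) / 2
  d <- diag(s)
  d[!zero] <- 1
  diag(s) <- d
  structure(list(values = s, meta = meta, order = ordering$order,
                 boundaries = ordering$boundaries,
                 strategy = ordering$strategy, measure = "cosine"),
            class = "ssm")
}

#' @export
#' @method print ssm
print.ssm <- function(x, ...) {
  cat(sprintf("<ssm> %d x %d (%s), ordering: %s, %d boundary line(s)\n",
              nrow(x$values), ncol(x$values), x$measure, x$strategy,
              length(x$boundaries)))
  invisible(x)
}

#' Within- vs. between-block contrast of an SSM
#'
#' Quantifies what SSM images show qualitatively: with well-chosen features,
#' same-group spectra form high-similarity diagonal blocks separated by
#' low-similarity off-diagonal areas.  The statistic is
#' `contrast = mean(same-group similarity) - mean(different-group
#' similarity)`, diagonals excluded, with a label-permutation p-value using
#' the `(b + 1)/(n + 1)` estimator.  The statistic depends only on the
#' labels, not on the SSM's display ordering.
#'
#' @param ssm An [compute_ssm()] result.
#' @param labels Group label per spectrum aligned to `ssm` rows, or the name
#'   of a metadata column (e.g. `"diagnosis"`, `"batch_id"`).
#' @param n_perm Number of label shuffles for the p-value (default 999;
#'   0 skips the test).
#' @param seed Seed for the shuffles.
#' @return A one-row tibble: `grouping_key`, `within_mean`, `between_mean`,
#'   `contrast`, `p_value`, `n_perm`, plus a `per_class_within` list-column
#'   with the per-group within means.
#' @export
block_contrast <- function(ssm, labels, n_perm = 999L, seed = 1L) {
  stopifnot(inherits(ssm, "ssm"))
  key <- "labels"
  if (is.character(labels) && length(labels) == 1 && labels %in% names(ssm$meta)) {
    key <- labels
    labels <- ssm$meta[[labels]]
  }
  labels <- as.character(labels)
  n <- nrow(ssm$values)
  if (length(labels) != n) {
    abort("`labels` must align with the SSM rows.", class = "ssmdr_validation_error")
  }
  sizes <- table(labels)
  if (length(sizes) < 2) {
    abort("need at least 2 groups for a block contrast.",
          class = "ssmdr_validation_error")
  }
  if (any(sizes < 2)) {
    warn(paste0("group(s) with < 2 members contribute no within-group pairs: ",
                paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  s <- ssm$values

  stat <- function(lab) {
    g <- factor(lab)
    bs <- rowsum(t(rowsum(s, g)), g) # k x k block sums
    ng <- as.vector(table(g))
    d_self <- rowsum(diag(s), g)[, 1]
    within_sum <- sum(diag(bs) - d_self)
    within_pairs <- sum(ng * (ng - 1))
    between_sum <- sum(bs) - sum(diag(bs))
    between_pairs <- as.double(n)^2 - sum(as.double(ng)^2)
    c(within = within_sum / within_pairs, between = between_sum / between_pairs)
  }

  obs <- stat(labels)
  contrast <- unname(obs["within"] - obs["between"])

  g <- factor(labels)
  per_class <- {
    bs <- rowsum(t(rowsum(s, g)), g)
    ng <- as.vector(table(g))
    d_self <- rowsum(diag(s), g)[, 1]
    w <- (diag(bs) - d_self) / (ng * (ng - 1))
    tibble(group = levels(g), n = ng, within_mean = ifelse(ng > 1, w, NA_real_))
  }

  p <- NA_real_
  if (n_perm > 0) {
    perm <- with_seed(derive_seed(seed, 97L), {
      vapply(seq_len(n_perm), function(i) {
        o <- stat(sample(labels))
        unname(o["within"] - o["between"])
      }, numeric(1))
    })
    p <- (sum(perm >= contrast) + 1) / (n_perm + 1)
  }

  tibble(grouping_key = key,
         within_mean = unname(obs["within"]),
         between_mean = unname(obs["between"]),
         contrast = contrast,
         p_value = p,
         n_perm = as.integer(n_perm),
         per_class_within = list(per_class))
}

#' Heatmap of an SSM
#'
#' @param object An `ssm`.
#' @param color_limits Numeric `(lo, hi)` for the fill scale, or `NULL` for
#'   the data range.  SSM panels are only comparable when their color limits
#'   match, so the limits in use are attached as the plot's
#'   `color_limits` attribute and written to the sidecar by [render_ssm()].
#' @param ... Unused.
#' @return A ggplot object; block boundaries drawn as black lines.
#' @export
autoplot.ssm <- function(object, color_limits = NULL, ...) {
  n <- nrow(object$values)
  df <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n))
  df$value <- object$values[cbind(df$i, df$j)]
  lims <- color_limits %||% range(object$values)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = lims, name = object$measure) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("SSM (%d spectra, %s)", n, object$strategy)) +
    ggplot2::theme_minimal()
  if (length(object$boundaries)) {
    p <- p +
      ggplot2::geom_hline(yintercept = object$boundaries + 0.5, colour = "black") +
      ggplot2::geom_vline(xintercept = object$boundaries + 0.5, colour = "black")
  }
  attr(p, "color_limits") <- lims
  p
}

#' Render an SSM heatmap to an image file with a sidecar
#'
#' Writes the heatmap plus a JSON sidecar (`<path>.json`) recording the
#' color limits, ordering strategy, boundaries and spectrum order, so panels
#' rendered with different limits are never silently compared.
#'
#' @param ssm An `ssm`.
#' @param path Output image path (extension selects the device, e.g. `.png`).
#' @param color_limits See [autoplot.ssm()].
#' @param width,height,dpi Forwarded to [ggplot2::ggsave()].
#' @return `path`, invisibly.
#' @export
render_ssm <- function(ssm, path, color_limits = NULL,
                       width = 5, height = 4.5, dpi = 150) {
  p <- autoplot(ssm, color_limits = color_limits)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tryCatch(
    suppressMessages(ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi)),
    error = function(e) {
      abort(paste0("cannot write image: ", path, " (", conditionMessage(e), ")"),
            class = "ssmdr_io_error")
    })
  sidecar <- list(measure = ssm$measure,
                  color_limits = attr(p, "color_limits"),
                  ordering = ssm$strategy,
                  boundaries = ssm$boundaries,
                  spectrum_order = ssm$meta$spectrum_id)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write an SSM as CSV (ordering in the header row)
#'
#' @param ssm An `ssm`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ssm_csv <- function(ssm, path) {
  m <- as.data.frame(ssm$values)
  names(m) <- ssm$meta$spectrum_id
  readr::write_csv(m, path, progress = FALSE)
  invisible(path)
}
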