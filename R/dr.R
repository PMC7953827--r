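.dr_methods <- c("pca", "plsda", "nnmf", "isomap", "umap", "diffusion_map")

#' Specify a dimensionality-reduction method
#'
#' One uniform contract covers two linear methods (PCA; PLS-DA, the only
#' supervised one) and four nonlinear ones (NNMF, Isomap, UMAP, diffusion
#' map).  All six support out-of-sample projection of new spectra through
#' the fitted mapping — the package's inclusion criterion, which excludes
#' e.g. t-SNE.  Hyperparameters not set here keep the backing
#' implementation's defaults and are recorded in the fitted object's
#' provenance.
#'
#' @param method One of `"pca"`, `"plsda"`, `"nnmf"`, `"isomap"`, `"umap"`,
#'   `"diffusion_map"`.
#' @param n_components Target dimension k (typical grid 3, 5, 7).
#' @param n_neighbors Neighborhood size for Isomap and UMAP (default 5).
#' @param ... Extra parameters passed through to the backend (e.g.
#'   `metric = "cosine"` for UMAP's cosine variant, `max_iter` for NNMF).
#' @return A `dr_spec` list.
#' @export
dr_spec <- function(method, n_components, n_neighbors = 5L, ...) {
  method <- match.arg(method, .dr_methods)
  n_components <- as.integer(n_components)
  if (is.na(n_components) || n_components < 1) {
    abort("`n_components` must be an integer >= 1.", class = "ssmdr_validation_error")
  }
  if (n_neighbors < 1) {
    abort("`n_neighbors` must be >= 1.", class = "ssmdr_validation_error")
  }
  structure(list(method = method, n_components = n_components,
                 n_neighbors = as.integer(n_neighbors),
                 extra_params = list(...)),
            class = "dr_spec")
}

#' Fit a dimensionality reduction and embed a dataset
#'
#' @param dataset A [spectra_dataset()].
#' @param spec A [dr_spec()]; alternatively pass `method`/`n_components`
#'   through `...` for convenience.
#' @param labels Class labels (vector aligned to rows, or a metadata column
#'   name, default `"diagnosis"`); required for `plsda`, ignored otherwise.
#' @param seed Seed fixing any stochastic initialization (NNMF, UMAP).
#' @param ... Used to build a `dr_spec` when `spec` is a method name.
#' @return A `dr_embedding`: `coordinates` (n x k), `loadings` (k x n_bins
#'   for the linear methods and NNMF's H with nonnegative entries; `NULL`
#'   for neighbor-graph methods), `method`, `spec`, `provenance` (recorded
#'   backend parameters), `meta`, and a dataset `fingerprint` checked by
#'   [predict.dr_embedding()].
#' @examples
#' \donttest{
#' sim <- generate_spectra(synth_config(n_patients_per_class = 2), "positive")
#' emb <- fit_reduce(sim$dataset, "pca", n_components = 3)
#' glance(emb)
#' }
#' @export
fit_reduce <- function(dataset, spec, labels = "diagnosis", seed = 1L, ...) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  if (is.character(spec)) spec <- dr_spec(spec, ...)
  stopifnot(inherits(spec, "dr_spec"))
  x <- dataset$values
  n <- nrow(x)
  k <- spec$n_components
  if (k >= n) {
    abort(sprintf("n_components (%d) must be < the number of spectra (%d).", k, n),
          class = "ssmdr_validation_error")
  }
  uses_neighbors <- spec$method %in% c("isomap", "umap")
  if (uses_neighbors && spec$n_neighbors >= n) {
    abort("`n_neighbors` must be < the number of spectra.",
          class = "ssmdr_validation_error")
  }
  lab <- NULL
  if (spec$method == "plsda") {
    if (is.character(labels) && length(labels) == 1) {
      if (!labels %in% names(dataset$meta)) {
        abort("plsda requires class labels (metadata column not found).",
              class = "ssmdr_validation_error")
      }
      lab <- dataset$meta[[labels]]
    } else lab <- labels
    if (is.null(lab) || length(lab) != n || length(unique(lab)) < 2) {
      abort("plsda is supervised: provide >= 2 distinct class labels.",
            class = "ssmdr_validation_error")
    }
  }
  fitter <- switch(spec$method,
                   pca = fit_pca, plsda = fit_plsda, nnmf = fit_nnmf,
                   isomap = fit_isomap, umap = fit_umap,
                   diffusion_map = fit_diffusion)
  fit <- with_seed(derive_seed(seed, match(spec$method, .dr_methods)),
                   fitter(x, spec, lab))
  coords <- fit$coordinates
  rownames(coords) <- dataset$meta$spectrum_id
  colnames(coords) <- paste0(".dim", seq_len(ncol(coords)))
  structure(list(coordinates = coords,
                 loadings = fit$loadings,
                 method = spec$method,
                 spec = spec,
                 provenance = c(fit$provenance, list(seed = seed)),
                 model = fit$model,
                 meta = dataset$meta,
                 fingerprint = dataset_fingerprint(dataset)),
            class = "dr_embedding")
}

dataset_fingerprint <- function(dataset) {
  list(n_spectra = nrow(dataset$values),
       n_features = ncol(dataset$values),
       grid = if (!is.null(dataset$grid)) unclass(dataset$grid) else NULL,
       hash = rlang::hash(list(dim(dataset$values), dataset$meta$spectrum_id)))
}

# ---- backends ---------------------------------------------------------------

fit_pca <- function(x, spec, labels) {
  fit <- prcomp(x, center = TRUE, scale. = FALSE, rank. = spec$n_components)
  list(coordinates = fit$x[, seq_len(spec$n_components), drop = FALSE],
       loadings = t(fit$rotation),
       model = list(center = fit$center, rotation = fit$rotation),
       provenance = list(backend = "stats::prcomp", center = TRUE, scale = FALSE,
                         sdev = fit$sdev))
}

fit_plsda <- function(x, spec, labels) {
  keep <- which(apply(x, 2, function(col) max(col) > min(col)))
  xk <- x[, keep, drop = FALSE]
  colnames(xk) <- paste0("b", keep)
  fit <- mixOmics::plsda(xk, factor(labels),
                         ncomp = spec$n_components, scale = FALSE)
  load <- matrix(0, spec$n_components, ncol(x))
  load[, keep] <- t(unname(fit$loadings$X))
  list(coordinates = unname(fit$variates$X),
       loadings = load,
       model = list(fit = fit, keep = keep),
       provenance = list(backend = "mixOmics::plsda", scale = FALSE,
                         mode = fit$mode, kept_features = length(keep)))
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Lee--Seung updates for the Frobenius objective `|X - W H|_F`; both
#' factors stay nonnegative, and the objective is non-increasing across
#' iterations.  `W` holds per-spectrum coordinates, `H` the spectral
#' components.
#' @noRd
nmf_multiplicative <- function(x, k, max_iter = 200L, tol = 1e-5) {
  eps <- .Machine$double.eps
  n <- nrow(x); p <- ncol(x)
  scale0 <- sqrt(mean(x) / k + eps)
  w <- matrix(runif(n * k), n, k) * scale0
  h <- matrix(runif(k * p), k, p) * scale0
  obj <- numeric(0)
  last <- Inf
  for (it in seq_len(max_iter)) {
    h <- h * (crossprod(w, x)) / (crossprod(w) %*% h + eps)
    w <- w * (x %*% t(h)) / (w %*% tcrossprod(h) + eps)
    if (it %% 10L == 0L || it == max_iter) {
      e <- sqrt(sum((x - w %*% h)^2))
      obj <- c(obj, e)
      if (is.finite(last) && (last - e) < tol * last) break
      last <- e
    }
  }
  # polish W against the final components so coordinates are the exact
  # (convex) nonnegative least-squares solution given H — this makes
  # out-of-sample projection of a training row reproduce its coordinates
  w <- nnls_rows(x, h)
  obj <- c(obj, sqrt(sum((x - w %*% h)^2)))
  list(w = w, h = h, objective = obj)
}

#' Exact small-k nonnegative least squares, one row at a time
#'
#' Solves min_w >= 0 |x_i - w H|^2 per row by enumerating active sets
#' (k <= ~10), which is exact and deterministic.
#' @noRd
nnls_rows <- function(x, h) {
  k <- nrow(h)
  a <- tcrossprod(h)                 # k x k
  bmat <- tcrossprod(x, h)           # n x k
  subsets <- lapply(seq_len(2^k) - 1L, function(m) which(bitwAnd(m, 2^(seq_len(k) - 1L)) > 0))
  w <- matrix(0, nrow(x), k)
  for (i in seq_len(nrow(x))) {
    b <- bmat[i, ]
    best <- Inf
    best_w <- numeric(k)
    for (s in subsets) {
      wi <- numeric(k)
      if (length(s)) {
        sol <- tryCatch(solve(a[s, s, drop = FALSE], b[s]),
                        error = function(e) NULL)
        if (is.null(sol) || any(sol < 0)) next
        wi[s] <- sol
      }
      obj <- sum(wi * (a %*% wi)) - 2 * sum(wi * b)
      if (obj < best - 1e-12) {
        best <- obj
        best_w <- wi
      }
    }
    w[i, ] <- best_w
  }
  w
}

fit_nnmf <- function(x, spec, labels) {
  if (any(x < 0)) {
    abort("nnmf requires nonnegative input.", class = "ssmdr_validation_error")
  }
  max_iter <- spec$extra_params$max_iter %||% 200L
  tol <- spec$extra_params$tol %||% 1e-5
  fit <- nmf_multiplicative(x, spec$n_components, max_iter = max_iter, tol = tol)
  rel <- tail(fit$objective, 1) / sqrt(sum(x^2))
  list(coordinates = fit$w,
       loadings = fit$h,
       model = list(h = fit$h, max_iter = max_iter, tol = tol),
       provenance = list(backend = "ssmdr multiplicative-update NMF",
                         max_iter = max_iter, tol = tol,
                         objective = fit$objective,
                         relative_frobenius_error = rel))
}

#' Symmetrized kNN graph geodesics
#' @noRd
geodesic_distances <- function(d, n_neighbors) {
  n <- nrow(d)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nn <- order(d[i, ])[2:(n_neighbors + 1L)]
    adj[i, nn] <- TRUE
  }
  adj <- adj | t(adj)
  w <- d
  w[!adj] <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected", weighted = TRUE)
  comp <- igraph::components(g)
  bridges <- 0L
  while (comp$no > 1L) {
    # connect the two closest components by their shortest bridging edge
    main <- which(comp$membership == which.max(comp$csize))
    rest <- setdiff(seq_len(n), main)
    sub <- d[main, rest, drop = FALSE]
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    g <- igraph::add_edges(g, c(main[ij[1]], rest[ij[2]]),
                           weight = sub[ij[1], ij[2]])
    bridges <- bridges + 1L
    comp <- igraph::components(g)
  }
  list(geodesic = igraph::distances(g, weights = igraph::E(g)$weight),
       graph = g, bridges = bridges)
}

fit_isomap <- function(x, spec, labels) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  geo <- geodesic_distances(d, spec$n_neighbors)
  d2 <- geo$geodesic^2
  mu <- rowMeans(d2)
  b <- -0.5 * (sweep(sweep(d2, 1, mu), 2, mu) + mean(d2))
  eig <- eigen(b, symmetric = TRUE)
  k <- spec$n_components
  pos <- which(eig$values > 1e-9)[seq_len(min(k, sum(eig$values > 1e-9)))]
  vals <- eig$values[pos]
  vecs <- fix_eigen_sign(eig$vectors[, pos, drop = FALSE])
  coords <- sweep(vecs, 2, sqrt(vals), "*")
  if (ncol(coords) < k) {
    coords <- cbind(coords, matrix(0, n, k - ncol(coords)))
  }
  list(coordinates = coords,
       loadings = NULL,
       model = list(x = x, geodesic = geo$geodesic, mu = mu,
                    vectors = vecs, values = vals,
                    n_neighbors = spec$n_neighbors, k = k),
       provenance = list(backend = "ssmdr Isomap (igraph geodesics + classical MDS)",
                         n_neighbors = spec$n_neighbors,
                         component_bridges = geo$bridges,
                         eigenvalues = vals))
}

# deterministic sign: largest-magnitude element of each eigenvector positive
fix_eigen_sign <- function(v) {
  s <- apply(v, 2, function(col) sign(col[which.max(abs(col))]))
  sweep(v, 2, ifelse(s == 0, 1, s), "*")
}

fit_umap <- function(x, spec, labels) {
  metric <- spec$extra_params$metric %||% "euclidean"
  fit <- uwot::umap(x, n_neighbors = spec$n_neighbors,
                    n_components = spec$n_components,
                    metric = metric, ret_model = TRUE,
                    n_sgd_threads = 0, n_threads = 1)
  list(coordinates = unname(fit$embedding),
       loadings = NULL,
       model = list(fit = fit),
       provenance = list(backend = "uwot::umap", metric = metric,
                         n_neighbors = spec$n_neighbors,
                         min_dist = fit$min_dist %||% 0.1,
                         n_epochs = fit$n_epochs))
}

fit_diffusion <- function(x, spec, labels) {
  d <- as.matrix(dist(x))
  sigma <- spec$extra_params$sigma %||% median(d[upper.tri(d)])
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  kern <- exp(-d^2 / (2 * sigma^2))
  q <- rowSums(kern)
  k1 <- kern / (q %o% q) # alpha = 1 density normalization
  d1 <- rowSums(k1)
  s <- k1 / sqrt(d1 %o% d1)
  eig <- eigen((s + t(s)) / 2, symmetric = TRUE)
  k <- spec$n_components
  idx <- 2:(k + 1L) # skip the trivial stationary eigenvector
  lambda <- eig$values[idx]
  psi <- fix_eigen_sign(eig$vectors[, idx, drop = FALSE] / sqrt(d1))
  coords <- sweep(psi, 2, lambda, "*")
  list(coordinates = coords,
       loadings = NULL,
       model = list(x = x, sigma = sigma, q = q, psi = psi, lambda = lambda),
       provenance = list(backend = "ssmdr diffusion map (alpha = 1, Nystrom extension)",
                         sigma = sigma, eigenvalues = lambda))
}

# ---- out-of-sample transform ------------------------------------------------

#' Project new spectra through a fitted DR mapping
#'
#' Out-of-sample extension without refitting: PCA and PLS-DA apply their
#' linear maps; NNMF solves for new nonnegative coordinates with the fitted
#' components held fixed; Isomap embeds via graph-distance extension of the
#' classical-MDS solution; the diffusion map uses a Nystrom extension; UMAP
#' uses `uwot::umap_transform()`.  Projecting an exact copy of a training
#' spectrum reproduces its training coordinates (exactly for the spectral
#' methods, to optimizer tolerance for NNMF, and to its nearest embedded
#' neighbor for UMAP's stochastic refinement).
#'
#' @param object A `dr_embedding` from [fit_reduce()].
#' @param new_dataset A [spectra_dataset()] on the same bin grid.
#' @param seed Seed for stochastic backends (UMAP).
#' @param ... Unused.
#' @return Matrix of coordinates, `nrow(new_dataset)` x k.
#' @export
predict.dr_embedding <- function(object, new_dataset, seed = 1L, ...) {
  stopifnot(inherits(new_dataset, "spectra_dataset"))
  x <- new_dataset$values
  if (ncol(x) != object$fingerprint$n_features) {
    abort(sprintf("new data has %d features; the mapping was fitted on %d.",
                  ncol(x), object$fingerprint$n_features),
          class = "ssmdr_validation_error")
  }
  fp_grid <- object$fingerprint$grid
  if (!is.null(fp_grid) && !is.null(new_dataset$grid) &&
      !grid_equal(new_dataset$grid, do.call(bin_grid, fp_grid[c("start", "stop", "width")]))) {
    abort("new data is on a different bin grid than the fitted mapping.",
          class = "ssmdr_validation_error")
  }
  k <- object$spec$n_components
  m <- object$model
  coords <- switch(
    object$method,
    pca = sweep(x, 2, m$center) %*% m$rotation[, seq_len(k), drop = FALSE],
    plsda = {
      xk <- x[, m$keep, drop = FALSE]
      colnames(xk) <- paste0("b", m$keep)
      pr <- predict(m$fit, xk)
      unname(pr$variates[, seq_len(k), drop = FALSE])
    },
    nnmf = with_seed(derive_seed(seed, 53L),
                     nmf_project(x, m$h, m$max_iter, m$tol)),
    isomap = isomap_project(x, m),
    umap = with_seed(derive_seed(seed, 54L), {
      uwot::umap_transform(x, m$fit, n_sgd_threads = 0, n_threads = 1)
    }),
    diffusion_map = diffusion_project(x, m)
  )
  coords <- unname(as.matrix(coords))
  rownames(coords) <- new_dataset$meta$spectrum_id
  colnames(coords) <- paste0(".dim", seq_len(ncol(coords)))
  coords
}

nmf_project <- function(x, h, max_iter = NULL, tol = NULL) {
  nnls_rows(x, h)
}

isomap_project <- function(x, m) {
  n <- nrow(m$x)
  vapply_rows <- function(new_row) {
    de <- sqrt(colSums((t(m$x) - new_row)^2))
    nn <- order(de)[seq_len(m$n_neighbors)]
    dg <- apply(m$geodesic[nn, , drop = FALSE] + de[nn], 2, min)
    (crossprod(m$vectors, m$mu - dg^2) / (2 * sqrt(m$values)))[, 1]
  }
  out <- t(apply(x, 1, vapply_rows))
  if (ncol(out) < m$k) out <- cbind(out, matrix(0, nrow(out), m$k - ncol(out)))
  out
}

diffusion_project <- function(x, m) {
  d2 <- outer(rowSums(x^2), rowSums(m$x^2), "+") - 2 * tcrossprod(x, m$x)
  d <- sqrt(pmax(d2, 0))
  kern <- exp(-d^2 / (2 * m$sigma^2))
  qn <- rowSums(kern)
  k1 <- kern / (qn %o% m$q)
  p <- k1 / rowSums(k1)
  p %*% m$psi
}

# ---- result surface ---------------------------------------------------------

#' @export
#' @method print dr_embedding
print.dr_embedding <- function(x, ...) {
  cat(sprintf("<dr_embedding> %s, %d spectra -> %d components\n",
              x$method, nrow(x$coordinates), ncol(x$coordinates)))
  invisible(x)
}

#' Turn an embedding back into a dataset for the similarity stage
#'
#' Wraps the k coordinates as a k-feature [spectra_dataset()] (no bin grid)
#' so the SSM of a reduced representation is computed exactly like the SSM
#' of spectra.  Coordinates of most methods may be negative; the similarity
#' stage accepts that (cosine then lies in \[-1, 1\]).
#'
#' @param embedding A `dr_embedding`.
#' @param meta Metadata tibble; defaults to the metadata captured at fit time.
#' @return A `spectra_dataset` with k features.
#' @export
embedding_to_dataset <- function(embedding, meta = NULL) {
  stopifnot(inherits(embedding, "dr_embedding"))
  meta <- meta %||% embedding$meta
  if (nrow(embedding$coordinates) == 0) {
    abort("embedding is empty.", class = "ssmdr_validation_error")
  }
  if (nrow(meta) != nrow(embedding$coordinates)) {
    abort("metadata rows do not match embedding rows.",
          class = "ssmdr_validation_error")
  }
  spectra_dataset(unname(embedding$coordinates), meta, grid = NULL,
                  allow_negative = TRUE)
}

#' @export
tidy.dr_embedding <- function(x, ...) {
  dplyr::bind_cols(x$meta, as_tibble(x$coordinates))
}

#' @export
glance.dr_embedding <- function(x, ...) {
  extra <- switch(x$method,
                  pca = {
                    sd <- x$provenance$sdev
                    sum(sd[seq_len(ncol(x$coordinates))]^2) / sum(sd^2)
                  },
                  nnmf = x$provenance$relative_frobenius_error,
                  NA_real_)
  tibble(method = x$method,
         n_components = ncol(x$coordinates),
         n_spectra = nrow(x$coordinates),
         n_features = x$fingerprint$n_features,
         n_neighbors = if (x$method %in% c("isomap", "umap")) x$spec$n_neighbors else NA_integer_,
         fit_quality = extra)
}

#' @export
autoplot.dr_embedding <- function(object, colour = "diagnosis", ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$.dim1, y = .data$.dim2,
                                   colour = .data[[colour]])) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(title = sprintf("%s embedding", object$method)) +
    ggplot2::theme_minimal()
}
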