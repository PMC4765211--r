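#' Fit a principal component model to an expression database
#'
#' Computes the top principal directions of the samples by singular value
#' decomposition of the mean-centered samples x features matrix. No
#' per-feature variance scaling is applied: the input is assumed to be
#' already log2-normalized expression. Each component's sign is fixed so
#' that its largest-magnitude loading is positive, making the fit
#' deterministic across linear-algebra backends.
#'
#' Queries against an index must be projected with the database-fitted
#' model (see [pca_transform()]), never refitted.
#'
#' @param x an [expression_matrix()] (features x samples).
#' @param n_components number of components to retain; default 10, the
#'   dimensionality at which metric-tree search of expression data stays
#'   efficient. A warning (not an error) is issued above 30, where tree
#'   pruning degrades.
#' @return An object of class `pca_model`: list with `mean` (feature means,
#'   length p), `components` (`n_components x p`, orthonormal rows),
#'   `explained_variance_fraction` (non-increasing, sums to <= 1), and
#'   `feature_ids`.
#' @export
fit_pca <- function(x, n_components = 10L) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  n_components <- as.integer(n_components)
  p <- n_features(x)
  n <- n_samples(x)
  if (n_components < 1L || n_components > min(p, n))
    stop(sprintf(
      "parameter error: n_components must be in [1, min(p=%d, n=%d)]", p, n),
      call. = FALSE)
  if (n_components > 30L)
    warning("n_components > 30: metric-tree search degrades in high ",
            "dimension; consider a smaller reduced space", call. = FALSE)
  xs <- t(x$values)                       # n x p, samples in rows
  mu <- colMeans(xs)
  xc <- sweep(xs, 2L, mu, "-")
  sv <- svd(xc, nu = 0L, nv = n_components)
  comp <- t(sv$v)                         # n_components x p
  # sign convention: largest-|loading| positive
  for (i in seq_len(nrow(comp))) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  total_var <- sum(sv$d^2)
  evf <- if (total_var > 0) sv$d[seq_len(n_components)]^2 / total_var
         else rep(0, n_components)
  structure(
    list(mean = mu, components = comp,
         explained_variance_fraction = evf,
         feature_ids = x$feature_ids),
    class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d components over %d features; cumulative variance %.3f\n",
              nrow(x$components), ncol(x$components),
              sum(x$explained_variance_fraction)))
  invisible(x)
}

#' Project vectors into a fitted principal component space
#'
#' Computes `components %*% (v - mean)` for each input vector. The map is an
#' orthogonal projection of centered data, so it never increases Euclidean
#' distance between any pair of vectors, and at full rank it preserves
#' distances exactly.
#'
#' @param model a [fit_pca()] model.
#' @param x numeric vector of length p, or a p x m matrix of column vectors.
#' @return A vector of length `n_components`, or an `n_components x m`
#'   matrix.
#' @export
pca_transform <- function(model, x) {
  stopifnot(inherits(model, "pca_model"))
  p <- ncol(model$components)
  if (is.matrix(x)) {
    if (nrow(x) != p)
      stop(sprintf("dimension error: expected %d rows, got %d", p, nrow(x)),
           call. = FALSE)
    model$components %*% (x - model$mean)
  } else {
    if (length(x) != p)
      stop(sprintf("dimension error: expected length %d, got %d", p,
                   length(x)), call. = FALSE)
    drop(model$components %*% (x - model$mean))
  }
}

#' Cumulative explained variance per retained component count
#'
#' @param model a [fit_pca()] model.
#' @return Numeric vector: entry k is the fraction of total variance
#'   captured by the first k components (non-decreasing).
#' @export
variance_report <- function(model) {
  stopifnot(inherits(model, "pca_model"))
  cumsum(model$explained_variance_fraction)
}
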