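#' Construct an expression matrix
#'
#' The database record store: a features x samples matrix of log2-normalized
#' expression values with unique sample and feature identifiers. All values
#' must be finite; non-finite entries are rejected at construction time
#' rather than imputed, since silent imputation would corrupt downstream
#' distances.
#'
#' @param values numeric matrix, shape `(n_features, n_samples)`.
#' @param feature_ids character vector of unique gene/feature identifiers,
#'   length `nrow(values)`.
#' @param sample_ids character vector of unique sample identifiers, length
#'   `ncol(values)`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix, with dimnames set), `feature_ids`, `sample_ids`.
#' @examples
#' m <- expression_matrix(matrix(0, 3, 2), c("g1", "g2", "g3"), c("s1", "s2"))
#' n_samples(m)
#' @export
expression_matrix <- function(values, feature_ids, sample_ids) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) == 0L)
    stop("validation error: at least one sample is required", call. = FALSE)
  if (length(feature_ids) == 0L)
    stop("validation error: at least one feature is required", call. = FALSE)
  if (nrow(values) != length(feature_ids))
    stop(sprintf(
      "consistency error: 'Data' has %d rows but %d feature ids",
      nrow(values), length(feature_ids)), call. = FALSE)
  if (ncol(values) != length(sample_ids))
    stop(sprintf(
      "consistency error: 'Data' has %d columns but %d sample ids",
      ncol(values), length(sample_ids)), call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("validation error: duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(feature_ids))
    stop("validation error: duplicate feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(values)))
    stop("validation error: expression values must be finite (no NA/NaN/Inf)",
         call. = FALSE)
  storage.mode(values) <- "double"
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(
    list(values = values, feature_ids = feature_ids, sample_ids = sample_ids),
    class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples\n",
              length(x$feature_ids), length(x$sample_ids)))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x an `ExpressionMatrix`.
#' @export
n_samples <- function(x) length(x$sample_ids)

#' @rdname expression_matrix
#' @export
n_features <- function(x) length(x$feature_ids)

#' Construct a single-sample profile vector
#'
#' One sample's expression vector, possibly PCA-reduced, carrying feature
#' provenance so it can be aligned against a database's feature order.
#'
#' @param sample_id sample identifier.
#' @param values finite numeric vector, length > 0.
#' @param feature_ids optional character vector of feature ids (same length
#'   as `values`); required for raw-space queries that must be aligned.
#' @param space one of `"raw"` or `"pca"`, recording which space the vector
#'   lives in.
#' @return An object of class `ProfileVector`.
#' @export
profile_vector <- function(sample_id, values, feature_ids = NULL,
                           space = c("raw", "pca")) {
  space <- match.arg(space)
  values <- as.double(values)
  if (length(values) == 0L)
    stop("validation error: profile vector must be non-empty", call. = FALSE)
  if (!all(is.finite(values)))
    stop("validation error: profile values must be finite", call. = FALSE)
  if (!is.null(feature_ids)) {
    feature_ids <- as.character(feature_ids)
    if (length(feature_ids) != length(values))
      stop("dimension error: feature_ids and values lengths differ",
           call. = FALSE)
  }
  structure(
    list(sample_id = as.character(sample_id)[1], values = values,
         feature_ids = feature_ids, space = space),
    class = "ProfileVector")
}

#' @export
print.ProfileVector <- function(x, ...) {
  cat(sprintf("ProfileVector '%s': %d values (%s space)\n",
              x$sample_id, length(x$values), x$space))
  invisible(x)
}

#' Euclidean distance between two equal-length vectors
#'
#' The default metric: the L2 norm of `a - b`. In the intended workflow the
#' inputs are expression profiles after principal component transformation.
#'
#' @param a,b finite numeric vectors of equal length.
#' @return Non-negative scalar distance.
#' @examples
#' euclidean_distance(c(3, 0), c(0, 4)) # 5
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b))
    stop(sprintf("dimension error: vector lengths differ (%d vs %d)",
                 length(a), length(b)), call. = FALSE)
  sqrt(sum((a - b)^2))
}

#' Vantage-point distance lower bound
#'
#' Given the query-to-vantage distance `d_qp` and the vantage-to-record
#' distance `d_ps`, returns `|d_qp - d_ps|`, which by the triangle inequality
#' never exceeds the true query-to-record distance for any metric. This lower
#' bound is what makes subtree fathoming sound.
#'
#' @param d_qp,d_ps non-negative distances.
#' @return `|d_qp - d_ps|`, a non-negative lower bound on `d(q, s)`.
#' @export
vantage_lower_bound <- function(d_qp, d_ps) {
  if (any(d_qp < 0) || any(d_ps < 0))
    stop("domain error: distances must be non-negative", call. = FALSE)
  abs(d_qp - d_ps)
}

#' Define a distance metric
#'
#' A metric pairs a name (used in persisted index files) with a binary
#' distance function on equal-length numeric vectors. The function must be a
#' true metric — symmetric, non-negative, zero on identical inputs, and
#' satisfying the triangle inequality — for pruned search to remain exact.
#' An optional vectorized form `fn_many(x, m)` computing distances from one
#' vector to every column of a matrix is used to speed up tree construction
#' and brute-force scans; it must agree with `fn` exactly.
#'
#' @param name string identifier.
#' @param fn function `(a, b) -> distance`.
#' @param fn_many optional function `(x, m) -> numeric` of `ncol(m)`
#'   distances; defaults to a column loop over `fn`.
#' @return An object of class `vps_metric`.
#' @export
metric <- function(name, fn, fn_many = NULL) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  if (is.null(fn_many)) {
    fn_many <- function(x, m) vapply(seq_len(ncol(m)),
                                     function(j) fn(x, m[, j]), numeric(1))
  }
  structure(list(name = name, fn = fn, fn_many = fn_many),
            class = "vps_metric")
}

#' @rdname metric
#' @export
metric_euclidean <- function() {
  metric("euclidean",
         fn = euclidean_distance,
         fn_many = function(x, m) {
           if (length(x) != nrow(m))
             stop("dimension error: vector lengths differ", call. = FALSE)
           sqrt(.colSums((m - x)^2, nrow(m), ncol(m)))
         })
}

#' @rdname metric
#' @export
metric_manhattan <- function() {
  metric("manhattan",
         fn = function(a, b) {
           if (length(a) != length(b))
             stop("dimension error: vector lengths differ", call. = FALSE)
           sum(abs(a - b))
         },
         fn_many = function(x, m) .colSums(abs(m - x), nrow(m), ncol(m)))
}

#' Look up a registered metric by name
#'
#' Used when reloading a persisted index, which stores only the metric name.
#' `euclidean` and `manhattan` are built in; additional metrics can be
#' registered with [register_metric()].
#'
#' @param name metric name.
#' @return A `vps_metric`.
#' @export
get_metric <- function(name) {
  if (is.null(.metric_registry[[name]]))
    stop(sprintf("unknown metric '%s'; registered: %s", name,
                 paste(ls(.metric_registry), collapse = ", ")), call. = FALSE)
  .metric_registry[[name]]()
}

.metric_registry <- new.env(parent = emptyenv())

#' @rdname get_metric
#' @param constructor zero-argument function returning a `vps_metric` whose
#'   `name` equals `name`.
#' @export
register_metric <- function(name, constructor) {
  stopifnot(is.function(constructor))
  assign(name, constructor, envir = .metric_registry)
  invisible(name)
}

# built-ins
local({
  assign("euclidean", metric_euclidean, envir = .metric_registry)
  assign("manhattan", metric_manhattan, envir = .metric_registry)
})

#' Construct a search result
#'
#' Ranked hits plus instrumentation. Distances are non-decreasing; ties at
#' equal distance are ordered lexicographically by sample id. The
#' distance-evaluation count is the hardware-independent cost measure used
#' throughout benchmarking.
#'
#' @param sample_ids character vector of hit ids (unique).
#' @param distances non-negative distances, ascending.
#' @param n_distance_evals number of metric evaluations spent on the query.
#' @return An object of class `SearchResult` with elements `hits`
#'   (data.frame `sample_id`, `distance`) and `n_distance_evals`.
#' @export
search_result <- function(sample_ids, distances, n_distance_evals) {
  sample_ids <- as.character(sample_ids)
  distances <- as.double(distances)
  stopifnot(length(sample_ids) == length(distances))
  if (anyDuplicated(sample_ids))
    stop("invalid result: duplicate sample ids", call. = FALSE)
  if (length(distances) && (any(distances < 0) || is.unsorted(distances)))
    stop("invalid result: distances must be non-negative and ascending",
         call. = FALSE)
  structure(
    list(hits = data.frame(sample_id = sample_ids, distance = distances,
                           stringsAsFactors = FALSE),
         n_distance_evals = as.integer(n_distance_evals)),
    class = "SearchResult")
}

#' @export
print.SearchResult <- function(x, ...) {
  cat(sprintf("SearchResult: %d hits (%d distance evaluations)\n",
              nrow(x$hits), x$n_distance_evals))
  if (nrow(x$hits)) print(x$hits, row.names = FALSE)
  invisible(x)
}

# Order hit candidates by (distance, sample_id): the package-wide tie-break.
rank_hits <- function(ids, d) order(d, ids, method = "radix")
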