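#' Build a search index over an expression database
#'
#' The end-to-end build step: optionally fits a PCA model to the database
#' (see [fit_pca()]), projects every sample into the reduced space, and
#' constructs the vantage-point tree over the projected vectors. With
#' `n_components = NULL` the tree indexes the raw expression vectors — the
#' right choice for small feature counts and required for non-Euclidean
#' metrics, since PCA distance contraction is a Euclidean argument.
#'
#' @param matrix an [expression_matrix()].
#' @param n_components components to retain, or `NULL` to index raw
#'   vectors; default 10.
#' @param metric metric name (see [get_metric()]) or a [metric()] object.
#' @param seed integer seed for vantage-point selection.
#' @return An object of class `vps_index`: `format_version`, `pca` (model
#'   or `NULL`), `tree` (a `vp_tree` over the reduced vectors) and
#'   `feature_ids` (the database's raw feature order).
#' @examples
#' db <- generate_profiles(synthetic_spec(n_per_cluster = c(10, 10),
#'                                        n_features = 20))
#' idx <- build_index(db$matrix, n_components = 2)
#' q <- profile_vector("q", db$matrix$values[, 1],
#'                     feature_ids = db$matrix$feature_ids)
#' search_index(idx, q, k = 3)
#' @export
build_index <- function(matrix, n_components = 10L, metric = "euclidean",
                        seed = 1L) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (is.character(metric)) metric <- get_metric(metric)
  stopifnot(inherits(metric, "vps_metric"))
  pca <- NULL
  vectors <- matrix$values
  if (!is.null(n_components)) {
    pca <- fit_pca(matrix, n_components)
    # project one sample at a time, through the same code path a query
    # takes: batch BLAS rounds differently at the last bit, which would
    # break exact distance-0 self-matches
    vectors <- vapply(seq_len(ncol(matrix$values)),
                      function(j) pca_transform(pca, matrix$values[, j]),
                      numeric(nrow(pca$components)))
    if (!is.matrix(vectors)) vectors <- matrix(vectors, nrow = 1L)
  }
  dimnames(vectors) <- list(NULL, matrix$sample_ids)
  tree <- build_vptree(vectors, metric = metric, seed = seed)
  structure(list(format_version = INDEX_FORMAT_VERSION, pca = pca,
                 tree = tree, feature_ids = matrix$feature_ids),
            class = "vps_index")
}

#' @export
print.vps_index <- function(x, ...) {
  cat(sprintf(
    "vps_index: %d records, %s space (dim %d), metric '%s', format v%d\n",
    length(x$tree$sample_ids), if (is.null(x$pca)) "raw" else "PCA",
    nrow(x$tree$vectors), x$tree$metric$name, x$format_version))
  invisible(x)
}

#' Query a search index
#'
#' Aligns a raw-space query to the index's feature order, projects it with
#' the index's PCA model (never refitting), and runs the exact pruned
#' k-nearest-neighbor search. A numeric vector or a `"pca"`-space
#' [profile_vector()] is taken to be in the tree's space already.
#'
#' @param index a [build_index()] / [load_index()] object.
#' @param query a [profile_vector()] (raw space, with feature ids) or a
#'   numeric vector already in the index's search space.
#' @param k number of hits; default 10.
#' @param exclude_self drop the query's own database record (matched by
#'   sample id at distance 0) from the hits.
#' @return A [search_result()].
#' @export
search_index <- function(index, query, k = 10L, exclude_self = FALSE) {
  stopifnot(inherits(index, "vps_index"))
  query_id <- NULL
  if (inherits(query, "ProfileVector")) {
    query_id <- query$sample_id
    if (query$space == "raw") {
      vals <- align_query(query, index$feature_ids)
      q <- if (is.null(index$pca)) vals else pca_transform(index$pca, vals)
    } else {
      q <- query$values
    }
  } else {
    q <- as.double(query)
  }
  search_knn(index$tree, q, k = k, exclude_self = exclude_self,
             query_id = query_id)
}
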