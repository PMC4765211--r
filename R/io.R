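#' Read an expression database from HDF5
#'
#' The database dialect is a single HDF5 file with exactly three root-level
#' datasets: `"Sample"` (n sample-id strings), `"Feature"` (p feature-id
#' strings) and `"Data"`, the p x n (features x samples) matrix of
#' log2-normalized expression values stored as float64. Malformed files are
#' rejected, never silently repaired. Note that a transposed `"Data"` matrix
#' is detectable only through a dimension mismatch with the id vectors; a
#' square matrix with swapped orientation cannot be caught.
#'
#' @param path HDF5 file path.
#' @return An [expression_matrix()].
#' @export
read_database <- function(path) {
  if (!file.exists(path))
    stop(sprintf("I/O error: no such file: %s", path), call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- tryCatch(rhdf5::h5ls(path),
                 error = function(e) stop(sprintf(
                   "format error: not a readable HDF5 file: %s", path),
                   call. = FALSE))
  root <- ls$name[ls$group == "/"]
  for (needed in c("Sample", "Feature", "Data"))
    if (!needed %in% root)
      stop(sprintf("format error: missing dataset '%s' in %s", needed, path),
           call. = FALSE)
  samples <- as.character(rhdf5::h5read(path, "Sample"))
  features <- as.character(rhdf5::h5read(path, "Feature"))
  values <- rhdf5::h5read(path, "Data")
  if (length(dim(values)) != 2L)
    stop("consistency error: 'Data' must be a 2-D matrix", call. = FALSE)
  # stored C-order (features x samples), i.e. transposed from rhdf5's view
  expression_matrix(t(as.matrix(values)), features, samples)
}

#' Write an expression database to HDF5
#'
#' Inverse of [read_database()]: emits the `"Sample"`/`"Feature"`/`"Data"`
#' dialect with variable-length UTF-8 string datasets and a float64 matrix.
#' An existing file at `path` is replaced.
#'
#' @param matrix an [expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_database <- function(matrix, path) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  if (file.exists(path)) unlink(path)
  ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
  if (!isTRUE(ok))
    stop(sprintf("I/O error: cannot create file: %s", path), call. = FALSE)
  rhdf5::h5write(matrix$sample_ids, path, "Sample",
                 variableLengthString = TRUE, encoding = "UTF-8")
  rhdf5::h5write(matrix$feature_ids, path, "Feature",
                 variableLengthString = TRUE, encoding = "UTF-8")
  # transpose so the dataset's C-order shape is (features, samples),
  # matching files produced by row-major (numpy/h5py) writers of the dialect
  rhdf5::h5write(t(unname(matrix$values)), path, "Data")
  invisible(path)
}

#' Read a query profile from HDF5 or CSV
#'
#' HDF5 queries use the database dialect with exactly one sample column.
#' CSV queries come in two dialects (comma delimiter, `.` decimal, UTF-8):
#' (a) two columns `feature,value` with that header, one feature per row, or
#' (b) a header row of feature ids followed by a single row of values.
#' A two-column file whose header is not `feature,value` and which has a
#' single data row is parsed as dialect (b). The query's sample id is taken
#' from the HDF5 `"Sample"` entry, or the file's base name for CSV.
#'
#' @param path query file path (format detected from content: HDF5
#'   signature vs. text).
#' @return A raw-space [profile_vector()] carrying feature ids.
#' @export
read_query <- function(path) {
  if (!file.exists(path))
    stop(sprintf("I/O error: no such file: %s", path), call. = FALSE)
  is_h5 <- tryCatch(isTRUE(rhdf5::H5Fis_hdf5(path)),
                    error = function(e) FALSE)
  if (is_h5) {
    db <- read_database(path)
    if (n_samples(db) != 1L)
      stop(sprintf(
        "ambiguity error: query file has %d sample columns, expected 1",
        n_samples(db)), call. = FALSE)
    return(profile_vector(db$sample_ids[1], db$values[, 1],
                          feature_ids = db$feature_ids, space = "raw"))
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8"),
    error = function(e) stop(sprintf("format error: unparsable CSV: %s",
                                     conditionMessage(e)), call. = FALSE))
  sid <- sub("\\.[^.]*$", "", basename(path))
  if (ncol(df) == 2L &&
      identical(tolower(names(df)), c("feature", "value"))) {
    vals <- suppressWarnings(as.numeric(df[[2]]))
    if (anyNA(vals))
      stop("format error: non-numeric values in CSV query", call. = FALSE)
    return(profile_vector(sid, vals, feature_ids = as.character(df[[1]]),
                          space = "raw"))
  }
  if (nrow(df) == 1L) {
    vals <- suppressWarnings(as.numeric(unlist(df[1, ], use.names = FALSE)))
    if (anyNA(vals))
      stop("format error: non-numeric values in CSV query", call. = FALSE)
    return(profile_vector(sid, vals, feature_ids = names(df), space = "raw"))
  }
  stop("format error: CSV query must be either a 'feature,value' table or ",
       "a header row of feature ids plus one value row", call. = FALSE)
}

#' Align a query's features to a database's feature order
#'
#' Reorders the query values to the database's feature order. Every database
#' feature must be present in the query (absentees raise an error listing
#' them); query features absent from the database are dropped with a
#' warning.
#'
#' @param query a [profile_vector()] carrying feature ids.
#' @param feature_ids the database's ordered feature ids.
#' @return Numeric vector in database feature order.
#' @export
align_query <- function(query, feature_ids) {
  stopifnot(inherits(query, "ProfileVector"))
  if (is.null(query$feature_ids))
    stop("query carries no feature ids; cannot align", call. = FALSE)
  missing <- setdiff(feature_ids, query$feature_ids)
  if (length(missing))
    stop(sprintf("missing-feature error: query lacks %d database feature(s): %s",
                 length(missing),
                 paste(utils::head(missing, 10), collapse = ", ")),
         call. = FALSE)
  extra <- setdiff(query$feature_ids, feature_ids)
  if (length(extra))
    warning(sprintf("dropping %d query feature(s) absent from the database",
                    length(extra)), call. = FALSE)
  query$values[match(feature_ids, query$feature_ids)]
}

INDEX_FORMAT_VERSION <- 1L

#' Persist a search index to a versioned HDF5 container
#'
#' Layout: `/meta` (format_version, metric_name, seed, has_pca), `/pca`
#' (mean, components, explained_variance; present only for PCA-backed
#' indexes), `/tree` (per-node arrays: vantage record index, mu, left and
#' right child indexes, with -1 as the leaf/absent sentinel) and `/vectors`
#' (the reduced record matrix plus sample ids and original feature ids).
#' A reloaded index reproduces bit-identical search results.
#'
#' @param index a [build_index()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "vps_index"))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  if (file.exists(path)) unlink(path)
  ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
  if (!isTRUE(ok))
    stop(sprintf("I/O error: cannot create file: %s", path), call. = FALSE)
  for (g in c("meta", "tree", "vectors")) rhdf5::h5createGroup(path, g)
  rhdf5::h5write(INDEX_FORMAT_VERSION, path, "meta/format_version")
  rhdf5::h5write(index$tree$metric$name, path, "meta/metric_name",
                 variableLengthString = TRUE, encoding = "UTF-8")
  rhdf5::h5write(index$tree$seed, path, "meta/seed")
  rhdf5::h5write(as.integer(!is.null(index$pca)), path, "meta/has_pca")
  rhdf5::h5write(index$tree$n_build_evals, path, "meta/n_build_evals")
  if (!is.null(index$pca)) {
    rhdf5::h5createGroup(path, "pca")
    rhdf5::h5write(index$pca$mean, path, "pca/mean")
    rhdf5::h5write(index$pca$components, path, "pca/components")
    rhdf5::h5write(index$pca$explained_variance_fraction, path,
                   "pca/explained_variance")
  }
  tr <- index$tree
  na_to_sentinel <- function(x) { x[is.na(x)] <- -1; x }
  rhdf5::h5write(as.integer(tr$vantage), path, "tree/vantage")
  rhdf5::h5write(na_to_sentinel(tr$mu), path, "tree/mu")
  rhdf5::h5write(na_to_sentinel(as.integer(tr$left)), path, "tree/left")
  rhdf5::h5write(na_to_sentinel(as.integer(tr$right)), path, "tree/right")
  rhdf5::h5write(unname(tr$vectors), path, "vectors/data")
  rhdf5::h5write(tr$sample_ids, path, "vectors/sample_ids",
                 variableLengthString = TRUE, encoding = "UTF-8")
  rhdf5::h5write(index$feature_ids, path, "vectors/feature_ids",
                 variableLengthString = TRUE, encoding = "UTF-8")
  invisible(path)
}

#' @rdname save_index
#' @return `load_index`: the reconstructed `vps_index`.
#' @export
load_index <- function(path) {
  if (!file.exists(path))
    stop(sprintf("I/O error: no such file: %s", path), call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- tryCatch(rhdf5::h5ls(path),
                 error = function(e) stop(sprintf(
                   "format error: not a valid index file: %s", path),
                   call. = FALSE))
  if (!"meta" %in% ls$name[ls$group == "/"] ||
      !"format_version" %in% ls$name[ls$group == "/meta"])
    stop("format error: index file has no /meta/format_version",
         call. = FALSE)
  ver <- as.integer(rhdf5::h5read(path, "meta/format_version"))
  if (!identical(ver, INDEX_FORMAT_VERSION))
    stop(sprintf("version error: index format %d unsupported (expected %d)",
                 ver, INDEX_FORMAT_VERSION), call. = FALSE)
  metric_name <- as.character(rhdf5::h5read(path, "meta/metric_name"))
  met <- get_metric(metric_name)
  has_pca <- as.integer(rhdf5::h5read(path, "meta/has_pca")) == 1L
  feature_ids <- as.character(rhdf5::h5read(path, "vectors/feature_ids"))
  sample_ids <- as.character(rhdf5::h5read(path, "vectors/sample_ids"))
  vectors <- as.matrix(rhdf5::h5read(path, "vectors/data"))
  colnames(vectors) <- sample_ids
  sentinel_to_na <- function(x, as_int = TRUE) {
    x[x == -1] <- NA
    if (as_int) as.integer(x) else as.double(x)
  }
  tree <- structure(
    list(vantage = as.integer(rhdf5::h5read(path, "tree/vantage")),
         mu = sentinel_to_na(as.double(rhdf5::h5read(path, "tree/mu")),
                             as_int = FALSE),
         left = sentinel_to_na(rhdf5::h5read(path, "tree/left")),
         right = sentinel_to_na(rhdf5::h5read(path, "tree/right")),
         root = if (length(sample_ids)) 1L else NA_integer_,
         vectors = vectors, sample_ids = sample_ids, metric = met,
         seed = as.integer(rhdf5::h5read(path, "meta/seed")),
         n_build_evals = as.integer(rhdf5::h5read(path,
                                                  "meta/n_build_evals"))),
    class = "vp_tree")
  pca <- NULL
  if (has_pca) {
    pca <- structure(
      list(mean = as.double(rhdf5::h5read(path, "pca/mean")),
           components = as.matrix(rhdf5::h5read(path, "pca/components")),
           explained_variance_fraction =
             as.double(rhdf5::h5read(path, "pca/explained_variance")),
           feature_ids = feature_ids),
      class = "pca_model")
  }
  structure(list(format_version = ver, pca = pca, tree = tree,
                 feature_ids = feature_ids),
            class = "vps_index")
}
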