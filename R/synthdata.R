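#' Specification for a synthetic clustered expression database
#'
#' Describes a Gaussian-mixture expression dataset with the structure of a
#' two-cancer-type cohort: well-separated clusters in expression space, an
#' optional "crosser" sample (drawn from one cluster's distribution but
#' carrying another cluster's label) and an optional outlier far from every
#' cluster. The defaults — two clusters of 50 samples, 200 features of
#' which 10 carry cluster signal, a 6-standard-deviation mean shift, unit
#' within-cluster noise, one crosser, one outlier at 20 standard deviations,
#' seed 17 — are the fixture used across the test suites.
#'
#' @param n_per_cluster integer vector: samples per cluster.
#' @param n_features total features.
#' @param n_informative features carrying the cluster mean shift
#'   (`<= n_features`).
#' @param cluster_separation between-cluster mean shift per informative
#'   feature, in units of `noise_sd`.
#' @param noise_sd within-cluster standard deviation (> 0): a scalar applied
#'   to every feature, or a length-`n_features` vector for anisotropic
#'   noise (e.g. the decaying per-coordinate spread of a PCA-reduced
#'   space). The separation parameters are expressed in units of the
#'   per-feature `noise_sd`.
#' @param n_crossers samples drawn from one cluster's distribution but
#'   labeled as another's.
#' @param n_outliers samples displaced from the baseline by
#'   `outlier_separation * noise_sd` on every informative feature.
#' @param outlier_separation outlier displacement per informative feature,
#'   in units of `noise_sd` (same convention as `cluster_separation`).
#' @param seed integer seed; generation is fully reproducible per seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_cluster = c(50L, 50L), n_features = 200L,
                           n_informative = 10L, cluster_separation = 6,
                           noise_sd = 1, n_crossers = 1L, n_outliers = 1L,
                           outlier_separation = 20, seed = 17L) {
  spec <- list(n_per_cluster = as.integer(n_per_cluster),
               n_features = as.integer(n_features),
               n_informative = as.integer(n_informative),
               cluster_separation = as.double(cluster_separation),
               noise_sd = as.double(noise_sd),
               n_crossers = as.integer(n_crossers),
               n_outliers = as.integer(n_outliers),
               outlier_separation = as.double(outlier_separation),
               seed = as.integer(seed))
  if (length(spec$n_per_cluster) < 1L || any(spec$n_per_cluster < 0L))
    stop("parameter error: n_per_cluster must be non-negative counts",
         call. = FALSE)
  if (spec$n_features < 1L)
    stop("parameter error: n_features must be >= 1", call. = FALSE)
  if (spec$n_informative < 0L || spec$n_informative > spec$n_features)
    stop("parameter error: n_informative must be in [0, n_features]",
         call. = FALSE)
  if (spec$cluster_separation < 0 || spec$outlier_separation < 0)
    stop("parameter error: separations must be non-negative", call. = FALSE)
  if (!length(spec$noise_sd) %in% c(1L, spec$n_features))
    stop("parameter error: noise_sd must be a scalar or length n_features",
         call. = FALSE)
  if (!all(is.finite(spec$noise_sd)) || any(spec$noise_sd <= 0))
    stop("parameter error: noise_sd must be > 0", call. = FALSE)
  if (spec$n_crossers < 0L || spec$n_outliers < 0L)
    stop("parameter error: counts must be >= 0", call. = FALSE)
  if (sum(spec$n_per_cluster) + spec$n_crossers + spec$n_outliers < 1L)
    stop("parameter error: spec generates no samples", call. = FALSE)
  structure(spec, class = "synthetic_spec")
}

# Deterministic cluster mean matrix (n_features x n_clusters), baseline 8.
# Two clusters sit symmetrically at -/+ separation/2 on every informative
# feature; with more clusters each gets +separation on its own block of
# informative features.
cluster_means <- function(spec) {
  k <- length(spec$n_per_cluster)
  base <- 8
  mu <- matrix(base, spec$n_features, k)
  ninf <- spec$n_informative
  if (ninf == 0L || spec$cluster_separation == 0) return(mu)
  sdv <- rep(spec$noise_sd, length.out = spec$n_features)
  shift <- spec$cluster_separation * sdv
  if (k == 1L) return(mu)
  if (k == 2L) {
    inf <- seq_len(ninf)
    mu[inf, 1L] <- base - shift[inf] / 2
    mu[inf, 2L] <- base + shift[inf] / 2
  } else {
    blocks <- split(seq_len(ninf), cut(seq_len(ninf), k, labels = FALSE))
    for (j in seq_len(k))
      if (length(blocks) >= j)
        mu[blocks[[j]], j] <- base + shift[blocks[[j]]]
  }
  mu
}

#' Generate a synthetic clustered expression database
#'
#' Draws each cluster's samples from an isotropic Gaussian around its mean
#' (see [synthetic_spec()] for the geometry), appends crossers (sampled from
#' the next cluster's distribution but labeled with their nominal cluster)
#' and outliers (displaced from the baseline on the informative features),
#' then clamps all values into the plausible log2-expression range [0, 20].
#' Deterministic per seed.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `matrix` (an [expression_matrix()]) and `labels`, a
#'   data.frame with columns `sample_id`, `label` (crossers and outliers
#'   labeled distinctly: `"<cluster>.crosser"`, `"outlier"`) and `role`
#'   (`member`, `crosser`, `outlier`).
#' @export
generate_profiles <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  k <- length(spec$n_per_cluster)
  mu <- cluster_means(spec)
  p <- spec$n_features
  ids <- character(0); labels <- character(0); roles <- character(0)
  cols <- list()
  with_seed(spec$seed, {
    for (j in seq_len(k)) {
      nj <- spec$n_per_cluster[j]
      if (nj == 0L) next
      cols[[length(cols) + 1L]] <-
        matrix(stats::rnorm(p * nj, mean = mu[, j], sd = spec$noise_sd),
               p, nj)
      ids <- c(ids, sprintf("c%d_s%03d", j, seq_len(nj)))
      labels <- c(labels, rep(sprintf("cluster%d", j), nj))
      roles <- c(roles, rep("member", nj))
    }
    if (spec$n_crossers > 0L) {
      for (i in seq_len(spec$n_crossers)) {
        nominal <- (i - 1L) %% k + 1L
        source <- nominal %% k + 1L       # next cluster's distribution
        cols[[length(cols) + 1L]] <-
          matrix(stats::rnorm(p, mean = mu[, source], sd = spec$noise_sd),
                 p, 1L)
        ids <- c(ids, sprintf("crosser%02d_c%d", i, nominal))
        labels <- c(labels, sprintf("cluster%d.crosser", nominal))
        roles <- c(roles, "crosser")
      }
    }
    if (spec$n_outliers > 0L) {
      for (i in seq_len(spec$n_outliers)) {
        om <- rep(8, p)
        if (spec$n_informative > 0L) {
          sdv <- rep(spec$noise_sd, length.out = p)
          inf <- seq_len(spec$n_informative)
          signs <- sample(c(-1, 1), spec$n_informative, replace = TRUE)
          om[inf] <- 8 + signs * spec$outlier_separation * sdv[inf]
        }
        cols[[length(cols) + 1L]] <-
          matrix(stats::rnorm(p, mean = om, sd = spec$noise_sd), p, 1L)
        ids <- c(ids, sprintf("outlier%02d", i))
        labels <- c(labels, "outlier")
        roles <- c(roles, "outlier")
      }
    }
  })
  values <- do.call(cbind, cols)
  values <- pmin(pmax(values, 0), 20)     # plausible log2-expression range
  mat <- expression_matrix(values, sprintf("g%04d", seq_len(p)), ids)
  list(matrix = mat,
       labels = data.frame(sample_id = ids, label = labels, role = roles,
                           stringsAsFactors = FALSE))
}

#' Prototype sample of a cluster
#'
#' Returns the database member nearest (Euclidean) to the cluster's mean
#' vector, computed in whatever space the matrix is expressed in — the
#' "prototypical" profile used as a representative query. Ties are broken
#' by lexicographically smaller sample id.
#'
#' @param matrix an [expression_matrix()].
#' @param labels the labels data.frame from [generate_profiles()] (or a
#'   named character vector mapping sample id to label).
#' @param cluster label value to summarize, e.g. `"cluster1"`.
#' @return A [profile_vector()] for the prototype member.
#' @export
prototype_query <- function(matrix, labels, cluster) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (is.data.frame(labels)) {
    lab <- stats::setNames(labels$label, labels$sample_id)
  } else lab <- labels
  members <- names(lab)[lab == cluster]
  members <- intersect(members, matrix$sample_ids)
  if (length(members) == 0L)
    stop(sprintf("parameter error: no samples labeled '%s'", cluster),
         call. = FALSE)
  sub <- matrix$values[, members, drop = FALSE]
  ctr <- rowMeans(sub)
  d <- metric_euclidean()$fn_many(ctr, sub)
  best <- members[rank_hits(members, d)[1L]]
  profile_vector(best, matrix$values[, best],
                 feature_ids = matrix$feature_ids, space = "raw")
}

#' Write a two-column sample label table
#'
#' @param labels labels data.frame from [generate_profiles()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(labels, path) {
  utils::write.csv(labels[, c("sample_id", "label")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
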