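#' Lower median of a multiset of distances
#'
#' Returns the element at rank `ceiling(m/2)` of the sorted values, i.e. the
#' lower median, so the split radius is always an attained distance.
#' Selection uses a partial sort (expected linear time) rather than a full
#' sort.
#'
#' @param x non-empty numeric vector.
#' @return The lower median, an element of `x`.
#' @examples
#' select_median(c(1, 2, 3, 4)) # 2
#' @export
select_median <- function(x) {
  m <- length(x)
  if (m == 0L) stop("domain error: empty multiset has no median",
                    call. = FALSE)
  r <- ceiling(m / 2)
  sort(x, partial = r)[r]
}

# normalize record input to a dim x n double matrix with unique colnames
as_record_matrix <- function(records) {
  if (inherits(records, "ExpressionMatrix")) {
    v <- records$values
  } else if (is.matrix(records)) {
    v <- records
  } else if (is.list(records)) {
    lens <- lengths(records)
    if (length(records) && length(unique(lens)) != 1L)
      stop("dimension error: record vectors have inconsistent lengths",
           call. = FALSE)
    v <- if (length(records)) vapply(records, as.double, numeric(lens[1]))
         else matrix(numeric(0), 0, 0)
    if (length(records) == 1L) v <- matrix(v, ncol = 1L)
  } else {
    stop("records must be a matrix, an ExpressionMatrix, or a named list",
         call. = FALSE)
  }
  if (ncol(v) > 0L) {
    if (is.null(colnames(v)))
      stop("records must carry sample ids as names/colnames", call. = FALSE)
    if (anyDuplicated(colnames(v)))
      stop("validation error: duplicate sample ids", call. = FALSE)
    if (!all(is.finite(v)))
      stop("validation error: record vectors must be finite", call. = FALSE)
  }
  storage.mode(v) <- "double"
  v
}

# run expr with a private RNG stream seeded from `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Build a vantage-point tree over a set of profile vectors
#'
#' Recursive median-split construction: each node stores a uniformly random
#' record `p` (the vantage point) and the median `mu` of the distances from
#' `p` to the remaining records of its set; records closer than `mu` go to
#' the left subtree, records at distance `>= mu` to the right. Construction
#' costs O(n log n) distance evaluations and is fully deterministic for a
#' given `(records, seed)` pair. The implementation is iterative (explicit
#' stack), so database size is not limited by the recursion depth.
#'
#' @param records a `dim x n` matrix with sample ids as column names, a
#'   named list of equal-length vectors, or an [expression_matrix()] (whose
#'   columns are indexed as-is; apply [pca_transform()] first if a reduced
#'   space is wanted).
#' @param metric a [metric()]; default Euclidean.
#' @param seed integer seed controlling vantage-point choice.
#' @return An object of class `vp_tree`: flat node arrays (`vantage`, `mu`,
#'   `left`, `right`, with `NA` as the leaf/absent-child sentinel), `root`,
#'   the record matrix `vectors`, `sample_ids`, the `metric`, the build
#'   `seed`, and `n_build_evals`, the total number of distance evaluations
#'   spent on construction.
#' @export
build_vptree <- function(records, metric = metric_euclidean(), seed = 1L) {
  stopifnot(inherits(metric, "vps_metric"))
  v <- as_record_matrix(records)
  n <- ncol(v)
  ids <- colnames(v)

  vantage <- integer(n); mu <- rep(NA_real_, n)
  left <- rep(NA_integer_, n); right <- rep(NA_integer_, n)
  n_evals <- 0L
  next_slot <- 1L

  if (n > 0L) {
    with_seed(seed, {
      # stack entries: (set of record indices, parent slot, side 1=L/2=R)
      stack <- vector("list", n)
      stack[[1L]] <- list(set = seq_len(n), parent = NA_integer_, side = 0L)
      top <- 1L
      while (top > 0L) {
        fr <- stack[[top]]; top <- top - 1L
        s <- fr$set
        node <- next_slot; next_slot <- next_slot + 1L
        vi <- s[sample.int(length(s), 1L)]
        vantage[node] <- vi
        rest <- s[s != vi]
        if (length(rest)) {
          d <- metric$fn_many(v[, vi], v[, rest, drop = FALSE])
          n_evals <- n_evals + length(rest)
          mu[node] <- select_median(d)
          li <- rest[d < mu[node]]
          ri <- rest[d >= mu[node]]
          if (length(ri)) {
            top <- top + 1L
            stack[[top]] <- list(set = ri, parent = node, side = 2L)
          }
          if (length(li)) {
            top <- top + 1L
            stack[[top]] <- list(set = li, parent = node, side = 1L)
          }
        }
        if (!is.na(fr$parent)) {
          if (fr$side == 1L) left[fr$parent] <- node
          else right[fr$parent] <- node
        }
      }
    })
  }

  structure(
    list(vantage = vantage, mu = mu, left = left, right = right,
         root = if (n > 0L) 1L else NA_integer_,
         vectors = v, sample_ids = ids, metric = metric,
         seed = as.integer(seed), n_build_evals = n_evals),
    class = "vp_tree")
}

#' @export
print.vp_tree <- function(x, ...) {
  cat(sprintf(
    "vp_tree: %d records, dim %d, metric '%s', %d build distance evals\n",
    length(x$sample_ids), nrow(x$vectors), x$metric$name, x$n_build_evals))
  invisible(x)
}

#' Subtree pruning decision
#'
#' Given the query-to-vantage distance `d_pq`, the node's split radius `mu`
#' and the current search radius `tau` (distance of the k-th best candidate,
#' `Inf` until k candidates exist), decides which subtrees can contain a
#' record within `tau` of the query. The left subtree (records closer than
#' `mu` to the vantage point) is fathomed when `d_pq >= tau + mu`; the right
#' subtree (records at distance `>= mu`) is fathomed when `d_pq + tau < mu`.
#' Both fathoming rules are strictly sound: every record in a fathomed
#' subtree is provably at distance greater than `tau` from the query.
#'
#' @param d_pq,mu non-negative reals.
#' @param tau non-negative real or `Inf`.
#' @return One of `"search_left_only"`, `"search_right_only"`,
#'   `"search_both"`.
#' @export
prune_decision <- function(d_pq, mu, tau) {
  stopifnot(d_pq >= 0, mu >= 0, tau >= 0)
  go_left <- d_pq < mu + tau
  go_right <- d_pq + tau >= mu
  if (go_left && go_right) "search_both"
  else if (go_left) "search_left_only"
  else if (go_right) "search_right_only"
  else stop("internal error: both subtrees fathomed")   # impossible, tau >= 0
}

#' Exact k-nearest-neighbor search in a vantage-point tree
#'
#' Depth-first traversal with triangle-inequality pruning. The search radius
#' `tau` starts at `Inf` and shrinks to the current k-th best distance; at
#' every node the vantage record itself is tested as a candidate, then the
#' subtree on the query's side of `mu` is descended first (shrinking `tau`
#' early), and the other subtree is visited only if [prune_decision()] —
#' re-evaluated with the then-current `tau` — cannot fathom it. Results are
#' always identical to a brute-force scan: the exact k smallest distances,
#' ascending, ties broken lexicographically by sample id.
#'
#' @param tree a [build_vptree()] index.
#' @param query numeric vector in the tree's vector space (or a
#'   [profile_vector()] already in that space).
#' @param k number of hits to return (all records if `k >= n`).
#' @param exclude_self if `TRUE`, drops hits at distance 0 whose sample id
#'   equals `query_id` before ranking (for queries that are themselves
#'   database records).
#' @param query_id sample id of the query, used only by `exclude_self`;
#'   taken from a `ProfileVector` query automatically.
#' @param audit if `TRUE`, the result additionally carries `fathomed` (a
#'   data.frame of fathomed subtree roots with the `tau` in force at
#'   fathoming time) and `tau_trace` (the successive values of `tau`),
#'   supporting soundness and monotonicity audits.
#' @return A [search_result()].
#' @export
search_knn <- function(tree, query, k = 10L, exclude_self = FALSE,
                       query_id = NULL, audit = FALSE) {
  stopifnot(inherits(tree, "vp_tree"))
  if (inherits(query, "ProfileVector")) {
    if (is.null(query_id)) query_id <- query$sample_id
    query <- query$values
  }
  k <- as.integer(k)
  if (k < 1L) stop("parameter error: k must be >= 1", call. = FALSE)
  n <- length(tree$sample_ids)
  if (n == 0L) {
    res <- search_result(character(0), numeric(0), 0L)
    if (audit) {
      res$fathomed <- data.frame(node = integer(0), tau = numeric(0))
      res$tau_trace <- numeric(0)
    }
    return(res)
  }
  if (length(query) != nrow(tree$vectors))
    stop(sprintf("dimension error: query length %d, index dimension %d",
                 length(query), nrow(tree$vectors)), call. = FALSE)
  if (!all(is.finite(query)))
    stop("validation error: query values must be finite", call. = FALSE)

  dist_fn <- tree$metric$fn
  v <- tree$vectors
  ids <- tree$sample_ids
  best_d <- numeric(0); best_id <- character(0)
  tau <- Inf
  n_evals <- 0L
  fath_node <- integer(0); fath_tau <- numeric(0)
  tau_trace <- numeric(0)

  # stack entries gate a node by its parent's (d_pq, mu) and side;
  # conditions are re-evaluated with the current tau when popped
  st_node <- integer(n); st_side <- integer(n)
  st_pd <- numeric(n); st_pmu <- numeric(n)
  top <- 1L
  st_node[1L] <- tree$root; st_side[1L] <- 0L

  while (top > 0L) {
    node <- st_node[top]; side <- st_side[top]
    pd <- st_pd[top]; pmu <- st_pmu[top]
    top <- top - 1L
    if (side == 1L && !(pd < pmu + tau)) {          # fathom left subtree
      if (audit) { fath_node <- c(fath_node, node); fath_tau <- c(fath_tau, tau) }
      next
    }
    if (side == 2L && !(pd + tau >= pmu)) {         # fathom right subtree
      if (audit) { fath_node <- c(fath_node, node); fath_tau <- c(fath_tau, tau) }
      next
    }

    vi <- tree$vantage[node]
    d <- dist_fn(query, v[, vi])
    n_evals <- n_evals + 1L
    id <- ids[vi]
    if (!(exclude_self && !is.null(query_id) && d == 0 && id == query_id)) {
      nb <- length(best_d)
      if (nb < k || d < tau || (d == tau && id < best_id[nb])) {
        pos <- sum(best_d < d | (best_d == d & best_id < id))
        best_d <- append(best_d, d, after = pos)
        best_id <- append(best_id, id, after = pos)
        if (length(best_d) > k) {
          best_d <- best_d[seq_len(k)]; best_id <- best_id[seq_len(k)]
        }
        if (length(best_d) == k) tau <- best_d[k]
        if (audit) tau_trace <- c(tau_trace, tau)
      }
    }

    m <- tree$mu[node]
    if (!is.na(m)) {
      lch <- tree$left[node]; rch <- tree$right[node]
      near_left <- d < m
      # push far child first so the near side is explored before it
      if (near_left) {
        if (!is.na(rch)) {
          top <- top + 1L
          st_node[top] <- rch; st_side[top] <- 2L
          st_pd[top] <- d; st_pmu[top] <- m
        }
        if (!is.na(lch)) {
          top <- top + 1L
          st_node[top] <- lch; st_side[top] <- 1L
          st_pd[top] <- d; st_pmu[top] <- m
        }
      } else {
        if (!is.na(lch)) {
          top <- top + 1L
          st_node[top] <- lch; st_side[top] <- 1L
          st_pd[top] <- d; st_pmu[top] <- m
        }
        if (!is.na(rch)) {
          top <- top + 1L
          st_node[top] <- rch; st_side[top] <- 2L
          st_pd[top] <- d; st_pmu[top] <- m
        }
      }
    }
  }

  res <- search_result(best_id, best_d, n_evals)
  if (audit) {
    res$fathomed <- data.frame(node = fath_node, tau = fath_tau)
    res$tau_trace <- tau_trace
  }
  res
}

#' Collect the sample ids stored in a subtree
#'
#' @param tree a `vp_tree`.
#' @param node node index (e.g. `tree$root` or an entry of
#'   `result$fathomed$node` from an audited search).
#' @return Character vector of sample ids in the subtree rooted at `node`.
#' @export
subtree_ids <- function(tree, node) {
  out <- character(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    out <- c(out, tree$sample_ids[tree$vantage[nd]])
    if (!is.na(tree$left[nd])) stack <- c(stack, tree$left[nd])
    if (!is.na(tree$right[nd])) stack <- c(stack, tree$right[nd])
  }
  out
}

#' Audit the structural invariants of a vantage-point tree
#'
#' Walks every node and verifies (a) all left-subtree records lie strictly
#' closer than `mu` to the node's vantage point and all right-subtree
#' records at distance `>= mu`, and (b) the multiset of sample ids stored in
#' the tree equals the indexed records exactly. Stops with a descriptive
#' error on any violation.
#'
#' @param tree a `vp_tree`.
#' @return `TRUE`, invisibly.
#' @export
validate_vptree <- function(tree) {
  stopifnot(inherits(tree, "vp_tree"))
  n <- length(tree$sample_ids)
  if (n == 0L) return(invisible(TRUE))
  seen <- subtree_ids(tree, tree$root)
  if (!identical(sort(seen), sort(tree$sample_ids)))
    stop("partition audit: tree id multiset differs from input records")
  fn_many <- tree$metric$fn_many
  for (node in seq_len(n)) {
    m <- tree$mu[node]
    vv <- tree$vectors[, tree$vantage[node]]
    for (side in 1:2) {
      ch <- if (side == 1L) tree$left[node] else tree$right[node]
      if (is.na(ch)) next
      if (is.na(m)) stop("partition audit: leaf node has a child")
      member_ids <- subtree_ids(tree, ch)
      d <- fn_many(vv, tree$vectors[, member_ids, drop = FALSE])
      bad <- if (side == 1L) d >= m else d < m
      if (any(bad))
        stop(sprintf(
          "partition audit: node %d side %d violates the d %s mu rule for %s",
          node, side, if (side == 1L) "<" else ">=",
          paste(member_ids[bad], collapse = ", ")))
    }
  }
  invisible(TRUE)
}

#' Verify that fathomed subtrees contained nothing better than tau
#'
#' For each fathoming event recorded by `search_knn(..., audit = TRUE)`,
#' exhaustively computes the query's distance to every record in the
#' fathomed subtree and checks that none is closer than the `tau` in force
#' when the subtree was discarded (up to floating-point slack).
#'
#' @param tree the searched `vp_tree`.
#' @param query the query vector used.
#' @param result the audited [search_knn()] result.
#' @param tol relative floating-point slack.
#' @return `TRUE` invisibly; stops with details on any unsound fathom.
#' @export
audit_fathoming <- function(tree, query, result, tol = 1e-9) {
  stopifnot(!is.null(result$fathomed))
  if (inherits(query, "ProfileVector")) query <- query$values
  fm <- result$fathomed
  for (i in seq_len(nrow(fm))) {
    member_ids <- subtree_ids(tree, fm$node[i])
    d <- tree$metric$fn_many(query, tree$vectors[, member_ids, drop = FALSE])
    lim <- fm$tau[i] * (1 - tol)
    if (any(d < lim))
      stop(sprintf(
        "unsound fathom: subtree at node %d held a record at distance %g < tau %g",
        fm$node[i], min(d), fm$tau[i]))
  }
  invisible(TRUE)
}
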