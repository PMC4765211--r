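test_that("select_median returns the lower median, an element of the input", {
  expect_identical(select_median(3), 3)
  expect_identical(select_median(c(1, 2, 3, 4)), 2)
  expect_error(select_median(numeric(0)), "domain error")

  set.seed(11)
  for (i in 1:200) {
    x <- sample(round(rnorm(sample(1:40, 1)), 2), replace = TRUE)
    ref <- sort(x)[ceiling(length(x) / 2)]      # full-sort oracle
    med <- select_median(x)
    expect_identical(med, ref)
    expect_true(med %in% x)
  }
})

test_that("degenerate builds: empty tree and single record", {
  t0 <- build_vptree(matrix(numeric(0), 2, 0))
  expect_true(is.na(t0$root))
  r0 <- search_knn(t0, c(0, 0), k = 3)
  expect_equal(nrow(r0$hits), 0L)

  t1 <- build_vptree(matrix(c(1, 2), 2, 1, dimnames = list(NULL, "only")))
  expect_equal(t1$vantage, 1L)
  expect_true(is.na(t1$mu[1]))
  expect_true(is.na(t1$left[1]) && is.na(t1$right[1]))
  expect_equal(t1$n_build_evals, 0L)
})

test_that("three collinear points partition as hand-enumerated", {
  # vantage at the middle point: distances {1, 1}, mu = 1, L empty (d < 1),
  # R holds both ends (d >= 1)
  v <- matrix(c(0, 1, 2), 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  tr <- NULL
  for (seed in 1:50) {
    cand <- build_vptree(v, seed = seed)
    if (cand$sample_ids[cand$vantage[1]] == "b") { tr <- cand; break }
  }
  expect_false(is.null(tr))
  expect_equal(tr$mu[1], 1)
  expect_true(is.na(tr$left[1]))
  expect_false(is.na(tr$right[1]))
  expect_setequal(subtree_ids(tr, tr$right[1]), c("a", "c"))
  validate_vptree(tr)
})

test_that("full-tree audit passes and id multiset is preserved", {
  v <- random_records(200, 10, seed = 21)
  tr <- build_vptree(v, seed = 4)
  expect_silent(validate_vptree(tr))
  expect_setequal(subtree_ids(tr, tr$root), colnames(v))
  # duplicated vectors (distance ties at mu) still partition totally
  v2 <- cbind(v[, 1:50], v[, 1:50])
  colnames(v2) <- sprintf("d%03d", 1:100)
  expect_silent(validate_vptree(build_vptree(v2, seed = 9)))
})

test_that("build distance evaluations respect the n(log2 n + 1) bound", {
  for (n in c(10, 100, 1000)) {
    v <- random_records(n, 10, seed = n)
    tr <- build_vptree(v, seed = 1)
    expect_lte(tr$n_build_evals, n * (floor(log2(n)) + 1))
  }
})

test_that("identical records and seed give identical trees and searches", {
  v <- random_records(300, 5, seed = 31)
  t1 <- build_vptree(v, seed = 7)
  t2 <- build_vptree(v, seed = 7)
  expect_identical(t1[c("vantage", "mu", "left", "right")],
                   t2[c("vantage", "mu", "left", "right")])
  set.seed(32); q <- rnorm(5)
  r1 <- search_knn(t1, q, k = 5); r2 <- search_knn(t2, q, k = 5)
  expect_same_hits(r1, r2)
  expect_identical(r1$n_distance_evals, r2$n_distance_evals)
  # a different seed reorders the tree but not the result
  t3 <- build_vptree(v, seed = 8)
  expect_same_hits(search_knn(t3, q, k = 5), r1)
})

test_that("build does not disturb the caller's RNG stream", {
  v <- random_records(50, 3, 1)
  set.seed(1234); before <- rnorm(3)
  set.seed(1234); invisible(build_vptree(v, seed = 2))
  expect_identical(rnorm(3), before)
})

test_that("prune_decision matches the fathoming rules", {
  expect_equal(prune_decision(10, 3, 2), "search_right_only")  # d >= tau+mu
  expect_equal(prune_decision(1, 5, 2), "search_left_only")    # d+tau <= mu
  expect_equal(prune_decision(4, 5, 2), "search_both")
  expect_equal(prune_decision(0, 5, Inf), "search_both")
})

test_that("self-match and exhaustive-k cases", {
  v <- random_records(40, 6, seed = 41)
  tr <- build_vptree(v, seed = 1)
  q <- v[, "s00007"]
  r <- search_knn(tr, q, k = 1)
  expect_equal(r$hits$sample_id, "s00007")
  expect_equal(r$hits$distance, 0)
  rx <- search_knn(tr, q, k = 1, exclude_self = TRUE, query_id = "s00007")
  expect_false("s00007" %in% rx$hits$sample_id)
  expect_gt(rx$hits$distance, 0)

  rall <- search_knn(tr, rnorm(6), k = 100)
  expect_equal(nrow(rall$hits), 40L)
  expect_false(is.unsorted(rall$hits$distance))
})

test_that("search equals the brute-force oracle across a parameter grid", {
  for (n in c(10, 100, 500)) {
    for (dim in c(2, 10)) {
      v <- random_records(n, dim, seed = n + dim)
      tr <- build_vptree(v, seed = 3)
      set.seed(n * dim)
      for (k in c(1, 5, 10)) {
        for (rep in 1:5) {
          q <- rnorm(dim)
          expect_same_hits(search_knn(tr, q, k = k),
                           brute_force_knn(v, q, k = k))
        }
      }
    }
  }
})

test_that("exactness holds under a non-Euclidean registered metric", {
  v <- random_records(150, 4, seed = 51)
  m <- metric_manhattan()
  tr <- build_vptree(v, metric = m, seed = 2)
  validate_vptree(tr)
  set.seed(52)
  for (rep in 1:20) {
    q <- rnorm(4)
    expect_same_hits(search_knn(tr, q, k = 5),
                     brute_force_knn(v, q, k = 5, metric = m))
  }
})

test_that("exactness survives duplicated vectors and distance ties", {
  base <- random_records(30, 3, seed = 61)
  v <- cbind(base, base, base[, 1:10])
  colnames(v) <- sprintf("t%03d", seq_len(ncol(v)))
  tr <- build_vptree(v, seed = 5)
  set.seed(62)
  for (rep in 1:20) {
    q <- v[, sample(ncol(v), 1)]           # query on a duplicated point
    for (k in c(1, 3, 25))
      expect_same_hits(search_knn(tr, q, k = k),
                       brute_force_knn(v, q, k = k))
  }
})

test_that("per-query evaluation count never exceeds n", {
  v <- random_records(256, 8, seed = 71)
  tr <- build_vptree(v, seed = 1)
  set.seed(72)
  for (rep in 1:30) {
    r <- search_knn(tr, rnorm(8), k = 3)
    expect_lte(r$n_distance_evals, 256L)
  }
})

test_that("tau shrinks monotonically and fathoming is sound", {
  gen <- generate_profiles(synthetic_spec(n_per_cluster = c(100, 100),
                                          n_features = 10,
                                          n_informative = 10,
                                          n_crossers = 0L, n_outliers = 0L,
                                          seed = 81))
  v <- gen$matrix$values
  tr <- build_vptree(v, seed = 6)
  set.seed(82)
  n_fathoms <- 0L
  for (rep in 1:25) {
    q <- v[, sample(ncol(v), 1)] + rnorm(10, sd = 0.3)
    r <- search_knn(tr, q, k = 3, audit = TRUE)
    expect_false(is.unsorted(rev(r$tau_trace)))
    expect_silent(audit_fathoming(tr, q, r))
    n_fathoms <- n_fathoms + nrow(r$fathomed)
  }
  expect_gt(n_fathoms, 0L)   # clustered data must actually prune
})

test_that("dimension and parameter errors are reported", {
  v <- random_records(20, 4, seed = 91)
  tr <- build_vptree(v, seed = 1)
  expect_error(search_knn(tr, rnorm(3), k = 1), "dimension error")
  expect_error(search_knn(tr, rnorm(4), k = 0), "parameter error")
  expect_error(build_vptree(list(a = 1:3, b = 1:2)), "dimension error")
})
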