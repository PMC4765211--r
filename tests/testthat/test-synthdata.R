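test_that("generation is deterministic per seed and exchangeable across seeds", {
  g1 <- default_fixture(seed = 17)
  g2 <- default_fixture(seed = 17)
  expect_identical(g1$matrix$values, g2$matrix$values)
  expect_identical(g1$labels, g2$labels)

  g3 <- default_fixture(seed = 18)
  expect_false(identical(g1$matrix$values, g3$matrix$values))
  expect_identical(dim(g1$matrix$values), dim(g3$matrix$values))
  expect_identical(g1$labels$label, g3$labels$label)
})

test_that("default fixture has the advertised composition and range", {
  g <- default_fixture()
  expect_equal(n_samples(g$matrix), 102L)    # 50 + 50 + crosser + outlier
  expect_equal(n_features(g$matrix), 200L)
  expect_equal(sum(g$labels$role == "member"), 100L)
  expect_equal(sum(g$labels$role == "crosser"), 1L)
  expect_equal(sum(g$labels$role == "outlier"), 1L)
  expect_true(all(g$matrix$values >= 0 & g$matrix$values <= 20))
  # crossers and outliers are labeled distinctly from plain members
  expect_true(all(grepl("crosser", g$labels$label[g$labels$role == "crosser"])))
  expect_true(all(g$labels$label[g$labels$role == "outlier"] == "outlier"))
})

test_that("single-cluster null structure yields label-proportional neighbors", {
  g <- generate_profiles(synthetic_spec(n_per_cluster = 60L, n_features = 30,
                                        cluster_separation = 0,
                                        n_crossers = 0L, n_outliers = 0L,
                                        seed = 5))
  expect_true(all(g$labels$label == "cluster1"))
  r <- brute_force_knn(g$matrix, g$matrix$values[, 1], k = 10)
  expect_equal(nrow(r$hits), 10L)
})

test_that("separated clusters give same-label nearest neighbors", {
  # lighter version of the acceptance sweep: 3 seeds, spec-example geometry
  for (seed in c(1, 2, 3)) {
    g <- generate_profiles(synthetic_spec(n_per_cluster = c(50L, 50L),
                                          n_features = 50,
                                          n_informative = 10,
                                          cluster_separation = 6,
                                          n_crossers = 0L, n_outliers = 0L,
                                          seed = seed))
    lab <- setNames(g$labels$label, g$labels$sample_id)
    v <- g$matrix$values
    set.seed(seed)
    for (j in sample(ncol(v), 10)) {
      r <- brute_force_knn(v, v[, j], k = 10, exclude_self = TRUE,
                           query_id = colnames(v)[j])
      expect_gte(mean(lab[r$hits$sample_id] == lab[j]), 0.9)
    }
  }
})

test_that("crossers sit with their source cluster, not their label", {
  g <- default_fixture()
  lab <- setNames(g$labels$label, g$labels$sample_id)
  crosser <- g$labels$sample_id[g$labels$role == "crosser"]
  r <- brute_force_knn(g$matrix, g$matrix$values[, crosser], k = 10,
                       exclude_self = TRUE, query_id = crosser)
  hit_labels <- base_label(lab[r$hits$sample_id])
  # nominal cluster1, drawn from cluster2's distribution
  expect_gte(mean(hit_labels == "cluster2"), 0.9)
})

test_that("the outlier is farther out than within-cluster neighbor scales", {
  g <- default_fixture()
  v <- g$matrix$values
  members <- g$labels$sample_id[g$labels$role == "member"]
  outlier <- g$labels$sample_id[g$labels$role == "outlier"]
  nn1 <- function(id) {
    r <- brute_force_knn(v, v[, id], k = 1, exclude_self = TRUE,
                         query_id = id)
    r$hits$distance[1]
  }
  member_nn <- vapply(members, nn1, numeric(1))
  expect_gt(nn1(outlier), quantile(member_nn, 0.99))
})

test_that("prototype query matches a full-scan argmin oracle with tie-break", {
  g <- generate_profiles(synthetic_spec(n_per_cluster = c(30L, 30L),
                                        n_features = 40, seed = 23,
                                        n_crossers = 0L, n_outliers = 0L))
  for (cl in c("cluster1", "cluster2")) {
    ids <- g$labels$sample_id[g$labels$label == cl]
    ctr <- rowMeans(g$matrix$values[, ids])
    d <- vapply(ids, function(i) euclid_loop(ctr, g$matrix$values[, i]),
                numeric(1))
    expected <- ids[order(d, ids)][1]
    expect_equal(prototype_query(g$matrix, g$labels, cl)$sample_id, expected)
  }

  # singleton cluster returns its only member
  g1 <- generate_profiles(synthetic_spec(n_per_cluster = c(1L, 5L),
                                         n_features = 10, n_crossers = 0L,
                                         n_outliers = 0L, seed = 3))
  expect_equal(prototype_query(g1$matrix, g1$labels, "cluster1")$sample_id,
               "c1_s001")
  # symmetric pair equidistant from its mean: lexicographically smaller id
  em <- expression_matrix(matrix(c(0, 2), 1, 2), "g1", c("b", "a"))
  lab <- data.frame(sample_id = c("b", "a"), label = "x")
  expect_equal(prototype_query(em, lab, "x")$sample_id, "a")
  expect_error(prototype_query(em, lab, "nope"), "parameter error")
})

test_that("high separation separates clusters in 2-component PCA space", {
  g <- default_fixture()
  keep <- g$labels$role == "member"
  m <- fit_pca(g$matrix, 2)
  proj <- pca_transform(m, g$matrix$values[, g$labels$sample_id[keep]])
  lab <- g$labels$label[keep]
  c1 <- rowMeans(proj[, lab == "cluster1"])
  c2 <- rowMeans(proj[, lab == "cluster2"])
  within <- c(sqrt(colSums((proj[, lab == "cluster1"] - c1)^2)),
              sqrt(colSums((proj[, lab == "cluster2"] - c2)^2)))
  expect_gt(euclidean_distance(c1, c2), 4 * mean(within))
})

test_that("invalid specs are rejected with parameter errors", {
  expect_error(synthetic_spec(n_per_cluster = integer(0)), "parameter error")
  expect_error(synthetic_spec(n_per_cluster = -1L), "parameter error")
  expect_error(synthetic_spec(n_informative = 300L), "parameter error")
  expect_error(synthetic_spec(noise_sd = 0), "parameter error")
  expect_error(synthetic_spec(noise_sd = c(1, 2)), "parameter error")
  expect_error(synthetic_spec(n_crossers = -1L), "parameter error")
  expect_error(synthetic_spec(n_per_cluster = 0L, n_crossers = 0L,
                              n_outliers = 0L), "parameter error")
})
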