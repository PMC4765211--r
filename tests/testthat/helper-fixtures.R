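# Shared fixture builders. Everything is generated in code; no stored data.

# random record matrix: dim x n with unique ids
random_records <- function(n, dim, seed) {
  set.seed(seed)
  v <- matrix(rnorm(dim * n), dim, n)
  colnames(v) <- sprintf("s%05d", seq_len(n))
  v
}

# the default two-cluster fixture used across suites
default_fixture <- function(seed = 17L) {
  generate_profiles(synthetic_spec(seed = seed))
}

expect_same_hits <- function(a, b) {
  expect_equal(a$hits$sample_id, b$hits$sample_id)
  expect_equal(a$hits$distance, b$hits$distance)
}

# independent elementwise euclidean oracle (no vectorized shortcuts)
euclid_loop <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  sqrt(s)
}

# nominal cluster of a label ("cluster1.crosser" -> "cluster1")
base_label <- function(x) sub("\\.crosser$", "", x)
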