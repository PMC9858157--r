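# Shared fixtures, generated in code.

# 12-node / 8-hyperedge / 6-attribute fixture: three 4-node communities,
# hyperedges are intra-community triples, attributes are two indicator
# columns per community.
tiny_hypernetwork <- function() {
  edges <- list(c(0L, 1L, 2L), c(0L, 1L, 3L), c(1L, 2L, 3L),
                c(4L, 5L, 6L), c(4L, 5L, 7L), c(5L, 6L, 7L),
                c(8L, 9L, 10L), c(9L, 10L, 11L))
  X <- matrix(0, 12, 6)
  comm <- rep(1:3, each = 4)
  for (c in 1:3) X[comm == c, (c - 1L) * 2L + 1:2] <- 1
  attribute_hypernetwork(edges, X)
}

# memorizable 12/8/6 fixture: two 4-node communities with all four
# intra-community triples each, plus 4 isolated distractor nodes; every
# sampled negative necessarily contains a node from a foreign block
overfit_hypernetwork <- function() {
  edges <- list(c(0L, 1L, 2L), c(0L, 1L, 3L), c(0L, 2L, 3L), c(1L, 2L, 3L),
                c(4L, 5L, 6L), c(4L, 5L, 7L), c(4L, 6L, 7L), c(5L, 6L, 7L))
  X <- matrix(0, 12, 6)
  X[1:4, 1:2] <- 1
  X[5:8, 3:4] <- 1
  X[9:12, 5:6] <- 1
  attribute_hypernetwork(edges, X)
}

# move attention vectors off their zero init so no LeakyReLU/softmax
# input sits exactly at a kink during finite-difference checks
perturb_off_kink <- function(params) {
  if (!is.null(params$a)) params$a <- params$a + rnorm(length(params$a), sd = 0.1)
  if (!is.null(params$w)) params$w <- params$w + rnorm(length(params$w), sd = 0.1)
  params
}

# random valid attribute hypernetwork for property tests
random_hypernetwork <- function(m = 20, n = 15, d = 10, seed = 1) {
  set.seed(seed)
  edges <- lapply(seq_len(n), function(.) {
    sort(sample.int(m, sample(2:4, 1)) - 1L)
  })
  X <- matrix(rbinom(m * d, 1, 0.35), m, d)
  X[rowSums(X) == 0, 1] <- 1
  zero <- which(colSums(X) == 0)
  for (j in zero) X[sample.int(m, 1), j] <- 1
  attribute_hypernetwork(edges, X)
}

# small config for fast tests
tiny_config <- function(...) {
  ahlp_config(d1 = 8L, d2 = 8L, dv = 8L, d_att = 8L, d_EA = 8L, de = 6L,
              restarts = 1L, ...)
}

expect_rel_equal <- function(actual, expected, tol = 1e-6) {
  denom <- pmax(abs(expected), 1)
  testthat::expect_true(all(abs(actual - expected) / denom < tol),
                        label = paste("relative difference <", tol))
}
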