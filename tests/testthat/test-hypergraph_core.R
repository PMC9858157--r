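test_that("structure incidence matches the membership definition", {
  S <- build_structure_incidence(list(c(0L, 1L), c(1L, 2L)), 3L)
  expect_equal(as.matrix(S), matrix(c(1, 1, 0, 0, 1, 1), 3, 2),
               ignore_attr = TRUE)

  expect_equal(dim(build_structure_incidence(list(), 2L)), c(2L, 0L))

  set.seed(5)
  edges <- lapply(1:50, function(.) sort(sample.int(20, sample(2:5, 1)) - 1L))
  S <- build_structure_incidence(edges, 20L)
  # independent membership loop
  for (j in seq_along(edges)) {
    expect_equal(which(as.matrix(S)[, j] == 1) - 1L, edges[[j]])
  }
  expect_equal(unname(Matrix::colSums(S)), lengths(edges))
})

test_that("structure incidence rejects invalid hyperedges", {
  expect_error(build_structure_incidence(list(c(0L, 5L)), 3L),
               "out of range")
  expect_error(build_structure_incidence(list(c(1L, 1L)), 3L),
               "fewer than 2")
})

test_that("attribute incidence marks exactly the nonzero entries", {
  expect_equal(build_attribute_incidence(matrix(c(2, 3, 0, 5), 2, 2)),
               matrix(c(1, 1, 0, 1), 2, 2))
  expect_equal(build_attribute_incidence(matrix(0, 2, 2)), matrix(0, 2, 2))
  set.seed(8)
  X <- matrix(rbinom(60, 1, 0.3) * runif(60, 1, 5), 10, 6)
  H <- build_attribute_incidence(X)
  expect_equal(sum(H), sum(X != 0))
  expect_error(build_attribute_incidence(matrix(c(1, NaN), 1, 2)), "NaN")
  expect_error(build_attribute_incidence(matrix(c(1, -1), 1, 2)),
               "nonnegative")
})

test_that("degree vectors are the row and column sums of H", {
  d <- degree_matrices(matrix(c(1, 1, 0, 1), 2, 2))
  expect_equal(d$dv, c(1, 2))
  expect_equal(d$da, c(2, 1))

  H1 <- matrix(1, 4, 3)
  d1 <- degree_matrices(H1)
  expect_equal(d1$dv, rep(3, 4))
  expect_equal(d1$da, rep(4, 3))

  set.seed(2)
  H <- matrix(rbinom(50, 1, 0.5), 10, 5)
  H[rowSums(H) == 0, 1] <- 1
  d <- degree_matrices(H)
  expect_equal(sum(d$dv), sum(d$da))   # both equal nnz(H)
  expect_equal(sum(d$dv), sum(H))

  expect_error(degree_matrices(matrix(c(0, 1, 0, 1), 2, 2)),
               "node\\(s\\) 0")
})

test_that("neighborhoods are the clique expansion plus self-loops", {
  S <- build_structure_incidence(list(c(0L, 1L), c(1L, 2L)), 4L)
  nb <- derive_neighborhoods(S)
  expect_equal(nb[[1]], c(0L, 1L))
  expect_equal(nb[[2]], c(0L, 1L, 2L))
  expect_equal(nb[[3]], c(1L, 2L))
  expect_equal(nb[[4]], 3L)           # isolated node keeps its self-loop

  hn <- random_hypernetwork(seed = 3)
  nb <- hn$neighborhoods
  # symmetry via independent pairwise co-membership scan
  for (i in seq_len(hn$m)) {
    for (j in nb[[i]]) {
      if (j != i - 1L) {
        co <- any(vapply(hn$hyperedges,
                         function(e) all(c(i - 1L, j) %in% e), TRUE))
        expect_true(co)
        expect_true((i - 1L) %in% nb[[j + 1L]])
      }
    }
  }
})

test_that("constructor validates nodes and drops empty attribute columns", {
  X <- matrix(c(1, 0, 1, 1, 1, 1, 0, 1), 4, 2)
  X <- cbind(X, 0)                    # all-zero column
  expect_warning(
    hn <- attribute_hypernetwork(list(c(0L, 1L), c(2L, 3L)), X),
    "all-zero attribute")
  expect_equal(hn$d, 2L)
  expect_equal(length(hn$da), 2L)

  Xbad <- matrix(c(1, 0, 1, 0, 0, 1), 3, 2)  # node 1 has no attribute
  expect_error(attribute_hypernetwork(list(c(0L, 1L), c(1L, 2L)), Xbad),
               "zero attribute degree")
})

test_that("relabeling nodes permutes incidence and degrees equivariantly", {
  hn <- random_hypernetwork(m = 12, n = 10, d = 6, seed = 9)
  perm <- sample(seq_len(hn$m))       # new position of each old node
  inv <- order(perm)
  edges_p <- lapply(hn$hyperedges, function(e) sort(perm[e + 1L] - 1L))
  hn_p <- attribute_hypernetwork(edges_p, hn$X[inv, , drop = FALSE])
  expect_equal(hn_p$H, hn$H[inv, , drop = FALSE], ignore_attr = TRUE)
  expect_equal(hn_p$dv, hn$dv[inv])
  expect_equal(hn_p$da, hn$da)
  expect_equal(sum(hn_p$dv), sum(hn$dv))
})

test_that("hypernetwork files round-trip exactly in both formats", {
  hn <- random_hypernetwork(seed = 11)
  for (fmt in c("tsv", "mtx")) {
    ep <- tempfile(fileext = ".txt")
    ap <- tempfile(fileext = if (fmt == "mtx") ".mtx" else ".tsv")
    write_hypernetwork(hn, ep, ap, format = fmt)
    hn2 <- read_hypernetwork(ep, ap)
    expect_equal(hn2$hyperedges, hn$hyperedges)
    expect_equal(hn2$X, hn$X, ignore_attr = TRUE)
    expect_equal(as.matrix(hn2$S), as.matrix(hn$S))
    expect_equal(hn2$H, hn$H, ignore_attr = TRUE)
  }
})

test_that("edge file parsing handles comments, labels and duplicates", {
  ep <- tempfile(); ap <- tempfile()
  writeLines(c("# a comment", "0 1", "1 2  # trailing"), ep)
  write.table(matrix(1, 3, 2), ap, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  hn <- read_hypernetwork(ep, ap)
  expect_equal(hn$n, 2L)
  expect_equal(hn$m, 3L)

  writeLines(c("alice bob", "bob carol"), ep)
  hn2 <- read_hypernetwork(ep, ap)
  expect_equal(hn2$node_labels, c("alice", "bob", "carol"))
  expect_equal(hn2$hyperedges, list(c(0L, 1L), c(1L, 2L)))

  writeLines(c("0 1 1 2"), ep)
  expect_warning(hn3 <- read_hypernetwork(ep, ap), "duplicate")
  expect_equal(hn3$hyperedges[[1]], c(0L, 1L, 2L))

  writeLines(c("0 1", "1 2 3"), ep)   # id 3 but only 3 attribute rows
  expect_error(read_hypernetwork(ep, ap), "only 3 rows")
})
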