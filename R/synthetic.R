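#' Specification of a planted-community attribute hypernetwork
#'
#' The generator emulates the shape of coauthorship/citation/reaction
#' hypernetworks: nodes belong to communities, most hyperedges are drawn
#' inside one community (groups of collaborators, reacting compounds),
#' the rest uniformly at random (noise hyperedges), and each community is
#' enriched for its own block of sparse binary attributes (bag-of-words
#' style), corrupted at rate `attr_noise`.
#'
#' @param m nodes; `C` communities (`m >= C >= 2`).
#' @param C number of communities.
#' @param n hyperedges.
#' @param size_range integer `(min, max)` hyperedge size, min `>= 2`.
#' @param p_intra probability a hyperedge is drawn within one community.
#' @param d total attribute columns (`>= C * attrs_per_community`).
#' @param attrs_per_community enriched attribute columns per community.
#' @param attr_noise activation noise rate: enriched columns fire for
#'   members with probability `1 - attr_noise`, for outsiders (and all
#'   background columns) with probability `attr_noise`.
#' @param seed integer seed.
#' @return a list of class `planted_spec`.
#' @export
planted_spec <- function(m = 300L, C = 5L, n = 400L, size_range = c(2L, 5L),
                         p_intra = 0.9, d = 120L,
                         attrs_per_community = 15L, attr_noise = 0.05,
                         seed = 1L) {
  stopifnot(m >= C, C >= 2, n >= 1, size_range[1] >= 2,
            size_range[2] >= size_range[1],
            p_intra >= 0, p_intra <= 1,
            attr_noise >= 0, attr_noise <= 1,
            d >= C * attrs_per_community)
  if (size_range[2] > m) stop("hyperedge size exceeds node count",
                              call. = FALSE)
  structure(list(m = as.integer(m), C = as.integer(C), n = as.integer(n),
                 size_range = as.integer(size_range), p_intra = p_intra,
                 d = as.integer(d),
                 attrs_per_community = as.integer(attrs_per_community),
                 attr_noise = attr_noise, seed = as.integer(seed)),
            class = "planted_spec")
}

#' Generate a planted-community attribute hypernetwork
#'
#' Nodes are partitioned into `C` near-equal communities. Each hyperedge
#' draws its size uniformly from `size_range`; with probability `p_intra`
#' its nodes are sampled without replacement inside one uniformly chosen
#' community, otherwise uniformly from all nodes. Duplicate hyperedges are
#' redrawn. Attributes are binary: community-enriched blocks plus
#' background columns, with every node forced to carry at least one
#' attribute so node degrees are positive.
#'
#' @param spec a [planted_spec()].
#' @return list with `hn` (an [attribute_hypernetwork]), `communities`
#'   (length-`m` integer vector of 1-based community labels), and `spec`.
#' @export
generate_hypernetwork <- function(spec) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  m <- spec$m; C <- spec$C
  communities <- sort(rep_len(seq_len(C), m))
  members <- split(0:(m - 1L), communities)
  if (any(lengths(members) < spec$size_range[2])) {
    stop("communities too small for the requested hyperedge sizes",
         call. = FALSE)
  }

  seen <- character(0)
  edges <- vector("list", spec$n)
  k <- 0L
  guard <- 0L
  while (k < spec$n) {
    guard <- guard + 1L
    if (guard > 50L * spec$n) stop("cannot draw enough distinct hyperedges",
                                   call. = FALSE)
    sz <- sample(spec$size_range[1]:spec$size_range[2], 1L)
    pool <- if (stats::runif(1) < spec$p_intra) {
      members[[sample.int(C, 1L)]]
    } else {
      0:(m - 1L)
    }
    e <- sort(pool[sample.int(length(pool), sz)])
    key <- paste(e, collapse = " ")
    if (key %in% seen) next
    seen <- c(seen, key)
    k <- k + 1L
    edges[[k]] <- e
  }

  apc <- spec$attrs_per_community
  X <- matrix(stats::rbinom(m * spec$d, 1L, spec$attr_noise), m, spec$d)
  for (c in seq_len(C)) {
    cols <- (c - 1L) * apc + seq_len(apc)
    rows <- members[[c]] + 1L
    X[rows, cols] <- stats::rbinom(length(rows) * apc, 1L,
                                   1 - spec$attr_noise)
  }
  # guarantee a positive attribute degree for every node
  zero <- which(rowSums(X) == 0)
  for (i in zero) {
    cols <- (communities[i] - 1L) * apc + seq_len(apc)
    X[i, cols[sample.int(apc, 1L)]] <- 1L
  }
  storage.mode(X) <- "double"

  list(hn = attribute_hypernetwork(edges, X), communities = communities,
       spec = spec)
}

#' Write a synthetic benchmark bundle to disk
#'
#' Generates a planted hypernetwork, writes the hyperedge list and the
#' attribute matrix in the package's standard formats plus a split TSV
#' (`edge_id`, `partition`), and returns the in-memory objects. The files
#' round-trip through [read_hypernetwork()].
#'
#' @param spec a [planted_spec()].
#' @param dir output directory (created if missing).
#' @param split_seed seed for [split_edges()].
#' @param format attribute matrix format, `"tsv"` or `"mtx"`.
#' @return list with `hn`, `communities`, `split`, and the file `paths`.
#' @export
make_benchmark <- function(spec = planted_spec(), dir = tempfile("bench"),
                           split_seed = spec$seed, format = "tsv") {
  gen <- generate_hypernetwork(spec)
  split <- split_edges(gen$hn$n, split_seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    edges = file.path(dir, "hyperedges.txt"),
    attrs = file.path(dir, if (format == "mtx") "attributes.mtx"
                           else "attributes.tsv"),
    split = file.path(dir, "split.tsv"))
  write_hypernetwork(gen$hn, paths$edges, paths$attrs, format = format)
  part <- rep(NA_character_, gen$hn$n)
  part[split$train] <- "train"
  part[split$val] <- "val"
  part[split$test] <- "test"
  utils::write.table(data.frame(edge_id = seq_len(gen$hn$n) - 1L,
                                partition = part),
                     paths$split, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  list(hn = gen$hn, communities = gen$communities, split = split,
       paths = paths, spec = spec)
}

#' Read a split TSV written by [make_benchmark()]
#' @param path path to the split file.
#' @return a list usable as the `split` argument of [train_model()].
#' @export
read_split <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  idx <- df$edge_id + 1L
  list(train = sort(idx[df$partition == "train"]),
       val = sort(idx[df$partition == "val"]),
       test = sort(idx[df$partition == "test"]),
       seed = NA_integer_)
}
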