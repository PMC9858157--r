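#' Build the structure incidence matrix of a hypergraph
#'
#' The structure incidence matrix \eqn{S \in \{0,1\}^{m \times n}} has
#' \eqn{S_{ij} = 1} exactly when node \eqn{i} belongs to hyperedge \eqn{j}.
#' Column \eqn{j} therefore sums to the size of hyperedge \eqn{j}.
#'
#' @param hyperedges list of integer vectors of 0-based node ids, one per
#'   hyperedge; each hyperedge must contain at least two distinct ids.
#' @param m number of nodes; all ids must lie in `0..m-1`.
#' @return a sparse `Matrix::dgCMatrix` of dimension `m x length(hyperedges)`.
#' @export
build_structure_incidence <- function(hyperedges, m) {
  stopifnot(is.numeric(m), length(m) == 1L, m >= 0)
  n <- length(hyperedges)
  if (n == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(m, 0L)))
  }
  edges <- lapply(hyperedges, function(e) sort(unique(as.integer(e))))
  sizes <- lengths(edges)
  if (any(sizes < 2L)) {
    stop("hyperedge ", which(sizes < 2L)[1L],
         " has fewer than 2 distinct nodes", call. = FALSE)
  }
  ii <- unlist(edges, use.names = FALSE)
  if (any(ii < 0L) || any(ii >= m)) {
    stop("node id out of range 0..", m - 1L, call. = FALSE)
  }
  jj <- rep.int(seq_len(n), sizes)
  Matrix::sparseMatrix(i = ii + 1L, j = jj, x = 1, dims = c(m, n))
}

#' Build the attribute incidence matrix from a feature matrix
#'
#' \eqn{H_{ij} = 1} exactly where \eqn{X_{ij} \neq 0}: each attribute is
#' viewed as a hyperedge joining every node that possesses it.
#'
#' @param X nonnegative, finite `m x d` numeric matrix.
#' @return a binary base matrix of the same dimension.
#' @export
build_attribute_incidence <- function(X) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X contains NaN/Inf entries", call. = FALSE)
  if (any(X < 0)) stop("X must be nonnegative", call. = FALSE)
  H <- (X != 0) * 1
  storage.mode(H) <- "double"
  H
}

#' Node and attribute degrees of the attribute incidence matrix
#'
#' Node degree = number of attributes a node carries (row sum of `H`);
#' attribute degree = number of nodes carrying the attribute (column sum).
#' Degrees are returned as vectors; the diagonal-matrix formulation is a
#' storage-free contract. A zero node degree is an error because the
#' attribute convolution normalizes by `Dv^(-1/2)`.
#'
#' @param H binary `m x d` matrix.
#' @return `list(dv = <length-m vector>, da = <length-d vector>)`.
#' @export
degree_matrices <- function(H) {
  H <- as.matrix(H)
  if (!all(H %in% c(0, 1))) stop("H must be binary", call. = FALSE)
  dv <- rowSums(H)
  da <- colSums(H)
  if (any(dv == 0)) {
    stop("node(s) ", paste(which(dv == 0) - 1L, collapse = ", "),
         " have zero attribute degree; Dv^(-1/2) is undefined", call. = FALSE)
  }
  list(dv = dv, da = da)
}

#' Attention neighborhoods from the clique expansion
#'
#' Two nodes are neighbors iff they co-occur in at least one hyperedge;
#' every node is additionally its own neighbor, so no neighborhood is ever
#' empty. Neighbor ids are 0-based and sorted ascending.
#'
#' @param S structure incidence matrix (`m x n`).
#' @return list of integer vectors, element `i` holding the neighborhood of
#'   node `i-1`.
#' @export
derive_neighborhoods <- function(S) {
  m <- nrow(S)
  A <- Matrix::tcrossprod(S)          # S S^T: co-membership counts
  # symmetric sparse classes store one triangle only; expand before reading
  A <- as(as(A, "generalMatrix"), "TsparseMatrix")
  keep <- A@x > 0
  ii <- A@i[keep]
  jj <- A@j[keep]
  nbr <- split(jj, factor(ii, levels = 0:(m - 1L)))
  lapply(seq_len(m), function(i) {
    v <- sort(unique(c(nbr[[i]], i - 1L)))
    as.integer(v)
  })
}

#' Construct an attribute hypernetwork
#'
#' Validates and assembles the container used throughout the package: the
#' hyperedge list, the feature matrix `X`, the structure incidence `S`, the
#' attribute incidence `H`, node/attribute degree vectors, and the attention
#' neighborhoods. All-zero attribute columns are dropped with a warning
#' (their degree would be zero); nodes without any nonzero attribute are
#' rejected.
#'
#' @param hyperedges list of integer vectors of 0-based node ids.
#' @param X `m x d` nonnegative feature matrix, row `i` belonging to node
#'   `i-1`.
#' @param node_labels optional character vector of original node labels.
#' @return an object of class `attribute_hypernetwork`.
#' @export
attribute_hypernetwork <- function(hyperedges, X, node_labels = NULL) {
  X <- as.matrix(X)
  m <- nrow(X)
  hyperedges <- lapply(hyperedges, function(e) sort(unique(as.integer(e))))
  S <- build_structure_incidence(hyperedges, m)
  H <- build_attribute_incidence(X)
  zero_cols <- which(colSums(H) == 0)
  if (length(zero_cols) > 0L) {
    warning("dropping ", length(zero_cols),
            " all-zero attribute column(s): ",
            paste(utils::head(zero_cols, 10L), collapse = ", "),
        call. = FALSE)
    X <- X[, -zero_cols, drop = FALSE]
    H <- H[, -zero_cols, drop = FALSE]
  }
  deg <- degree_matrices(H)
  structure(list(
    m = m,
    n = length(hyperedges),
    d = ncol(X),
    hyperedges = hyperedges,
    X = X,
    S = S,
    H = H,
    dv = deg$dv,
    da = deg$da,
    neighborhoods = derive_neighborhoods(S),
    node_labels = node_labels
  ), class = "attribute_hypernetwork")
}

#' @exportS3Method base::print
print.attribute_hypernetwork <- function(x, ...) {
  cat("attribute hypernetwork:", x$m, "nodes,", x$n, "hyperedges,",
      x$d, "attributes\n")
  cat("  hyperedge sizes:", paste(range(lengths(x$hyperedges)), collapse = "-"),
      " mean node degree:", round(mean(x$dv), 2), "\n")
  invisible(x)
}

parse_edge_file <- function(edge_path) {
  lines <- readLines(edge_path, warn = FALSE)
  raw <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(raw)))
  tokens <- strsplit(trimws(raw[keep]), "\\s+")
  all_tok <- unlist(tokens, use.names = FALSE)
  as_int <- suppressWarnings(as.integer(all_tok))
  if (anyNA(as_int)) {
    # arbitrary string labels: map to dense 0-based ids by first appearance
    labels <- unique(all_tok)
    lookup <- stats::setNames(seq_along(labels) - 1L, labels)
  } else {
    labels <- NULL
    lookup <- NULL
  }
  edges <- vector("list", length(tokens))
  for (k in seq_along(tokens)) {
    tok <- tokens[[k]]
    ids <- if (is.null(lookup)) suppressWarnings(as.integer(tok)) else
      unname(lookup[tok])
    if (anyNA(ids)) {
      stop("malformed hyperedge at line ", keep[k], " of ", edge_path,
           call. = FALSE)
    }
    if (anyDuplicated(ids)) {
      warning("duplicate node id within hyperedge at line ", keep[k],
              "; deduplicated", call. = FALSE)
      ids <- unique(ids)
    }
    edges[[k]] <- sort(ids)
  }
  list(edges = edges, labels = labels)
}

read_attribute_matrix <- function(attr_path) {
  first <- readLines(attr_path, n = 1L, warn = FALSE)
  X <- if (grepl("^%%MatrixMarket", first)) {
    as.matrix(Matrix::readMM(attr_path))
  } else {
    as.matrix(utils::read.table(attr_path, header = FALSE, sep = "\t",
                                colClasses = "numeric"))
  }
  storage.mode(X) <- "double"          # pattern MTX files read as logical
  X
}

#' Read an attribute hypernetwork from disk
#'
#' The hyperedge file holds one hyperedge per line as whitespace-separated
#' node ids (`#` starts a comment); the attribute file is either a
#' header-free dense TSV or a MatrixMarket coordinate file, row `i`
#' belonging to node id `i-1`. Non-integer node labels are mapped to dense
#' 0-based ids in order of first appearance.
#'
#' @param edge_path path to the hyperedge list.
#' @param attr_path path to the attribute matrix (TSV or MTX).
#' @return an [attribute_hypernetwork].
#' @export
read_hypernetwork <- function(edge_path, attr_path) {
  parsed <- parse_edge_file(edge_path)
  X <- read_attribute_matrix(attr_path)
  max_id <- max(unlist(parsed$edges, use.names = FALSE), -1L)
  if (max_id >= nrow(X)) {
    stop("hyperedge file references node id ", max_id, " but attribute ",
         "matrix has only ", nrow(X), " rows", call. = FALSE)
  }
  attribute_hypernetwork(parsed$edges, X, node_labels = parsed$labels)
}

#' Write an attribute hypernetwork to disk
#'
#' Inverse of [read_hypernetwork()]: a round-trip reproduces `S`, `H` and
#' `X` exactly.
#'
#' @param hn an [attribute_hypernetwork].
#' @param edge_path,attr_path output paths.
#' @param format `"tsv"` (dense) or `"mtx"` (MatrixMarket) for attributes.
#' @export
write_hypernetwork <- function(hn, edge_path, attr_path,
                               format = c("tsv", "mtx")) {
  format <- match.arg(format)
  writeLines(vapply(hn$hyperedges, paste, "", collapse = " "), edge_path)
  if (format == "tsv") {
    utils::write.table(hn$X, attr_path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  } else {
    Matrix::writeMM(methods::as(Matrix::Matrix(hn$X, sparse = TRUE),
                                "generalMatrix"), attr_path)
  }
  invisible(hn)
}
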