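#' Model and training configuration
#'
#' Collects every tunable of the hyperlink predictor. Defaults follow the
#' method's reference setting: learning rate 0.001 (Adam), dropout 0.5,
#' structure and attribute embedding dimensions `d1 = d2 = 128`, one
#' sampled negative hyperedge per positive, 70/10/20 train/validation/test
#' split handled by [split_edges()].
#'
#' @param d1 structure-channel embedding dimension.
#' @param d2 attribute-channel embedding dimension.
#' @param dv fused node-embedding dimension.
#' @param d_att node-level attention dimension (rows of `W_NA`).
#' @param d_EA hyperedge-level attention dimension.
#' @param de scoring-layer hidden size.
#' @param dropout dropout rate applied during training to the projected
#'   structure features, the node-attention weights, and between the two
#'   attribute-convolution layers.
#' @param leaky_slope negative slope of the LeakyReLU used on attention
#'   logits.
#' @param learning_rate Adam step size.
#' @param max_epochs maximum training epochs `T`.
#' @param batch_size positive hyperedges per mini-batch.
#' @param patience early-stopping patience on validation AUC.
#' @param negatives_per_positive sampled negatives per observed hyperedge.
#' @param loss_mode `"mean"` scores each positive against the batch mean of
#'   negative scores (the ranking loss as written); `"paired"` scores each
#'   positive against its own matched negative.
#' @param use_structure,use_attribute channel switches; disabling one makes
#'   the other the sole input of the fusion layer (ablation variants).
#' @param uniform_node_attention replace learned node-level attention by
#'   uniform `1/|N_i|` weights (ablation variant).
#' @param uniform_edge_attention replace learned hyperedge-level attention
#'   by uniform `1/|e|` weights (ablation variant).
#' @param restarts independent training restarts; the run with the best
#'   validation AUC is kept (ties to the first). Mitigates the
#'   initialization lottery of the nonconvex ranking objective.
#' @param seed integer seed controlling initialization, sampling, dropout.
#' @return a list of class `ahlp_config`.
#' @export
ahlp_config <- function(d1 = 128L, d2 = 128L, dv = 128L, d_att = d1,
                        d_EA = 128L, de = 64L,
                        dropout = 0.5, leaky_slope = 0.2,
                        learning_rate = 0.001, max_epochs = 200L,
                        batch_size = 64L, patience = 20L,
                        negatives_per_positive = 1L,
                        loss_mode = c("mean", "paired"),
                        use_structure = TRUE, use_attribute = TRUE,
                        uniform_node_attention = FALSE,
                        uniform_edge_attention = FALSE,
                        restarts = 3L, seed = 1L) {
  loss_mode <- match.arg(loss_mode)
  stopifnot(d1 >= 1, d2 >= 1, dv >= 1, d_att >= 1, d_EA >= 1, de >= 1,
            dropout >= 0, dropout < 1, learning_rate > 0, max_epochs >= 0,
            batch_size >= 1, patience >= 1, negatives_per_positive >= 1,
            restarts >= 1, use_structure || use_attribute)
  structure(list(
    d1 = as.integer(d1), d2 = as.integer(d2), dv = as.integer(dv),
    d_att = as.integer(d_att), d_EA = as.integer(d_EA), de = as.integer(de),
    dropout = dropout, leaky_slope = leaky_slope,
    learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
    batch_size = as.integer(batch_size), patience = as.integer(patience),
    negatives_per_positive = as.integer(negatives_per_positive),
    loss_mode = loss_mode,
    use_structure = isTRUE(use_structure),
    use_attribute = isTRUE(use_attribute),
    uniform_node_attention = isTRUE(uniform_node_attention),
    uniform_edge_attention = isTRUE(uniform_edge_attention),
    restarts = as.integer(restarts),
    seed = as.integer(seed)
  ), class = "ahlp_config")
}

glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Initialize all trainable parameters
#'
#' Uniform Glorot (fan-based) initialization, drawn from the current RNG
#' state, except the two attention vectors `a` and `w`, which start at
#' zero so that both attention modules begin as exactly uniform
#' aggregation and learn their weighting from data: randomly initialized
#' attention logits saturate the softmax (and the tanh of the hyperedge
#' module) before any structure has been learned, which measurably locks
#' training into poor basins. Only the parameters required by the
#' configured variant are created; the fusion matrix width adapts to the
#' active channels.
#'
#' @param d number of attributes (input feature dimension).
#' @param config an [ahlp_config()].
#' @return named list of matrices/vectors.
#' @export
init_params <- function(d, config) {
  p <- list()
  fused_in <- 0L
  if (config$use_structure) {
    p$W_SE <- glorot(d, config$d1)
    p$b_SE <- numeric(config$d1)
    if (!config$uniform_node_attention) {
      p$W_NA <- glorot(config$d_att, 2L * config$d1)
      p$a <- numeric(config$d_att)
    }
    fused_in <- fused_in + config$d1
  }
  if (config$use_attribute) {
    p$W_AE1 <- glorot(d, config$d2)
    p$W_AE2 <- glorot(config$d2, config$d2)
    fused_in <- fused_in + config$d2
  }
  p$W_FF <- glorot(config$dv, fused_in)
  if (!config$uniform_edge_attention) {
    p$W_EA <- glorot(config$d_EA, config$dv)
    p$w <- numeric(config$d_EA)
  }
  p$W_SC <- glorot(config$de, config$dv)
  p$b_SC <- numeric(config$de)
  p$u <- as.numeric(glorot(config$de, 1L))
  p
}

relu <- function(x) pmax(x, 0)
leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Nonlinear feature projection of the structure encoder
#'
#' `Z~SE = ReLU(X W_SE + b_SE)`: embeds raw node features into the common
#' structural space before attention aggregation.
#'
#' @param X `m x d` feature matrix.
#' @param W_SE `d x d_SE` projection matrix; `b_SE` length-`d_SE` bias.
#' @param b_SE bias vector.
#' @return `m x d_SE` nonnegative matrix.
#' @export
project_features <- function(X, W_SE, b_SE) {
  if (ncol(X) != nrow(W_SE)) stop("shape mismatch: ncol(X) != nrow(W_SE)",
                                  call. = FALSE)
  relu(sweep(X %*% W_SE, 2L, -b_SE))
}

# flatten neighborhood list into directed pair vectors (1-based)
neighbor_pairs <- function(neighborhoods) {
  sizes <- lengths(neighborhoods)
  list(ii = rep.int(seq_along(neighborhoods), sizes),
       jj = unlist(neighborhoods, use.names = FALSE) + 1L)
}

softmax_by_group <- function(logits, group, n_groups) {
  f <- factor(group, levels = seq_len(n_groups))
  mx <- tapply(logits, f, max)
  ex <- exp(logits - as.numeric(mx)[group])
  denom <- as.numeric(rowsum(ex, f))
  ex / denom[group]
}

#' Node-level attention weights over clique-expansion neighborhoods
#'
#' Logits follow the graph-attention composition
#' `omega_ij = LeakyReLU(a' W_NA [z_i || z_j])`, softmax-normalized over
#' each neighborhood `N_i` (self-loop included), so every row of the
#' returned table sums to 1 and is zero outside `N_i`.
#'
#' @param Ztilde `m x d_SE` projected features.
#' @param neighborhoods list of 0-based neighbor id vectors (see
#'   [derive_neighborhoods()]).
#' @param W_NA `d_att x 2*d_SE` attention projection; `a` length-`d_att`
#'   attention vector. Ignored when `uniform = TRUE`.
#' @param a attention vector.
#' @param uniform if `TRUE`, use uniform weights `1/|N_i|`.
#' @param leaky_slope negative LeakyReLU slope.
#' @return sparse `m x m` row-stochastic `Matrix::dgCMatrix`.
#' @export
attention_weights <- function(Ztilde, neighborhoods, W_NA = NULL, a = NULL,
                              uniform = FALSE, leaky_slope = 0.2) {
  m <- nrow(Ztilde)
  pr <- neighbor_pairs(neighborhoods)
  if (uniform) {
    alpha <- 1 / lengths(neighborhoods)[pr$ii]
  } else {
    p <- as.numeric(crossprod(W_NA, a))
    dse <- ncol(Ztilde)
    si <- as.numeric(Ztilde %*% p[seq_len(dse)])
    tj <- as.numeric(Ztilde %*% p[dse + seq_len(dse)])
    g <- si[pr$ii] + tj[pr$jj]
    omega <- leaky_relu(g, leaky_slope)
    if (any(!is.finite(omega))) stop("non-finite attention logits",
                                     call. = FALSE)
    alpha <- softmax_by_group(omega, pr$ii, m)
  }
  Matrix::sparseMatrix(i = pr$ii, j = pr$jj, x = alpha, dims = c(m, m))
}

#' Attention-weighted neighborhood aggregation
#'
#' `Z_SE[i] = sum_{j in N_i} a_ij Z~SE[j]` — each output row is a convex
#' combination of its neighborhood's projected features.
#'
#' @param Ztilde `m x d_SE` projected features.
#' @param weights row-stochastic sparse weight matrix from
#'   [attention_weights()].
#' @return `m x d_SE` structural embedding.
#' @export
aggregate_neighbors <- function(Ztilde, weights) {
  as.matrix(weights %*% Ztilde)
}

#' First attribute-convolution layer: nodes to attributes
#'
#' `Y_AE1 = H' Dv^(-1/2) X W_AE1`: each attribute embedding is the
#' degree-normalized sum of the (projected) features of the nodes carrying
#' it.
#'
#' @param X `m x d` feature matrix.
#' @param H `m x d` attribute incidence matrix.
#' @param dv length-`m` node degree vector (strictly positive).
#' @param W_AE1 `d x d2` first-layer filter.
#' @return `d x d2` attribute embedding matrix.
#' @export
aggregate_to_attributes <- function(X, H, dv, W_AE1) {
  if (any(dv <= 0)) stop("node degrees must be strictly positive",
                         call. = FALSE)
  Hs <- H / sqrt(dv)                  # Dv^(-1/2) H, row scaling
  crossprod(Hs, X %*% W_AE1)
}

#' Second attribute-convolution layer: attributes back to nodes
#'
#' `Z_AE = ReLU(Dv^(-1/2) H Da^(-1) Y_AE1 W_AE2)`: node embeddings are
#' updated from the degree-normalized embeddings of their attributes.
#'
#' @param Y_AE1 `d x d2` attribute embeddings.
#' @param H `m x d` attribute incidence matrix.
#' @param dv,da node and attribute degree vectors (strictly positive).
#' @param W_AE2 `d2 x d2` second-layer filter.
#' @return `m x d2` attribute-channel node embedding.
#' @export
update_nodes <- function(Y_AE1, H, dv, da, W_AE2) {
  if (any(da <= 0)) stop("attribute degrees must be strictly positive",
                         call. = FALSE)
  if (ncol(Y_AE1) != nrow(W_AE2)) stop("shape mismatch: Y_AE1 vs W_AE2",
                                       call. = FALSE)
  Hn <- sweep(H / sqrt(dv), 2L, da, "/")   # Dv^(-1/2) H Da^(-1)
  relu(Hn %*% Y_AE1 %*% W_AE2)
}

#' Full attribute encoder
#'
#' Composes [aggregate_to_attributes()] and [update_nodes()] — the
#' node-to-attribute-to-node two-layer hypergraph convolution in which the
#' hyperedges are the attributes themselves.
#'
#' @param hn an [attribute_hypernetwork].
#' @param W_AE1,W_AE2 the two convolution filters.
#' @return `m x d2` attribute-channel node embedding.
#' @export
encode_attributes <- function(hn, W_AE1, W_AE2) {
  Y1 <- aggregate_to_attributes(hn$X, hn$H, hn$dv, W_AE1)
  update_nodes(Y1, hn$H, hn$dv, hn$da, W_AE2)
}

#' Fuse the structural and attribute channels
#'
#' `Z_v = W_FF [Z_SE || Z_AE]` applied row-wise (structure first). Either
#' argument may be `NULL` under the single-channel ablations.
#'
#' @param Z_SE,Z_AE channel embeddings with equal row counts.
#' @param W_FF `dv x (d1+d2)` fusion matrix.
#' @return `m x dv` fused node embedding.
#' @export
fuse <- function(Z_SE, Z_AE, W_FF) {
  if (!is.null(Z_SE) && !is.null(Z_AE) && nrow(Z_SE) != nrow(Z_AE)) {
    stop("channel row counts differ", call. = FALSE)
  }
  cbind(Z_SE, Z_AE) %*% t(W_FF)
}

#' Hyperedge-level attention over a hyperedge's members
#'
#' Raw member score `w' tanh(W_EA z_i)`, softmax-normalized over the
#' members of `e`; weights sum to 1.
#'
#' @param Z_v `m x dv` fused node embeddings.
#' @param e integer vector of 0-based member node ids (nonempty).
#' @param W_EA `d_EA x dv` attention projection; `w` length-`d_EA` vector.
#' @param w attention vector.
#' @param uniform if `TRUE`, return uniform `1/|e|` weights.
#' @return numeric weight vector aligned with `e`.
#' @export
hyperedge_attention <- function(Z_v, e, W_EA = NULL, w = NULL,
                                uniform = FALSE) {
  if (length(e) == 0L) stop("empty hyperedge", call. = FALSE)
  if (any(e < 0L) || any(e >= nrow(Z_v))) stop("member id out of range",
                                               call. = FALSE)
  if (uniform) return(rep(1 / length(e), length(e)))
  Q <- tanh(Z_v[e + 1L, , drop = FALSE] %*% t(W_EA))
  r <- as.numeric(Q %*% w)
  ex <- exp(r - max(r))
  ex / sum(ex)
}

#' Pool member embeddings into a hyperedge embedding
#'
#' `Z_e = sum_{i in e} a_i Z_v[i]` with normalized weights `a`.
#'
#' @param Z_v `m x dv` node embeddings.
#' @param e 0-based member ids.
#' @param weights normalized weights over `e`.
#' @return length-`dv` numeric vector.
#' @export
embed_hyperedge <- function(Z_v, e, weights) {
  as.numeric(crossprod(Z_v[e + 1L, , drop = FALSE], weights))
}

#' Score a hyperedge embedding
#'
#' `s(e) = sigmoid(u' ReLU(W_SC Z_e + b_SC))`: a one-hidden-layer scorer
#' collapsed to a scalar strictly inside (0, 1).
#'
#' @param Z_e length-`dv` hyperedge embedding.
#' @param W_SC `de x dv` scoring matrix; `b_SC`, `u` length-`de` vectors.
#' @param b_SC bias vector.
#' @param u output projection vector.
#' @return scalar score in (0, 1).
#' @export
score_hyperedge <- function(Z_e, W_SC, b_SC, u) {
  h <- relu(as.numeric(W_SC %*% Z_e) + b_SC)
  sigmoid(sum(u * h))
}
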