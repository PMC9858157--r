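# Batch forward/backward engine.
#
# The full computation graph (both encoder channels, fusion, hyperedge
# pooling, scoring, ranking loss) is differentiated analytically; the
# gradient of every trainable parameter is accumulated in one backward
# sweep mirroring the forward caches. Finite-difference agreement is
# enforced in the test suite.

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# quantities that depend only on the hypernetwork, reused across epochs
precompute_graph <- function(hn) {
  pairs <- neighbor_pairs(hn$neighborhoods)
  Hs <- hn$H / sqrt(hn$dv)                    # Dv^(-1/2) H
  list(
    pairs = pairs,
    nbr_sizes = lengths(hn$neighborhoods),
    Hs = Hs,
    Hn = sweep(Hs, 2L, hn$da, "/"),           # Dv^(-1/2) H Da^(-1)
    G0 = crossprod(Hs, hn$X)                  # H' Dv^(-1/2) X  (d x d)
  )
}

dropout_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix(stats::rbinom(nr * nc, 1L, 1 - rate) / (1 - rate), nr, nc)
}

# forward pass over all nodes; caches everything backward needs
forward_nodes <- function(params, hn, config, pc, training = FALSE) {
  rate <- if (training) config$dropout else 0
  cache <- list(pc = pc, training = training)
  Z_SE <- NULL
  Z_AE <- NULL

  if (config$use_structure) {
    pre1 <- sweep(hn$X %*% params$W_SE, 2L, -params$b_SE)
    Z1 <- relu(pre1)
    maskZ <- dropout_mask(nrow(Z1), ncol(Z1), rate)
    Z1d <- if (is.null(maskZ)) Z1 else Z1 * maskZ
    ii <- pc$pairs$ii; jj <- pc$pairs$jj
    if (config$uniform_node_attention) {
      alpha <- 1 / pc$nbr_sizes[ii]
      g <- NULL
    } else {
      p <- as.numeric(crossprod(params$W_NA, params$a))
      d1 <- ncol(Z1d)
      si <- as.numeric(Z1d %*% p[seq_len(d1)])
      tj <- as.numeric(Z1d %*% p[d1 + seq_len(d1)])
      g <- si[ii] + tj[jj]
      omega <- leaky_relu(g, config$leaky_slope)
      if (any(!is.finite(omega))) stop("non-finite attention logits",
                                       call. = FALSE)
      alpha <- softmax_by_group(omega, ii, hn$m)
      cache$p <- p
    }
    maskA <- if (rate > 0)
      stats::rbinom(length(alpha), 1L, 1 - rate) / (1 - rate) else NULL
    alphad <- if (is.null(maskA)) alpha else alpha * maskA
    A <- Matrix::sparseMatrix(i = ii, j = jj, x = alphad,
                              dims = c(hn$m, hn$m))
    Z_SE <- as.matrix(A %*% Z1d)
    cache <- c(cache, list(pre1 = pre1, Z1d = Z1d, maskZ = maskZ,
                           alpha = alpha, alphad = alphad, maskA = maskA,
                           g = g, A = A))
  }

  if (config$use_attribute) {
    Y1 <- pc$G0 %*% params$W_AE1               # H' Dv^(-1/2) X W_AE1
    maskY <- dropout_mask(nrow(Y1), ncol(Y1), rate)
    Y1d <- if (is.null(maskY)) Y1 else Y1 * maskY
    T2 <- pc$Hn %*% Y1d
    P <- T2 %*% params$W_AE2
    Z_AE <- relu(P)
    cache <- c(cache, list(Y1d = Y1d, maskY = maskY, T2 = T2, P = P))
  }

  C <- cbind(Z_SE, Z_AE)
  Z_v <- C %*% t(params$W_FF)
  cache$C <- C
  cache$Z_v <- Z_v
  cache$Z_SE <- Z_SE
  cache$Z_AE <- Z_AE
  cache
}

# score a batch of hyperedges given the node forward cache
forward_edges <- function(params, cache, edges, config) {
  sizes <- lengths(edges)
  B <- length(edges)
  en <- rep.int(seq_len(B), sizes)
  vn <- unlist(edges, use.names = FALSE) + 1L
  Zv_mem <- cache$Z_v[vn, , drop = FALSE]
  if (config$uniform_edge_attention) {
    beta <- 1 / sizes[en]
    Qm <- NULL
    rlog <- NULL
  } else {
    Qm <- tanh(Zv_mem %*% t(params$W_EA))
    rlog <- as.numeric(Qm %*% params$w)
    beta <- softmax_by_group(rlog, en, B)
  }
  fB <- factor(en, levels = seq_len(B))
  Ze <- rowsum(beta * Zv_mem, fB)
  preS <- sweep(Ze %*% t(params$W_SC), 2L, -params$b_SC)
  Hh <- relu(preS)
  logit <- as.numeric(Hh %*% params$u)
  list(scores = sigmoid(logit), en = en, vn = vn, beta = beta, Qm = Qm,
       Zv_mem = Zv_mem, Ze = Ze, preS = preS, Hh = Hh, logit = logit,
       B = B)
}

#' Ranking loss over positive and sampled negative hyperedge scores
#'
#' `L = (1/|E1|) sum_i softplus(nbar_i - s(e_i))` where, in `"mean"` mode,
#' `nbar_i` is the mean negative score of the batch (the loss as written),
#' and in `"paired"` mode `nbar_i` is the score of positive `i`'s own
#' matched negative. Softplus is evaluated in its numerically stable form.
#'
#' @param scores_pos,scores_neg numeric score vectors (nonempty, finite;
#'   equal length required in `"paired"` mode).
#' @param mode `"mean"` or `"paired"`.
#' @return scalar loss.
#' @export
ranking_loss <- function(scores_pos, scores_neg, mode = c("mean", "paired")) {
  mode <- match.arg(mode)
  if (length(scores_pos) == 0L || length(scores_neg) == 0L) {
    stop("empty score batch", call. = FALSE)
  }
  if (any(!is.finite(scores_pos)) || any(!is.finite(scores_neg))) {
    stop("non-finite scores", call. = FALSE)
  }
  if (mode == "mean") {
    mean(softplus(mean(scores_neg) - scores_pos))
  } else {
    if (length(scores_pos) != length(scores_neg)) {
      stop("paired mode needs matched batches", call. = FALSE)
    }
    mean(softplus(scores_neg - scores_pos))
  }
}

# rowsum over groups 1..n_groups, keeping zero rows for absent groups
rowsum_full <- function(x, group, n_groups) {
  rs <- rowsum(x, group)
  out <- matrix(0, n_groups, ncol(x))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

zero_like <- function(params) {
  lapply(params, function(p) if (is.matrix(p)) p * 0 else numeric(length(p)))
}

# loss + analytic gradients for one mini-batch (positives then negatives)
loss_and_gradients <- function(params, hn, pos_edges, neg_edges, config, pc,
                               training = FALSE) {
  cache <- forward_nodes(params, hn, config, pc, training)
  edges <- c(pos_edges, neg_edges)
  fe <- forward_edges(params, cache, edges, config)
  np <- length(pos_edges); nn <- length(neg_edges)
  sp <- fe$scores[seq_len(np)]
  sn <- fe$scores[np + seq_len(nn)]
  loss <- ranking_loss(sp, sn, config$loss_mode)

  ds <- numeric(np + nn)
  if (config$loss_mode == "mean") {
    sg <- sigmoid(mean(sn) - sp)
    ds[seq_len(np)] <- -sg / np
    ds[np + seq_len(nn)] <- sum(sg) / (np * nn)
  } else {
    sg <- sigmoid(sn - sp)
    ds[seq_len(np)] <- -sg / np
    ds[np + seq_len(nn)] <- sg / np
  }

  gr <- zero_like(params)
  m <- hn$m

  # --- scoring head ---
  s <- fe$scores
  dlogit <- ds * s * (1 - s)
  gr$u <- as.numeric(crossprod(fe$Hh, dlogit))
  dHh <- outer(dlogit, params$u)
  dpreS <- dHh * (fe$preS > 0)
  gr$W_SC <- crossprod(dpreS, fe$Ze)
  gr$b_SC <- colSums(dpreS)
  dZe <- dpreS %*% params$W_SC

  # --- hyperedge pooling ---
  en <- fe$en; vn <- fe$vn; B <- fe$B
  fB <- factor(en, levels = seq_len(B))
  dZe_mem <- dZe[en, , drop = FALSE]
  dZv <- rowsum_full(fe$beta * dZe_mem, vn, m)
  if (!config$uniform_edge_attention) {
    dbeta <- rowSums(dZe_mem * fe$Zv_mem)
    sgrp <- as.numeric(rowsum(fe$beta * dbeta, fB))
    dr <- fe$beta * (dbeta - sgrp[en])
    gr$w <- as.numeric(crossprod(fe$Qm, dr))
    dQm <- outer(dr, params$w)
    dpreQ <- dQm * (1 - fe$Qm^2)
    gr$W_EA <- crossprod(dpreQ, fe$Zv_mem)
    dZv <- dZv + rowsum_full(dpreQ %*% params$W_EA, vn, m)
  }

  # --- fusion ---
  gr$W_FF <- crossprod(dZv, cache$C)
  dC <- dZv %*% params$W_FF
  col0 <- 0L
  dZ_SE <- NULL; dZ_AE <- NULL
  if (config$use_structure) {
    dZ_SE <- dC[, seq_len(config$d1), drop = FALSE]
    col0 <- config$d1
  }
  if (config$use_attribute) {
    dZ_AE <- dC[, col0 + seq_len(config$d2), drop = FALSE]
  }

  # --- attribute channel ---
  if (config$use_attribute) {
    dP <- dZ_AE * (cache$P > 0)
    gr$W_AE2 <- crossprod(cache$T2, dP)
    dT2 <- dP %*% t(params$W_AE2)
    dY1d <- crossprod(pc$Hn, dT2)
    dY1 <- if (is.null(cache$maskY)) dY1d else dY1d * cache$maskY
    gr$W_AE1 <- crossprod(pc$G0, dY1)
  }

  # --- structure channel ---
  if (config$use_structure) {
    ii <- pc$pairs$ii; jj <- pc$pairs$jj
    fI <- factor(ii, levels = seq_len(m))
    fJ <- factor(jj, levels = seq_len(m))
    dZ1d <- as.matrix(Matrix::crossprod(cache$A, dZ_SE))
    dalphad <- rowSums(dZ_SE[ii, , drop = FALSE] *
                         cache$Z1d[jj, , drop = FALSE])
    dalpha <- if (is.null(cache$maskA)) dalphad else dalphad * cache$maskA
    if (!config$uniform_node_attention) {
      alpha <- cache$alpha
      sgrp2 <- as.numeric(rowsum(alpha * dalpha, fI))
      domega <- alpha * (dalpha - sgrp2[ii])
      dg <- domega * ifelse(cache$g > 0, 1, config$leaky_slope)
      dsi <- as.numeric(rowsum(dg, fI))
      dtj <- as.numeric(rowsum(dg, fJ))
      d1 <- config$d1
      dpl <- as.numeric(crossprod(cache$Z1d, dsi))
      dpr <- as.numeric(crossprod(cache$Z1d, dtj))
      dp <- c(dpl, dpr)
      gr$a <- as.numeric(params$W_NA %*% dp)
      gr$W_NA <- outer(params$a, dp)
      p <- cache$p
      dZ1d <- dZ1d + outer(dsi, p[seq_len(d1)]) +
        outer(dtj, p[d1 + seq_len(d1)])
    }
    dZ1 <- if (is.null(cache$maskZ)) dZ1d else dZ1d * cache$maskZ
    dpre1 <- dZ1 * (cache$pre1 > 0)
    gr$W_SE <- crossprod(hn$X, dpre1)
    gr$b_SE <- colSums(dpre1)
  }

  list(loss = loss, grads = gr, scores_pos = sp, scores_neg = sn)
}

#' Ranking loss and analytic parameter gradients for one batch
#'
#' Runs the full forward pass on the positive and negative hyperedge
#' batches and backpropagates the ranking loss through the scoring head,
#' hyperedge pooling, fusion, and both encoder channels. With
#' `training = FALSE` (default) dropout is disabled and the result is
#' deterministic, which is the mode used for gradient verification.
#'
#' @param params parameter list from [init_params()].
#' @param hn an [attribute_hypernetwork].
#' @param pos_edges,neg_edges lists of 0-based node-id vectors.
#' @param config an [ahlp_config()].
#' @param training apply dropout (masks drawn from the current RNG).
#' @return list with `loss`, `grads` (named like `params`), and the two
#'   score vectors.
#' @export
model_loss_gradients <- function(params, hn, pos_edges, neg_edges, config,
                                 training = FALSE) {
  pc <- precompute_graph(hn)
  loss_and_gradients(params, hn, pos_edges, neg_edges, config, pc,
                     training = training)
}

#' Score hyperedges with a parameter set
#'
#' Deterministic inference-mode forward pass (dropout disabled).
#'
#' @param params parameter list from [init_params()] or a trained model.
#' @param hn an [attribute_hypernetwork].
#' @param edges list of 0-based node-id vectors to score.
#' @param config the matching [ahlp_config()].
#' @return numeric vector of scores in (0, 1).
#' @export
model_scores <- function(params, hn, edges, config) {
  pc <- precompute_graph(hn)
  cache <- forward_nodes(params, hn, config, pc, training = FALSE)
  forward_edges(params, cache, edges, config)$scores
}

#' Fused node embeddings for a parameter set
#'
#' @inheritParams model_scores
#' @return `m x dv` matrix of fused node embeddings `Z_v`.
#' @export
node_embeddings <- function(params, hn, config) {
  pc <- precompute_graph(hn)
  forward_nodes(params, hn, config, pc, training = FALSE)$Z_v
}

#' Per-channel node embeddings (inference mode)
#'
#' Runs both encoder channels and the fusion layer without dropout and
#' returns the intermediate embeddings.
#'
#' @inheritParams model_scores
#' @return list with `Z_SE` (structure channel, or `NULL` if disabled),
#'   `Z_AE` (attribute channel, or `NULL`), and fused `Z_v`.
#' @export
forward_channels <- function(params, hn, config) {
  pc <- precompute_graph(hn)
  cache <- forward_nodes(params, hn, config, pc, training = FALSE)
  list(Z_SE = cache$Z_SE, Z_AE = cache$Z_AE, Z_v = cache$Z_v)
}
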