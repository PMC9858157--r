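#' Tie-aware AUC from positive and negative scores
#'
#' Probability that a random positive outscores a random negative, with
#' ties counted 1/2: `(1/(N*M)) sum_ij I(s_pos_i, s_neg_j)` where `I` is
#' 1 / 0.5 / 0 for greater / equal / less. Computed exactly via midranks,
#' which reproduces the pairwise indicator including ties.
#'
#' @param scores_pos,scores_neg nonempty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores_pos, scores_neg) {
  N <- length(scores_pos)
  M <- length(scores_neg)
  if (N == 0L || M == 0L) stop("empty score vector", call. = FALSE)
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(N)]) - N * (N + 1) / 2) / (N * M)
}

#' Recall at k over a ranked candidate list
#'
#' Candidates are ranked by score (descending, ties broken by original
#' candidate order, which is stable), `k = ceiling(L / 2)` with `L` the
#' number of truly missing hyperedges, and `R@k` is the fraction of the
#' `L` positives recovered among the top `k` — so it can never exceed
#' `k / L` (about one half).
#'
#' @param scores numeric candidate scores.
#' @param labels 0/1 labels aligned with `scores`; must contain all `L`
#'   positives.
#' @param L number of true missing hyperedges (default `sum(labels)`).
#' @return recall value in `[0, min(1, k/L)]`.
#' @export
recall_at_k <- function(scores, labels, L = sum(labels)) {
  if (length(scores) != length(labels)) stop("length mismatch",
                                             call. = FALSE)
  if (L < 1L) stop("L must be >= 1", call. = FALSE)
  k <- ceiling(L / 2)
  ord <- order(-scores)                 # stable: ties keep candidate order
  sum(labels[ord][seq_len(min(k, length(scores)))]) / L
}

#' Mean-pairwise-similarity hyperedge score for plain node embeddings
#'
#' The scoring rule used to lift pairwise embedding methods to hyperedges:
#' `sigmoid((1/|e|) * sum_{i<j in e} x_i' x_j)`. Note the normalization is
#' by the hyperedge size `|e|`, not by the number of pairs.
#'
#' @param node_embeddings `m x k` matrix of node embeddings.
#' @param e integer vector of 0-based member ids, `|e| >= 2`.
#' @return scalar score in (0, 1).
#' @export
baseline_pairwise_score <- function(node_embeddings, e) {
  e <- unique(as.integer(e))
  if (length(e) < 2L) stop("hyperedge must have >= 2 nodes", call. = FALSE)
  Z <- node_embeddings[e + 1L, , drop = FALSE]
  G <- Z %*% t(Z)
  tot <- (sum(G) - sum(diag(G))) / 2
  sigmoid(tot / length(e))
}

#' Evaluate a trained model on the held-out test hyperedges
#'
#' Scores the test positives and `neg_ratio` sampled negatives per
#' positive (size-matched, avoiding every observed hyperedge), computes
#' tie-aware AUC and R@k, and averages over `n_runs` independent negative
#' resamplings.
#'
#' @param model an `ahlp_model` (or any parameter list + config via
#'   `params`/`config` arguments of [model_scores()]).
#' @param hn the attribute hypernetwork.
#' @param split a [split_edges()] partition with a nonempty `test` set.
#' @param seed seed for negative resampling.
#' @param n_runs number of independent negative-resampling repetitions.
#' @param neg_ratio sampled negatives per test positive.
#' @return list of class `ahlp_eval`: `auc`, `r_at_k`, `k`, `n_pos`,
#'   `n_neg`, `n_runs`, `seed`, per-run values, and the last run's score
#'   table.
#' @export
evaluate_model <- function(model, hn, split, seed = 1L, n_runs = 1L,
                           neg_ratio = 1L) {
  if (length(split$test) == 0L) stop("empty test set", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  test_edges <- hn$hyperedges[split$test]
  observed_keys <- vapply(hn$hyperedges, edge_key, "")
  L <- length(test_edges)
  pos_scores <- predict_scores(model, hn, test_edges)

  aucs <- numeric(n_runs)
  recalls <- numeric(n_runs)
  table_last <- NULL
  for (r in seq_len(n_runs)) {
    negs <- unlist(lapply(test_edges, function(e) {
      lapply(seq_len(neg_ratio), function(.)
        sample_negative(e, hn$m, observed_keys))
    }), recursive = FALSE)
    neg_scores <- predict_scores(model, hn, negs)
    aucs[r] <- auc_score(pos_scores, neg_scores)
    scores <- c(pos_scores, neg_scores)
    labels <- c(rep(1L, L), rep(0L, length(negs)))
    recalls[r] <- recall_at_k(scores, labels, L)
    if (r == n_runs) {
      table_last <- data.frame(
        hyperedge = c(vapply(test_edges, edge_key, ""),
                      vapply(negs, edge_key, "")),
        score = scores, label = labels)
    }
  }
  structure(list(auc = mean(aucs), r_at_k = mean(recalls),
                 k = ceiling(L / 2), n_pos = L, n_neg = L * neg_ratio,
                 n_runs = n_runs, seed = as.integer(seed),
                 auc_runs = aucs, r_at_k_runs = recalls,
                 score_table = table_last),
            class = "ahlp_eval")
}

#' @exportS3Method base::print
print.ahlp_eval <- function(x, ...) {
  cat(sprintf(
    "hyperlink evaluation: AUC %.4f  R@%d %.4f  (%d pos / %d neg, %d run%s)\n",
    x$auc, x$k, x$r_at_k, x$n_pos, x$n_neg, x$n_runs,
    if (x$n_runs > 1) "s" else ""))
  invisible(x)
}
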