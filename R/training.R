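#' Sample a negative hyperedge matched in size to a positive one
#'
#' A hard negative keeps `floor(|e|/2)` nodes drawn uniformly without
#' replacement from the observed hyperedge `e` and fills the remainder
#' (the majority, for odd sizes) from the rest of the node universe, so
#' `|e_neg| = |e|`. If the draw collides with an observed hyperedge it is
#' redrawn, up to 100 times.
#'
#' @param e integer vector of 0-based node ids, `|e| >= 2`.
#' @param m number of nodes in the universe.
#' @param forbidden optional character set of canonical hyperedge keys
#'   (from [edge_key()]) that the sample must avoid (e.g. all observed
#'   hyperedges).
#' @return sorted integer vector of 0-based ids, same length as `e`.
#' @export
sample_negative <- function(e, m, forbidden = NULL) {
  e <- unique(as.integer(e))
  k <- length(e)
  if (k < 2L) stop("positive hyperedge must have >= 2 nodes", call. = FALSE)
  n_in <- k %/% 2L
  n_out <- k - n_in
  outside <- setdiff(0:(m - 1L), e)
  if (length(outside) < n_out) {
    stop("node universe too small to sample ", n_out, " outside nodes",
         call. = FALSE)
  }
  for (try in seq_len(100L)) {
    inside <- if (n_in > 0L) e[sample.int(k, n_in)] else integer(0)
    rest <- outside[sample.int(length(outside), n_out)]
    neg <- sort(c(inside, rest))
    if (is.null(forbidden) || !(edge_key(neg) %in% forbidden)) return(neg)
  }
  neg
}

#' Canonical string key of a hyperedge (sorted ids)
#' @param e integer vector of node ids.
#' @return a single string.
#' @export
edge_key <- function(e) paste(sort(unique(as.integer(e))), collapse = " ")

#' Random train/validation/test split of hyperedges
#'
#' Hides 20% of the hyperedges as the test set, keeps 70% for training and
#' 10% for validation; reproducible per seed.
#'
#' @param n_edges total number of hyperedges (`>= 10`).
#' @param seed integer seed.
#' @return list with integer index vectors `train`, `val`, `test`
#'   (1-based, disjoint, covering `1..n_edges`) and the `seed`.
#' @export
split_edges <- function(n_edges, seed = 1L) {
  if (n_edges < 10L) stop("need at least 10 hyperedges to split",
                          call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample.int(n_edges)
  n_train <- round(0.7 * n_edges)
  n_val <- round(0.1 * n_edges)
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[(n_train + n_val + 1L):n_edges]),
       seed = as.integer(seed))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the hyperlink predictor
#'
#' Runs the full optimization loop: per epoch, resample one size-matched
#' negative per training hyperedge, iterate mini-batches of the ranking
#' loss with Adam, track validation AUC against a frozen validation
#' negative set, and keep the best-validation parameter snapshot. Early
#' stopping after `config$patience` epochs without improvement. All
#' randomness (initialization, negative sampling, dropout, batching) flows
#' from `config$seed`, so a rerun with the same inputs is bitwise
#' reproducible.
#'
#' @param hn an [attribute_hypernetwork].
#' @param split a [split_edges()] partition (or `NULL` to train on all
#'   hyperedges without validation).
#' @param config an [ahlp_config()].
#' @param verbose print per-epoch progress.
#' @return an object of class `ahlp_model`: `params` (best snapshot),
#'   `final_params`, `config`, `history` (data.frame epoch/loss/val_auc),
#'   `split`, `best_epoch`.
#' @export
train_model <- function(hn, split = NULL, config = ahlp_config(),
                        verbose = FALSE) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  runs <- lapply(seq_len(config$restarts), function(k) {
    train_once(hn, split, config,
               seed = config$seed + (k - 1L) * 100003L, verbose = verbose)
  })
  crit <- vapply(runs, function(r) {
    bv <- r$history$val_auc[r$best_epoch]
    if (length(bv) == 1L && !is.na(bv)) bv else r$fit_criterion
  }, 0)
  best <- runs[[which.max(crit)]]
  best$restart_criteria <- crit
  best
}

train_once <- function(hn, split, config, seed, verbose = FALSE) {
  set.seed(seed)

  train_idx <- if (is.null(split)) seq_len(hn$n) else split$train
  val_idx <- if (is.null(split)) integer(0) else split$val
  train_edges <- hn$hyperedges[train_idx]
  observed_keys <- vapply(hn$hyperedges, edge_key, "")

  params <- init_params(hn$d, config)
  pc <- precompute_graph(hn)
  state <- adam_init(params)

  # frozen validation negatives for comparable epoch-to-epoch AUC; several
  # per positive so the model-selection signal is not dominated by
  # sampling noise on a small validation set
  val_neg <- unlist(lapply(hn$hyperedges[val_idx], function(e) {
    lapply(seq_len(5L), function(.) sample_negative(e, hn$m, observed_keys))
  }), recursive = FALSE)

  best_params <- params
  best_val <- -Inf
  best_epoch <- 0L
  stale <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_auc = numeric(0))

  n_tr <- length(train_edges)
  for (epoch in seq_len(config$max_epochs)) {
    negs <- unlist(lapply(train_edges, function(e) {
      lapply(seq_len(config$negatives_per_positive), function(.)
        sample_negative(e, hn$m, observed_keys))
    }), recursive = FALSE)
    perm <- sample.int(n_tr)
    nb <- ceiling(n_tr / config$batch_size)
    epoch_loss <- 0
    for (b in seq_len(nb)) {
      idx <- perm[((b - 1L) * config$batch_size + 1L):
                    min(b * config$batch_size, n_tr)]
      nidx <- as.vector(outer(
        (idx - 1L) * config$negatives_per_positive,
        seq_len(config$negatives_per_positive), "+"))
      lg <- loss_and_gradients(params, hn, train_edges[idx], negs[nidx],
                               config, pc, training = config$dropout > 0)
      if (!is.finite(lg$loss)) {
        stop("training diverged: non-finite loss at epoch ", epoch,
             call. = FALSE)
      }
      upd <- adam_step(params, lg$grads, state, config$learning_rate)
      params <- upd$params
      state <- upd$state
      epoch_loss <- epoch_loss + lg$loss * length(idx)
    }
    epoch_loss <- epoch_loss / n_tr

    val_auc <- NA_real_
    if (length(val_idx) > 0L) {
      sv <- forward_edges(params,
                          forward_nodes(params, hn, config, pc, FALSE),
                          c(hn$hyperedges[val_idx], val_neg), config)$scores
      nv <- length(val_idx)
      val_auc <- auc_score(sv[seq_len(nv)], sv[nv + seq_along(val_neg)])
      if (val_auc > best_val) {
        best_val <- val_auc
        best_params <- params
        best_epoch <- epoch
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
    } else {
      best_params <- params
      best_epoch <- epoch
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = epoch_loss,
                                         val_auc = val_auc))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val AUC %s", epoch, epoch_loss,
                      ifelse(is.na(val_auc), "-", sprintf("%.4f", val_auc))))
    }
    if (length(val_idx) > 0L && stale >= config$patience) break
  }

  # fallback restart-selection criterion when there is no validation set:
  # inference-mode ranking loss of the final parameters on the training
  # hyperedges against freshly sampled negatives
  fit_criterion <- -Inf
  if (length(val_idx) == 0L && config$max_epochs > 0L) {
    fit_neg <- lapply(train_edges, sample_negative, m = hn$m,
                      forbidden = observed_keys)
    sc <- forward_edges(params,
                        forward_nodes(params, hn, config, pc, FALSE),
                        c(train_edges, fit_neg), config)$scores
    fit_criterion <- -ranking_loss(sc[seq_len(n_tr)],
                                   sc[n_tr + seq_len(n_tr)],
                                   config$loss_mode)
  }

  structure(list(params = best_params, final_params = params,
                 config = config, history = history, split = split,
                 best_epoch = best_epoch, fit_criterion = fit_criterion),
            class = "ahlp_model")
}

#' @exportS3Method base::print
print.ahlp_model <- function(x, ...) {
  cat("ahlp model:", nrow(x$history), "epochs trained")
  if (nrow(x$history) > 0) {
    cat(sprintf(", final loss %.4f", utils::tail(x$history$loss, 1)))
    bv <- x$history$val_auc[x$best_epoch]
    if (x$best_epoch > 0 && !is.na(bv)) {
      cat(sprintf(", best val AUC %.4f (epoch %d)", bv, x$best_epoch))
    }
  }
  cat("\n")
  invisible(x)
}

#' Score hyperedges with a trained model
#'
#' @param model an `ahlp_model`.
#' @param hn the attribute hypernetwork.
#' @param edges list of 0-based node-id vectors.
#' @return numeric vector of scores in (0, 1).
#' @export
predict_scores <- function(model, hn, edges) {
  model_scores(model$params, hn, edges, model$config)
}

#' Export hyperedge-level attention weights
#'
#' For each requested hyperedge, the softmax-normalized importance weight
#' of every member node under the trained model; weights within a
#' hyperedge sum to 1. These are the per-node contributions used when
#' pooling node embeddings into the hyperedge embedding.
#'
#' @param model an `ahlp_model`.
#' @param hn the attribute hypernetwork.
#' @param edge_ids 1-based indices into `hn$hyperedges` (default: all).
#' @return data.frame with columns `hyperedge_id`, `node_id`, `weight`.
#' @export
export_attention <- function(model, hn, edge_ids = seq_len(hn$n)) {
  if (any(edge_ids < 1L) || any(edge_ids > hn$n)) {
    stop("unknown hyperedge id", call. = FALSE)
  }
  Z_v <- node_embeddings(model$params, hn, model$config)
  rows <- lapply(edge_ids, function(id) {
    e <- hn$hyperedges[[id]]
    w <- hyperedge_attention(Z_v, e, model$params$W_EA, model$params$w,
                             uniform = model$config$uniform_edge_attention)
    data.frame(hyperedge_id = id, node_id = e, weight = w)
  })
  do.call(rbind, rows)
}
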