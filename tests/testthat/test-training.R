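test_that("negative sampler matches the half-inside composition", {
  set.seed(44)
  e4 <- c(2L, 5L, 7L, 9L)
  for (rep in 1:50) {
    neg <- sample_negative(e4, 10L)
    expect_length(neg, 4L)
    expect_equal(length(intersect(neg, e4)), 2L)
  }
  # |e| = 2: one inside, one outside
  for (rep in 1:20) {
    neg <- sample_negative(c(0L, 1L), 6L)
    expect_length(neg, 2L)
    expect_equal(length(intersect(neg, c(0L, 1L))), 1L)
  }
  # odd size: floor(|e|/2) inside, majority outside
  for (rep in 1:20) {
    neg <- sample_negative(c(1L, 3L, 5L), 12L)
    expect_length(neg, 3L)
    expect_equal(length(intersect(neg, c(1L, 3L, 5L))), 1L)
  }
  expect_error(sample_negative(c(0L, 1L, 2L, 3L), 5L), "too small")
  expect_error(sample_negative(1L, 5L), ">= 2 nodes")
})

test_that("negative sampler avoids observed hyperedges and is unbiased", {
  hn <- tiny_hypernetwork()
  keys <- vapply(hn$hyperedges, edge_key, "")
  set.seed(10)
  for (rep in 1:200) {
    neg <- sample_negative(hn$hyperedges[[rep %% 8 + 1]], hn$m, keys)
    expect_false(edge_key(neg) %in% keys)
  }
  # binomial oracle: each inside node kept with prob floor(k/2)/k
  e <- c(0L, 3L, 6L, 9L)
  set.seed(11)
  n_draw <- 10000
  counts <- numeric(4)
  for (rep in seq_len(n_draw)) {
    neg <- sample_negative(e, 40L)
    counts <- counts + (e %in% neg)
  }
  p <- 2 / 4
  sd3 <- 3 * sqrt(p * (1 - p) / n_draw)
  expect_true(all(abs(counts / n_draw - p) < sd3))
})

test_that("edge split is a reproducible 70/10/20 partition", {
  sp <- split_edges(100L, seed = 3L)
  expect_length(sp$train, 70L)
  expect_length(sp$val, 10L)
  expect_length(sp$test, 20L)
  expect_equal(sort(c(sp$train, sp$val, sp$test)), 1:100)
  sp2 <- split_edges(100L, seed = 3L)
  expect_identical(sp, sp2)
  expect_false(identical(sp$test, split_edges(100L, seed = 4L)$test))
  expect_error(split_edges(9L), "at least 10")
  # proportions within one edge of 0.7/0.1/0.2 for awkward sizes
  for (n in c(10L, 37L, 101L)) {
    s <- split_edges(n, 1L)
    expect_lte(abs(length(s$train) - 0.7 * n), 1)
    expect_lte(abs(length(s$val) - 0.1 * n), 1)
    expect_lte(abs(length(s$test) - 0.2 * n), 1)
  }
})

test_that("ranking loss reproduces closed forms and the naive oracle", {
  expect_equal(ranking_loss(rep(0.4, 5), rep(0.4, 5)), log(2),
               tolerance = 1e-12)
  expect_equal(ranking_loss(1, 0), log(1 + exp(-1)), tolerance = 1e-12)
  set.seed(12)
  for (mode in c("mean", "paired")) {
    sp <- runif(7); sn <- runif(7)
    naive <- if (mode == "mean") {
      mean(sapply(sp, function(s) log(1 + exp(mean(sn) - s))))
    } else {
      mean(log(1 + exp(sn - sp)))
    }
    expect_rel_equal(ranking_loss(sp, sn, mode), naive)
  }
  # numerically stable for extreme gaps
  expect_equal(ranking_loss(1000, -1000), 0)
  expect_true(is.finite(ranking_loss(-1000, 1000)))
  expect_error(ranking_loss(numeric(0), 1), "empty")
  expect_error(ranking_loss(NaN, 1), "non-finite")
  expect_error(ranking_loss(c(0.1, 0.2), 0.3, mode = "paired"), "matched")
})

test_that("loss at random initialization concentrates near log 2", {
  hn <- tiny_hypernetwork()
  keys <- vapply(hn$hyperedges, edge_key, "")
  losses <- sapply(1:10, function(s) {
    cfg <- tiny_config(seed = s)
    set.seed(s)
    params <- init_params(hn$d, cfg)
    negs <- lapply(hn$hyperedges, sample_negative, m = hn$m,
                   forbidden = keys)
    ranking_loss(model_scores(params, hn, hn$hyperedges, cfg),
                 model_scores(params, hn, negs, cfg))
  })
  expect_true(all(abs(losses - log(2)) < 0.05))
})

test_that("analytic gradients agree with central finite differences", {
  hn <- tiny_hypernetwork()
  cfg <- tiny_config(dropout = 0, seed = 3L)
  set.seed(3)
  params <- perturb_off_kink(init_params(hn$d, cfg))
  pos <- hn$hyperedges[c(1, 4, 7)]
  set.seed(31)
  keys <- vapply(hn$hyperedges, edge_key, "")
  neg <- lapply(pos, sample_negative, m = hn$m, forbidden = keys)
  lg <- model_loss_gradients(params, hn, pos, neg, cfg)
  h <- 1e-5
  set.seed(13)
  for (nm in names(params)) {
    # a few random entries per parameter tensor
    for (rep in 1:2) {
      idx <- sample(length(params[[nm]]), 1)
      p2 <- params; p2[[nm]][idx] <- p2[[nm]][idx] + h
      fp <- model_loss_gradients(p2, hn, pos, neg, cfg)$loss
      p2 <- params; p2[[nm]][idx] <- p2[[nm]][idx] - h
      fm <- model_loss_gradients(p2, hn, pos, neg, cfg)$loss
      fd <- (fp - fm) / (2 * h)
      an <- lg$grads[[nm]][idx]
      expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-6), 1e-4)
    }
  }
})

test_that("training is deterministic and zero epochs return the init", {
  hn <- tiny_hypernetwork()
  cfg <- tiny_config(max_epochs = 4L, batch_size = 4L, seed = 7L)
  m1 <- train_model(hn, NULL, cfg)
  m2 <- train_model(hn, NULL, cfg)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_identical(m1$params, m2$params)

  cfg0 <- tiny_config(max_epochs = 0L, seed = 7L)
  m0 <- train_model(hn, NULL, cfg0)
  set.seed(7L)
  expect_identical(m0$params, init_params(hn$d, cfg0))
  expect_equal(nrow(m0$history), 0L)
})

test_that("training loss decreases overall on the tiny fixture", {
  hn <- tiny_hypernetwork()
  cfg <- tiny_config(max_epochs = 60L, batch_size = 4L, dropout = 0,
                     seed = 1L)
  m <- train_model(hn, NULL, cfg)
  ls <- m$history$loss
  expect_lt(tail(ls, 1), ls[1])
  # the per-epoch loss is noisy because negatives are resampled every
  # epoch; the downward trend is asserted on 10-epoch block means, of
  # which >= 90% of consecutive pairs must be non-increasing
  blocks <- tapply(ls, (seq_along(ls) - 1L) %/% 10L, mean)
  expect_gte(mean(diff(blocks) <= 1e-4), 0.9)
})

test_that("training keeps the best validation snapshot and can early-stop", {
  hn <- tiny_hypernetwork()
  split <- list(train = 1:5, val = 6L, test = 7:8, seed = 1L)
  cfg <- tiny_config(max_epochs = 30L, batch_size = 5L, patience = 5L,
                     seed = 2L)
  m <- train_model(hn, split, cfg)
  expect_true(m$best_epoch >= 1)
  expect_true(nrow(m$history) <= 30)
  best_val <- max(m$history$val_auc, na.rm = TRUE)
  expect_equal(m$history$val_auc[m$best_epoch], best_val)
})
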