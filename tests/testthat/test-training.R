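# Brute-force per-element loss oracles (plain loops, no vectorization).
mse_oracle <- function(truth, pred, mask) {
  tot <- 0
  for (j in seq_len(nrow(truth))) {
    M <- sum(mask[j, ] > 0)
    acc <- 0
    for (i in seq_len(ncol(truth))) {
      if (mask[j, i] > 0) acc <- acc + (truth[j, i] - pred[j, i])^2
    }
    tot <- tot + acc / M
  }
  tot / nrow(truth)
}

ce_oracle <- function(truth_list, pred_list, eps = 1e-12) {
  tot <- 0
  for (j in seq_along(truth_list)) {
    s <- 0
    Tn <- nrow(truth_list[[j]])
    for (i in seq_len(Tn)) {
      for (k in seq_len(ncol(truth_list[[j]]))) {
        s <- s - truth_list[[j]][i, k] * log(max(pred_list[[j]][i, k], eps))
      }
    }
    tot <- tot + s / Tn
  }
  tot / length(truth_list)
}

test_that("masked MSE matches its hand-computed example and the loop oracle", {
  expect_equal(masked_mse(c(1, 2, 3, 4), c(1, 2, 5, 4), c(1, 1, 1, 0)),
               4 / 3)
  expect_equal(masked_mse(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1)), 0)
  # outer mean over samples: per-sample losses 1 and 3 -> 2
  truth <- rbind(c(1, 0), c(0, 0))
  pred <- rbind(c(2, 1), c(sqrt(3), 5))
  mask <- rbind(c(1, 0), c(1, 0))
  expect_equal(masked_mse(truth, pred, mask), 2)
  expect_error(masked_mse(c(1), c(1), c(0)), "empty mask")

  set.seed(10)
  for (i in 1:100) {
    n <- sample(1:6, 1); Tn <- sample(2:20, 1)
    truth <- matrix(rnorm(n * Tn), n, Tn)
    pred <- matrix(rnorm(n * Tn), n, Tn)
    mask <- matrix(rbinom(n * Tn, 1, 0.7), n, Tn)
    mask[, 1] <- 1
    expect_equal(masked_mse(truth, pred, mask), mse_oracle(truth, pred, mask),
                 tolerance = 1e-10)
  }
})

test_that("class cross-entropy matches closed forms and the loop oracle", {
  onehot <- diag(4)[c(1, 2, 3, 4), ]
  expect_equal(class_ce(onehot, onehot), 0, tolerance = 1e-9)
  uniform <- matrix(0.25, 4, 4)
  expect_equal(class_ce(onehot, uniform), log(4))
  # clipping bounds the loss for a zero-probability true class
  zeros <- matrix(c(0, 1, 0, 0), 1, 4)
  truth1 <- matrix(c(1, 0, 0, 0), 1, 4)
  expect_true(is.finite(class_ce(truth1, zeros)))

  set.seed(11)
  for (i in 1:100) {
    n <- sample(1:4, 1); Tn <- sample(2:15, 1)
    truth <- purrr::map(seq_len(n), function(j) diag(4)[sample(1:4, Tn, TRUE), ])
    pred <- purrr::map(seq_len(n), function(j) {
      p <- matrix(stats::runif(Tn * 4), Tn, 4)
      p / rowSums(p)
    })
    expect_equal(class_ce(truth, pred), ce_oracle(truth, pred),
                 tolerance = 1e-10)
  }
})

test_that("the multitask loss combines with the 0.01 weight", {
  expect_equal(total_loss(1, 2), 1.02)
  expect_equal(total_loss(0.5, 0), 0.5)
  expect_equal(total_loss(0.5, 3, lambda = 0), 0.5)
})

test_that("cross-entropy is zero exactly at one-hot truth", {
  truth <- diag(4)[c(2, 4), ]
  expect_equal(class_ce(truth, truth), 0, tolerance = 1e-9)
  off <- truth
  off[1, ] <- c(0.05, 0.9, 0.04, 0.01)
  expect_gt(class_ce(truth, off), 0)
})

test_that("the patience schedule halves at 25 and stops at 50 stale epochs", {
  dec <- lr_schedule(seq(1, 0.5, length.out = 40))
  expect_equal(dec$lr, 1e-3)
  expect_false(dec$stop)
  flat25 <- lr_schedule(c(1, rep(1, 25)))
  expect_equal(flat25$lr, 5e-4)
  expect_false(flat25$stop)
  flat50 <- lr_schedule(c(1, rep(1, 50)))
  expect_true(flat50$stop)
  # improvement resets both counters
  reset <- lr_schedule(c(1, rep(1, 24), 0.9, rep(0.9, 24)))
  expect_equal(reset$lr, 1e-3)
  expect_false(reset$stop)
})

test_that("scenario splits honor subject disjointness and fold sizes", {
  manifest <- tibble::tibble(
    subject_id = rep(sprintf("S%03d", 1:100), each = 10),
    segment_id = sprintf("g%04d", 1:1000))
  mixno <- make_splits(manifest, "Mixno", seed = 6)
  for (f in 1:5) {
    tr <- mixno$subject_id[mixno$fold != f]
    te <- mixno$subject_id[mixno$fold == f]
    expect_length(intersect(unique(tr), unique(te)), 0L)
    expect_equal(dplyr::n_distinct(te), 20L)         # 20% of subjects
  }
  mixyes <- make_splits(manifest, "Mixyes+DI", seed = 6)
  expect_equal(as.integer(table(mixyes$fold)), rep(200L, 5))  # 20% of segments
  expect_error(make_splits(manifest[1:3, ], "Mixno"), "at least")
  expect_true(scenario_uses_di("Mixno+DI"))
  expect_true(scenario_uses_di("Mixyes+DI"))
  expect_false(scenario_uses_di("Mixno"))
})

test_that("a reduced model overfits a handful of synthetic pairs", {
  arch <- tiny_arch(use_di = TRUE)
  model <- init_weights(arch, seed = 3)
  model$fixed_length <- 30L
  samples <- purrr::map(1:8, ~ tiny_sample(arch, seed = .x))
  fitted <- train_seq2seq(model, samples, epochs = 500L, batch_size = 8L,
                          seed = 4)
  expect_lt(min(fitted$history$mse), 1e-3)
  expect_true(all(is.finite(fitted$history$loss)))
  # fixed seed -> reproducible loss history
  fitted2 <- train_seq2seq(init_weights(arch, seed = 3), samples,
                           epochs = 5L, batch_size = 8L, seed = 4)
  fitted3 <- train_seq2seq(init_weights(arch, seed = 3), samples,
                           epochs = 5L, batch_size = 8L, seed = 4)
  expect_equal(fitted2$history, fitted3$history)
  # batch size splits: 8 samples at batch 3 -> batches of 3, 3, 2
  fitted4 <- train_seq2seq(init_weights(arch, seed = 3), samples,
                           epochs = 1L, batch_size = 3L, seed = 4)
  expect_equal(nrow(fitted4$history), 1L)
})

test_that("training refuses a DI-less dataset for a DI model", {
  arch <- tiny_arch(use_di = TRUE)
  model <- init_weights(arch, seed = 3)
  s <- tiny_sample(arch, seed = 1)
  s$x_di <- NULL
  expect_error(train_seq2seq(model, list(s), epochs = 1L), "lacks demographic")
})
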