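# Brute-force GRU oracle: a direct, line-by-line evaluation of the gate
# equations, independent of the C++ path.
gru_oracle <- function(block, h_prev, x) {
  sig <- function(u) 1 / (1 + exp(-u))
  z <- sig(block$Wz %*% x + block$Uz %*% h_prev + block$bz)
  r <- sig(block$Wr %*% x + block$Ur %*% h_prev + block$br)
  hc <- tanh(block$Wh %*% x + block$Uh %*% (r * h_prev) + block$bh)
  drop((1 - z) * h_prev + z * hc)
}

rand_block <- function(m, n) {
  list(Wz = matrix(rnorm(m * n), m, n), Uz = matrix(rnorm(m * m), m, m),
       bz = rnorm(m),
       Wr = matrix(rnorm(m * n), m, n), Ur = matrix(rnorm(m * m), m, m),
       br = rnorm(m),
       Wh = matrix(rnorm(m * n), m, n), Uh = matrix(rnorm(m * m), m, m),
       bh = rnorm(m))
}

test_that("gru_step reproduces the gate equations on closed-form cases", {
  # all-zero weights: z = r = 0.5, h_cand = 0, h = h_prev / 2
  m <- 2L
  zero <- list(Wz = matrix(0, m, 2), Uz = matrix(0, m, m), bz = numeric(m),
               Wr = matrix(0, m, 2), Ur = matrix(0, m, m), br = numeric(m),
               Wh = matrix(0, m, 2), Uh = matrix(0, m, m), bh = numeric(m))
  h <- gru_step(zero, h_prev = c(1, -1), x = c(0.3, 0.7))
  expect_equal(h, c(0.5, -0.5))

  # update gate forced to 1 (huge bias): h = h_cand
  forced <- zero
  forced$bz <- rep(100, m)
  forced$Wh <- matrix(1, m, 2)
  h2 <- gru_step(forced, h_prev = c(1, -1), x = c(0.3, 0.7))
  expect_equal(h2, rep(tanh(1), m), tolerance = 1e-10)
})

test_that("gru_step matches the brute-force oracle on 100 random cases", {
  set.seed(99)
  for (i in 1:100) {
    m <- sample(1:6, 1); n <- sample(1:5, 1)
    blk <- rand_block(m, n)
    h_prev <- rnorm(m); x <- rnorm(n)
    expect_equal(gru_step(blk, h_prev, x), gru_oracle(blk, h_prev, x),
                 tolerance = 1e-12)
  }
})

test_that("attention weights are a softmax of bilinear scores", {
  # equal scores over 4 steps -> uniform weights
  W <- diag(2)
  h_enc <- matrix(1, 2, 4)
  a <- attention(W, c(0.5, 0.5), h_enc)
  expect_equal(a$weights, rep(0.25, 4))

  # W = I, h_t = (1,0), steps (1,0) and (0,1): scores (1, 0)
  h_enc2 <- cbind(c(1, 0), c(0, 1))
  a2 <- attention(diag(2), c(1, 0), h_enc2)
  expect_equal(a2$weights, c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)),
               tolerance = 1e-12)
  expect_equal(a2$context, drop(h_enc2 %*% a2$weights))

  set.seed(3)
  for (i in 1:20) {
    d <- sample(2:5, 1); L <- sample(2:9, 1)
    a3 <- attention(matrix(rnorm(d * d), d, d), rnorm(d),
                    matrix(rnorm(d * L), d, L))
    expect_equal(sum(a3$weights), 1)
  }
})

test_that("model gradients agree with central finite differences", {
  ns <- asNamespace("abpmorph")
  set.seed(42)
  arch <- bp_architecture(enc_units = c(2L, 3L), dec_units = c(4L, 6L),
                          use_di = TRUE)
  model <- init_weights(arch, seed = 7)
  cfg <- ns$arch_cfg(arch)
  L <- 7L; T_len <- 5L
  X <- matrix(runif(L * 2), L, 2)
  target <- list(values = runif(T_len), classes = c(0L, 1L, 1L, 2L, 3L),
                 mask = c(1, 1, 1, 1, 0), true_len = 4L)
  s <- ns$make_model_sample(arch, X, target, c(0.3, 1))
  out <- ns$s2s_batch_cpp(model$params, cfg, list(s), 0.01, TRUE)
  loss_at <- function(params) {
    ns$s2s_forward_cpp(params, cfg, s$X, s$Yin, s$target_v, s$target_c,
                       s$mask, 0.01)$loss
  }
  eps <- 1e-6
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    for (i in sample(length(p), min(length(p), 3L))) {
      pp <- model$params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      lp <- loss_at(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      lm <- loss_at(pp)
      num <- (lp - lm) / (2 * eps)
      ana <- out$grads[[nm]][i]
      # floor guards near-zero gradients where finite-difference noise
      # dominates
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3)
    }
  }
})

test_that("initialization follows the uniform fan-in and orthogonality scheme", {
  arch <- bp_architecture()
  model <- init_weights(arch, seed = 2)
  p <- model$params
  # GRU input weights bounded by 1/sqrt(units)
  expect_lte(max(abs(p$e3f_Wz)), 1 / sqrt(100))
  expect_lte(max(abs(p$d3_Wh)), 1 / sqrt(200))
  # recurrent transition matrices orthogonal
  for (nm in c("e1f_Uz", "e3b_Uh", "d2_Ur")) {
    Q <- p[[nm]]
    expect_equal(crossprod(Q), diag(nrow(Q)), tolerance = 1e-10)
  }
  # head weights bounded by 1/sqrt(fan-in)
  expect_lte(max(abs(p$v_W)), 1 / sqrt(400))
  expect_lte(max(abs(p$c_W)), 1 / sqrt(200))
  # biases start at zero (so the bias-free gate equations hold at init)
  expect_true(all(p$e1f_bz == 0) && all(p$d3_bh == 0))
})

test_that("the full architecture is finite, compact and fast at init", {
  arch <- bp_architecture()
  model <- init_weights(arch, seed = 1)
  expect_lt(n_params(model), 2e6)
  X <- matrix(stats::runif(625 * 2), 625, 2)
  t0 <- proc.time()
  pred <- predict_sequence(model, X, c(0.5, 1), T_steps = 164L)
  elapsed <- (proc.time() - t0)[["elapsed"]]
  expect_lt(elapsed, 1)
  expect_length(pred$values, 164L)
  expect_true(all(is.finite(pred$values)))
  expect_true(all(is.finite(pred$probs)))
  expect_equal(rowSums(pred$probs), rep(1, 164L))
  expect_equal(rowSums(pred$attention), rep(1, 164L))
  expect_equal(dim(pred$attention), c(164L, 625L))
})

test_that("decoder contracts: DI handling, determinism, dense information flow", {
  arch <- tiny_arch(use_di = TRUE)
  model <- init_weights(arch, seed = 5)
  s <- tiny_sample(arch, seed = 2)
  p1 <- predict_sequence(model, s$window, s$x_di, 20L)
  p2 <- predict_sequence(model, s$window, s$x_di, 20L)
  expect_identical(p1, p2)
  expect_error(predict_sequence(model, s$window, NULL, 20L), "requires")

  no_di <- init_weights(tiny_arch(use_di = FALSE), seed = 5)
  expect_error(predict_sequence(no_di, s$window, c(0.4, 1), 20L), "no-DI")

  # dense connections: perturbing layer-1 weights must reach the output
  altered <- model
  altered$params$e1f_Wz <- altered$params$e1f_Wz + 0.5
  p3 <- predict_sequence(altered, s$window, s$x_di, 20L)
  expect_gt(max(abs(p3$values - p1$values)), 0)

  # teacher-forced pass differs from autoregressive unless predictions
  # are perfect
  tf <- forward_teacher(model, s$window, s$target, s$x_di)
  ar <- predict_sequence(model, s$window, s$x_di,
                         length(s$target$values))
  expect_gt(max(abs(tf$values - ar$values)), 1e-8)
})
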