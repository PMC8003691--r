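#' Define the seq2seq architecture
#'
#' The model is a dense-connected bidirectional GRU encoder, a GRU decoder
#' whose per-layer hidden states are initialized from the concatenated
#' forward/backward final states of the matching encoder layer, Luong
#' general attention over the encoder outputs, and two output heads: a
#' 1-unit value head (ELU) fed by the concatenated context vector and top
#' decoder state, and a 4-unit class head (ELU + softmax) fed by the top
#' decoder state. Dense connections mean every layer receives the module
#' input concatenated with all previous layer outputs.
#'
#' @param enc_units integer vector of encoder GRU units per layer and
#'   direction (default `c(4, 20, 100)`).
#' @param dec_units integer vector of decoder GRU units per layer; must be
#'   exactly twice `enc_units` so the decoder state can be initialized from
#'   the concatenated encoder final states (default `c(8, 40, 200)`).
#' @param use_di logical; concatenate the age/gender demographic vector to
#'   every decoder input step.
#' @param in_dim number of input channels (PPG and its derivative).
#' @param n_class number of cardiac-cycle classes (4, including the
#'   ended/padding class).
#' @return A `bp_architecture` object.
#' @export
bp_architecture <- function(enc_units = c(4L, 20L, 100L),
                            dec_units = 2L * enc_units,
                            use_di = TRUE, in_dim = 2L, n_class = 4L) {
  enc_units <- as.integer(enc_units)
  dec_units <- as.integer(dec_units)
  stopifnot(length(enc_units) >= 1L, length(enc_units) == length(dec_units))
  if (!all(dec_units == 2L * enc_units)) {
    stop("`dec_units` must equal 2 * `enc_units` (decoder states are ",
         "initialized from concatenated encoder final states)")
  }
  structure(
    list(enc_units = enc_units, dec_units = dec_units,
         use_di = isTRUE(use_di), in_dim = as.integer(in_dim),
         n_class = as.integer(n_class), out_dim = 1L + as.integer(n_class)),
    class = "bp_architecture"
  )
}

arch_cfg <- function(arch) {
  list(enc_units = arch$enc_units, dec_units = arch$dec_units,
       in_dim = arch$in_dim, di_dim = if (arch$use_di) 2L else 0L,
       out_dim = arch$out_dim, n_class = arch$n_class)
}

enc_input_sizes <- function(arch) {
  n <- length(arch$enc_units)
  arch$in_dim + c(0L, cumsum(2L * arch$enc_units))[seq_len(n)]
}

dec_input_sizes <- function(arch) {
  n <- length(arch$dec_units)
  base <- arch$out_dim + if (arch$use_di) 2L else 0L
  base + c(0L, cumsum(arch$dec_units))[seq_len(n)]
}

random_orthogonal <- function(m) {
  qrd <- qr(matrix(stats::rnorm(m * m), m, m))
  q <- qr.Q(qrd)
  q %*% diag(sign(diag(qr.R(qrd))), m, m)
}

gru_param_block <- function(m, n) {
  k <- 1 / sqrt(m)                       # U(-k, k), k = 1/sqrt(#GRU units)
  blk <- list(
    Wz = matrix(stats::runif(m * n, -k, k), m, n),
    Uz = random_orthogonal(m), bz = numeric(m),
    Wr = matrix(stats::runif(m * n, -k, k), m, n),
    Ur = random_orthogonal(m), br = numeric(m),
    Wh = matrix(stats::runif(m * n, -k, k), m, n),
    Uh = random_orthogonal(m), bh = numeric(m)
  )
  blk
}

#' Initialize model weights
#'
#' Head and attention weights are drawn from \eqn{U(-w, w)} with
#' \eqn{w = 1/\sqrt{\mathrm{fan~in}}}; GRU input weights from
#' \eqn{U(-k, k)} with \eqn{k = 1/\sqrt{\mathrm{units}}}; the recurrent
#' transition matrices (acting on the previous hidden state) are random
#' orthogonal; biases start at zero so a freshly initialized cell matches
#' the bias-free GRU equations exactly.
#'
#' @param arch a [bp_architecture()].
#' @param seed integer seed for reproducible draws.
#' @return A `bp_seq2seq` model object holding the parameter list, the
#'   architecture, and (once fitted) the target scaler and fixed length.
#' @export
init_weights <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "bp_architecture"))
  set.seed(seed)
  params <- list()
  enc_in <- enc_input_sizes(arch)
  for (l in seq_along(arch$enc_units)) {
    m <- arch$enc_units[l]
    for (dir in c("f", "b")) {
      blk <- gru_param_block(m, enc_in[l])
      names(blk) <- paste0("e", l, dir, "_", names(blk))
      params <- c(params, blk)
    }
  }
  dec_in <- dec_input_sizes(arch)
  for (l in seq_along(arch$dec_units)) {
    blk <- gru_param_block(arch$dec_units[l], dec_in[l])
    names(blk) <- paste0("d", l, "_", names(blk))
    params <- c(params, blk)
  }
  n_layers <- length(arch$enc_units)
  enc_out <- 2L * arch$enc_units[n_layers]
  dec_top <- arch$dec_units[n_layers]
  w_att <- 1 / sqrt(enc_out)
  params$att_W <- matrix(stats::runif(dec_top * enc_out, -w_att, w_att),
                         dec_top, enc_out)
  w_v <- 1 / sqrt(enc_out + dec_top)
  params$v_W <- matrix(stats::runif(enc_out + dec_top, -w_v, w_v),
                       1, enc_out + dec_top)
  params$v_b <- 0
  w_c <- 1 / sqrt(dec_top)
  params$c_W <- matrix(stats::runif(arch$n_class * dec_top, -w_c, w_c),
                       arch$n_class, dec_top)
  params$c_b <- numeric(arch$n_class)
  structure(
    list(params = params, arch = arch, fixed_length = NULL, scaler = NULL,
         history = NULL),
    class = "bp_seq2seq"
  )
}

#' @export
print.bp_seq2seq <- function(x, ...) {
  cat("<bp_seq2seq>\n")
  cat("  encoder Bi-GRU units:", paste(x$arch$enc_units, collapse = "/"), "\n")
  cat("  decoder GRU units:   ", paste(x$arch$dec_units, collapse = "/"), "\n")
  cat("  demographic input:   ", if (x$arch$use_di) "age + gender" else "none", "\n")
  cat("  parameters:          ", n_params(x), "\n")
  if (!is.null(x$fixed_length))
    cat("  fixed target length: ", x$fixed_length, "steps\n")
  invisible(x)
}

#' Number of trainable parameters
#' @param model a `bp_seq2seq` object.
#' @return Integer count of scalar parameters.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' Single GRU step
#'
#' Computes one update of the gated recurrent unit:
#' \deqn{z_t = \sigma(W_z x_t + U_z h_{t-1} + b_z)}
#' \deqn{r_t = \sigma(W_r x_t + U_r h_{t-1} + b_r)}
#' \deqn{\tilde h_t = \tanh(W_h x_t + U_h (r_t \odot h_{t-1}) + b_h)}
#' \deqn{h_t = (1 - z_t) \odot h_{t-1} + z_t \odot \tilde h_t}
#'
#' @param block named list with matrices `Wz, Uz, Wr, Ur, Wh, Uh` and bias
#'   vectors `bz, br, bh` (biases default to zero if absent).
#' @param h_prev previous hidden state.
#' @param x input vector.
#' @return The new hidden state.
#' @export
gru_step <- function(block, h_prev, x) {
  m <- nrow(block$Uz)
  zb <- function(nm) if (!is.null(block[[nm]])) block[[nm]] else numeric(m)
  as.numeric(gru_step_cpp(block$Wz, block$Uz, zb("bz"),
                          block$Wr, block$Ur, zb("br"),
                          block$Wh, block$Uh, zb("bh"),
                          h_prev, x))
}

#' Luong general attention
#'
#' Scores each encoder output \eqn{\bar h_s} against the decoder state via
#' \eqn{\mathrm{score}(h_t, \bar h_s) = h_t^\top W \bar h_s}, normalizes the
#' scores with a softmax into weights \eqn{a}, and returns the context
#' vector \eqn{c = \sum_s a_s \bar h_s}.
#'
#' @param W score matrix (decoder width x encoder output width).
#' @param h_t decoder state vector.
#' @param h_enc matrix of encoder outputs, one column per source step.
#' @return list with `weights` (sums to 1) and `context`.
#' @export
attention <- function(W, h_t, h_enc) {
  s <- drop(crossprod(h_enc, crossprod(W, h_t)))
  s <- s - max(s)
  a <- exp(s) / sum(exp(s))
  list(weights = a, context = drop(h_enc %*% a))
}

#' Autoregressive sequence prediction
#'
#' Runs the encoder over a prepared input window, then exactly `T`
#' decoder steps feeding each prediction back as the next input (the first
#' input is the all-ones start token). Returns the value sequence, the
#' per-step class probabilities, and the full attention map.
#'
#' @param model a `bp_seq2seq` object.
#' @param X input window, `L x 2` matrix (scaled PPG, scaled PPG derivative).
#' @param x_di demographic vector of length 2 (scaled age, gender indicator)
#'   or `NULL` when the architecture takes none.
#' @param T_steps number of decoder steps; defaults to the model's fitted
#'   fixed length.
#' @return list with `values` (length `T_steps`), `probs`
#'   (`T_steps x 4`), `classes` (argmax codes 0-3) and `attention`
#'   (`T_steps x L`, rows sum to 1).
#' @export
predict_sequence <- function(model, X, x_di = NULL, T_steps = NULL) {
  stopifnot(inherits(model, "bp_seq2seq"))
  if (is.null(T_steps)) T_steps <- model$fixed_length
  if (is.null(T_steps)) stop("T_steps not given and model has no fixed length")
  if (model$arch$use_di && is.null(x_di))
    stop("this architecture requires the demographic vector `x_di`")
  if (!model$arch$use_di && !is.null(x_di))
    stop("demographic vector supplied to a no-DI architecture")
  X <- as.matrix(X)
  stopifnot(ncol(X) == model$arch$in_dim)
  out <- s2s_predict_cpp(model$params, arch_cfg(model$arch), t(X),
                         if (is.null(x_di)) numeric(0) else as.numeric(x_di),
                         as.integer(T_steps))
  list(values = as.numeric(out$values), probs = out$probs,
       classes = max.col(out$probs) - 1L, attention = out$attention)
}

#' Teacher-forced forward pass (loss components for one sample)
#'
#' Used for loss monitoring and testing: the decoder consumes the
#' ground-truth previous outputs instead of its own predictions.
#'
#' @inheritParams predict_sequence
#' @param target a homogenized target as returned by [homogenize_target()].
#' @param lambda class-loss weight.
#' @return list with `loss`, `mse`, `ce`, `values`, `probs`.
#' @export
forward_teacher <- function(model, X, target, x_di = NULL, lambda = 0.01) {
  s <- make_model_sample(model$arch, as.matrix(X), target, x_di)
  s2s_forward_cpp(model$params, arch_cfg(model$arch), s$X, s$Yin,
                  s$target_v, s$target_c, s$mask, lambda)
}

# Build the C++-facing sample: transposed input, teacher-forced decoder
# inputs (start token = ones), 0-based target classes, mask.
make_model_sample <- function(arch, X, target, x_di = NULL) {
  T_len <- length(target$values)
  oh <- matrix(0, arch$n_class, T_len)
  oh[cbind(target$classes + 1L, seq_len(T_len))] <- 1
  y <- rbind(target$values, oh)                   # out_dim x T
  yin <- cbind(rep(1, arch$out_dim), y[, -T_len, drop = FALSE])
  if (arch$use_di) {
    if (is.null(x_di)) stop("missing demographics for a DI architecture")
    yin <- rbind(yin, matrix(rep(as.numeric(x_di), T_len), nrow = 2))
  }
  list(X = t(X), Yin = yin,
       target_v = as.numeric(target$values),
       target_c = as.integer(target$classes),
       mask = as.numeric(target$mask))
}
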