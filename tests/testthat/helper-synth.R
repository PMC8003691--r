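# Shared fixture builders (everything generated in code).

tiny_arch <- function(use_di = TRUE) {
  bp_architecture(enc_units = c(2L, 4L), dec_units = c(4L, 8L),
                  use_di = use_di)
}

# A small teacher-forcible sample for the tiny architecture: a smooth
# pulse-like target with plausible class structure.
tiny_sample <- function(arch, L = 60L, T_len = 30L, seed = 1L) {
  set.seed(seed)
  tt <- seq(0, 1, length.out = L)
  X <- cbind(ppg = (sin(2 * pi * 2 * tt) + 1) / 2,
             dppg = (cos(2 * pi * 2 * tt) + 1) / 2)
  X <- X + matrix(runif(L * 2, 0, 0.05), L, 2)
  X <- apply(X, 2, function(c) (c - min(c)) / (max(c) - min(c)))
  true_len <- T_len - 8L
  u <- seq(0, 1, length.out = true_len)
  v <- 0.2 + 0.6 * exp(-((u - 0.25) / 0.2)^2) + 0.15 * exp(-((u - 0.6) / 0.15)^2)
  sp <- which.max(v)
  dn <- sp + which.min(v[(sp + 1):(true_len - 2)])
  cls <- integer(true_len)
  cls[(sp + 1):dn] <- 1L
  cls[(dn + 1):true_len] <- 2L
  target <- homogenize_target(list(values = v, classes = cls), T_len,
                              pad_steps = 8L)
  list(window = X, target = target,
       x_di = if (arch$use_di) c(0.4, 1) else NULL)
}

# Zero-noise, zero-jitter segment with exact ground truth.
clean_segment <- function(seed = 11L, subject_seed = 3L, fs = 125) {
  subject <- make_subject(subject_seed)
  sr <- synth_record(subject, duration = 16, noise_sd = 0, seed = seed,
                     period_jitter = 0, amp_jitter = 0)
  n <- 15L * fs
  list(subject = subject,
       abp = sr$record$abp[seq_len(n)], ppg = sr$record$ppg[seq_len(n)],
       truth = sr$truth[sr$truth$onset_idx + 2 <= n, ])
}

# Direct construction of a pulse-set tibble (for threshold tests).
fake_pulses <- function(n = 15L, duration = 0.8, pp = 40, skew = 0.5,
                        dbp = 70) {
  tibble::tibble(
    onset_idx = seq_len(n), duration = duration,
    dbp = dbp, sbp = dbp + pp, skewness = skew,
    samples = replicate(n, numeric(3), simplify = FALSE)
  )
}

# A synthetic morphology object with chosen summary properties.
fake_morphology <- function(max_val = 120, duration = 0.8, skew = 0.5,
                            subject_id = "S1", segment_id = "S1-a") {
  n <- round(duration * 125)
  v <- seq(70, max_val, length.out = n)
  structure(list(values = v, classes = assign_classes(v, 10L, 2L * 10L),
                 mu = v, sigma = rep(0, n), sp_idx = 10L, dn_idx = 20L,
                 duration = duration, fs = 125, skewness = skew,
                 subject_id = subject_id, segment_id = segment_id),
            class = "bp_morphology")
}
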