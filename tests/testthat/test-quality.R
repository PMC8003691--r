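test_that("flat detection finds constant runs and ignores ramps", {
  x <- c(sin(1:100 / 5), rep(0.4, 30), sin(101:200 / 5))
  r <- detect_flat(x, min_len = 0.2, tol = 0, fs = 125)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start_idx, 101L)
  expect_equal(r$end_idx, 130L)
  expect_equal(nrow(detect_flat(seq(0, 1, length.out = 500))), 0L)
  # constant series sits at its own global extreme -> saturation's job,
  # but null samples are always flagged
  withNA <- c(1:50, rep(NA, 10), 51:100)
  rn <- detect_flat(withNA)
  expect_true("null" %in% rn$type)
})

test_that("flat regions locate injected plateaus within one sample", {
  subject <- make_subject(4)
  art <- artifact_spec("flatline", start = 6, duration = 0.5)
  sr <- synth_record(subject, duration = 16, artifacts = list(art), seed = 8)
  r <- detect_flat(sr$record$abp)
  expect_gte(nrow(r), 1L)
  expect_lte(abs(r$start_idx[1] - (6 * 125 + 1)), 1L)
  expect_lte(abs(r$end_idx[1] - 6.5 * 125), 1L)
})

test_that("saturation detection flags clipping at either extreme only", {
  tt <- seq(0, 4, by = 1 / 125)
  clean <- sin(2 * pi * tt)
  expect_equal(nrow(detect_saturation(clean)), 0L)
  clipped_hi <- pmin(clean, 0.8)
  r <- detect_saturation(clipped_hi)
  expect_true(all(r$type == "saturation_high"))
  expect_gt(nrow(r), 0L)
  clipped_lo <- pmax(clean, -0.8)
  expect_true(all(detect_saturation(clipped_lo)$type == "saturation_low"))
})

test_that("flat and saturation screens report disjoint regions", {
  x <- c(sin(1:200 / 10), rep(0.2, 40), pmin(sin(201:400 / 10), 0.9))
  x[100:140] <- 0.95                     # plateau at the global max
  x <- pmin(x, 0.95)
  fl <- detect_flat(x)
  sat <- detect_saturation(x)
  flat_pts <- unlist(purrr::map2(fl$start_idx, fl$end_idx, `:`))
  sat_pts <- unlist(purrr::map2(sat$start_idx, sat$end_idx, `:`))
  expect_length(intersect(flat_pts, sat_pts), 0L)
  expect_gt(length(sat_pts), 0L)
  expect_gt(length(flat_pts), 0L)
})

test_that("PPG band-pass output is MinMax-normalized with DC removed", {
  tt <- seq(0, 15, by = 1 / 125)[-1]
  x <- 3 + sin(2 * pi * 2 * tt)
  y <- filter_ppg_sq(x)
  expect_equal(min(y), 0)
  expect_equal(max(y), 1)
  # 10 Hz attenuated relative to 2 Hz (band is [0.5, 8] Hz); amplitude is
  # read off the middle of the segment, away from filter edges
  amp <- function(f) {
    s <- sin(2 * pi * f * tt)
    bf <- signal::butter(4, c(0.5, 8) / 62.5, type = "pass")
    y <- signal::filtfilt(bf, s)
    diff(range(y[500:1300]))
  }
  expect_lt(amp(10), 0.7 * amp(2))
  expect_error(filter_ppg_sq(rep(1, 1875)), "degenerate")
})

test_that("moment skewness matches the direct formula and its symmetries", {
  x <- c(0, 0, 0, 1)
  m <- mean(x)
  direct <- mean((x - m)^3) / mean((x - m)^2)^1.5
  expect_equal(moment_skewness(x), direct)
  expect_equal(direct, 2 / sqrt(3), tolerance = 1e-12)  # hand-computed
  sym <- c(0, 1, 2, 3, 2, 1)          # symmetric sample distribution
  expect_equal(moment_skewness(sym), 0)
  y <- stats::runif(50)
  expect_equal(moment_skewness(-y), -moment_skewness(y))
  expect_error(moment_skewness(rep(2, 10)), "zero variance")
  expect_error(moment_skewness(c(1, 2)), "at least 3")
})

test_that("pulse delineation recovers clean synthetic onsets within 3 samples", {
  seg <- clean_segment(seed = 13, subject_seed = 17)
  pulses <- delineate_pulses(seg$abp)
  truth <- seg$truth$onset_idx
  expect_equal(nrow(pulses), length(truth) - 1L)
  err <- purrr::map_dbl(pulses$onset_idx, ~ min(abs(truth - .x)))
  expect_true(all(err <= 3))
  # flatline input: marker failure
  expect_equal(nrow(delineate_pulses(rep(1, 1875))), 0L)
  # two concatenated identical beats -> two onsets one period apart
  tpl <- beat_template(0.8, 70, 115)
  b <- synth_abp_beat(tpl)$samples
  two <- delineate_pulses(c(b, b, b))
  expect_gte(nrow(two), 1L)
  expect_equal(two$duration[1], 0.8, tolerance = 3 / 125)
})

test_that("pulse acceptance enforces every printed threshold", {
  good <- fake_pulses(15, duration = 0.8, pp = 40, skew = 0.5)
  expect_true(abp_sq(good)$accepted)

  expect_equal(abp_sq(fake_pulses(9))$failed_checks, "pulse_count")
  expect_equal(abp_sq(fake_pulses(31))$failed_checks, "pulse_count")
  expect_true(abp_sq(fake_pulses(10))$accepted)        # inclusive endpoints
  expect_true(abp_sq(fake_pulses(30))$accepted)

  expect_equal(abp_sq(fake_pulses(15, duration = 0.4))$failed_checks,
               "pulse_duration")
  expect_equal(abp_sq(fake_pulses(15, duration = 1.6))$failed_checks,
               "pulse_duration")
  expect_true(abp_sq(fake_pulses(15, duration = 0.5))$accepted)
  expect_true(abp_sq(fake_pulses(15, duration = 1.5))$accepted)

  expect_equal(abp_sq(fake_pulses(15, pp = 5))$failed_checks,
               "pulse_pressure")
  expect_equal(abp_sq(fake_pulses(15, pp = 10))$failed_checks,
               "pulse_pressure")                       # strictly greater

  expect_equal(abp_sq(fake_pulses(15, skew = -0.1))$failed_checks, "skewness")
  expect_equal(abp_sq(fake_pulses(15, skew = 0))$failed_checks, "skewness")

  expect_equal(abp_sq(good[0, ])$failed_checks, "marker")
})

test_that("acceptance is monotone in pulse removal", {
  set.seed(1)
  for (i in 1:20) {
    n <- sample(11:30, 1)
    p <- fake_pulses(n, duration = runif(1, 0.5, 1.5), pp = runif(1, 15, 60),
                     skew = runif(1, 0.1, 1))
    # corrupt one pulse; removing it must not break an accepted set
    bad <- p
    bad$duration[1] <- 2
    if (abp_sq(p)$accepted) expect_true(abp_sq(p[-1, ])$accepted || n - 1 < 10)
    expect_false(abp_sq(bad)$accepted)
  }
})

test_that("clean synthetic segments pass the whole quality chain", {
  for (s in c(31, 32, 33)) {
    seg <- clean_segment(seed = s, subject_seed = s + 100)
    chk <- check_segment(seg$abp, seg$ppg)
    expect_true(chk$verdict$accepted)
  }
})

test_that("each artifact is caught by its own screen", {
  subject <- make_subject(14)
  flat <- synth_record(subject, 16, artifacts = list(
    artifact_spec("flatline", 5, 1)), seed = 6)
  chk <- check_segment(flat$record$abp[1:1875], flat$record$ppg[1:1875])
  expect_false(chk$verdict$accepted)
  expect_true("flat" %in% chk$verdict$failed_checks)

  sat <- synth_record(subject, 16, artifacts = list(
    artifact_spec("saturation_high", 5, 0.5)), seed = 6)
  chk2 <- check_segment(sat$record$abp[1:1875], sat$record$ppg[1:1875])
  expect_false(chk2$verdict$accepted)
  expect_true("peak" %in% chk2$verdict$failed_checks)
})
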