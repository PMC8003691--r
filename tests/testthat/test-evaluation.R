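test_that("marker extraction follows the class-sequence rules", {
  # all in-pulse: DBP = mean(first, last), SBP = max
  m <- extract_markers(c(80, 120, 100, 90, 82), c(0L, 0L, 1L, 1L, 2L))
  expect_equal(m$dbp, 81)
  expect_equal(m$sbp, 120)
  expect_false(m$complete)

  # classes (0-based steps): duration = first ended index / fs
  m2 <- extract_markers(c(80, 120, 100, 90, 82, 80),
                        c(0L, 0L, 1L, 1L, 2L, 3L), fs = 125)
  expect_equal(m2$pulse_duration, 5 / 125 * 1000)
  expect_equal(m2$dnto, 3 / 125 * 1000)              # last class-1 at step 3
  expect_equal(m2$dn_value, 90)
  expect_lt(m2$dnto, m2$pulse_duration)
  expect_true(m2$complete && m2$dn_found)

  # no peak-to-notch class: DN undefined
  m3 <- extract_markers(c(80, 120, 90, 80), c(0L, 0L, 2L, 3L))
  expect_false(m3$dn_found)
  expect_true(is.na(m3$dnto))

  # degenerate: the prediction opens with the ended class
  m4 <- extract_markers(c(80, 85, 90), c(3L, 3L, 3L))
  expect_true(is.finite(m4$dbp) && is.finite(m4$sbp))
})

test_that("scalar metrics match hand-computed oracles and ideals", {
  z <- c(1, 2, 3); zh <- c(2, 2, 2)
  r <- metrics(z, zh)
  expect_equal(r$mae, 2 / 3)
  expect_equal(r$rmse, sqrt(2 / 3))
  expect_equal(r$r2, 0)

  ideal <- metrics(c(3, 1, 4, 1, 5), c(3, 1, 4, 1, 5))
  expect_equal(ideal$rmse, 0)
  expect_equal(ideal$mae, 0)
  expect_equal(ideal$r2, 1)
  expect_equal(ideal$r, 1)

  anti <- metrics(c(-1, 0, 1), c(1, 0, -1))
  expect_equal(anti$r, -1)

  # different durations: truncate to the shorter sequence
  tr <- metrics(c(1, 2, 3, 4, 5), c(1.1, 2.2, 2.9))
  expect_equal(tr$n, 3L)
  expect_error(metrics(rep(2, 5), 1:5), "zero variance")
})

test_that("rmse dominates mae on random error vectors", {
  set.seed(12)
  for (i in 1:50) {
    z <- rnorm(sample(3:40, 1))
    zh <- z + rnorm(length(z))
    r <- metrics(z, zh)
    expect_gte(r$rmse, r$mae)
    expect_gte(r$r, -1); expect_lte(r$r, 1)
  }
})

test_that("BHS grading reproduces the protocol's grade assignments", {
  expect_equal(bhs_grade(c(60, 85, 95), percentages = TRUE)$grade, "A")
  expect_equal(bhs_grade(c(41.8, 76.6, 92.9), percentages = TRUE)$grade, "C")
  expect_equal(bhs_grade(c(56.6, 86.0, 95.5), percentages = TRUE)$grade, "B")
  expect_equal(bhs_grade(c(39, 60, 80), percentages = TRUE)$grade, "fail")
  # from raw errors: all below 5 mmHg -> grade A
  g <- bhs_grade(runif(100, 0, 4.9))
  expect_equal(g$grade, "A")
  expect_equal(unname(g$cumulative_pct), c(100, 100, 100))
  expect_true(all(diff(g$cumulative_pct) >= 0))
})

test_that("BHS grading is monotone under error shrinkage", {
  set.seed(13)
  order_of <- c(fail = 0, C = 1, B = 2, A = 3)
  for (i in 1:20) {
    e <- runif(200, 0, 25)
    shrunk <- e * runif(1, 0.2, 0.9)
    expect_gte(order_of[[bhs_grade(shrunk)$grade]],
               order_of[[bhs_grade(e)$grade]])
  }
})

test_that("Bland-Altman limits match the hand computation", {
  ba <- bland_altman(c(10, 10), c(11, 9))            # d = (1, -1)
  expect_equal(ba$mean_diff, 0)
  expect_equal(unname(ba$limits), c(-1.96 * sqrt(2), 1.96 * sqrt(2)))
  same <- bland_altman(1:5, 1:5)
  expect_equal(same$mean_diff, 0)
  expect_equal(unname(same$limits), c(0, 0))
  expect_true(all(abs(ba$limits - ba$mean_diff) ==
                  max(abs(ba$limits - ba$mean_diff))))
})

test_that("ground truth passed as its own prediction is graded perfectly", {
  seg <- clean_segment(seed = 41, subject_seed = 9)
  chk <- check_segment(seg$abp, seg$ppg)
  morph <- compute_morphology(chk$abp_pulses, subject_id = "s", segment_id = "g")
  h <- homogenize_target(morph, length(morph$values) + 15L)
  mk <- extract_markers(
    c(h$values[seq_len(h$true_len)], h$values[1]),
    c(h$classes[seq_len(h$true_len)], 3L))
  expect_equal(mk$sbp, max(morph$values))
  e <- metrics(rep(c(mk$dbp, mk$sbp), 3) + rnorm(6, 0, 1e-12),
               rep(c(mk$dbp, mk$sbp), 3))
  expect_equal(e$rmse, 0, tolerance = 1e-9)
  expect_equal(bhs_grade(rep(0, 10))$grade, "A")
})

test_that("fold aggregation reports mean and sd per marker and metric", {
  fake_eval <- function(shift) {
    structure(list(
      markers = tibble::tibble(),
      waveform = tibble::tibble(r = 0.9 + shift, rmse = 5 + shift,
                                mae = 4 + shift),
      summary = tibble::tibble(
        marker = c("DBP", "waveform"),
        rmse = c(8 + shift, 5 + shift), mae = c(6 + shift, 4 + shift),
        std = c(8, NA), r2 = c(0.2, NA), r = c(0.5, 0.9 + shift),
        n = c(10L, 10L))),
      class = "bp_evaluation")
  }
  rep_tbl <- evaluate_scenario(list(fake_eval(0), fake_eval(0.1)), "Mixno")
  row <- rep_tbl[rep_tbl$marker == "DBP" & rep_tbl$metric == "mae", ]
  expect_equal(row$mean, 6.05)
  expect_equal(row$sd, stats::sd(c(6, 6.1)))
  expect_true(all(c("scenario", "marker", "metric") %in% names(rep_tbl)))
})
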