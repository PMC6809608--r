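test_that("average trend regression nails an exact line", {
  rate <- 512
  time <- seq(-2, 0.2, by = 1 / rate)[-1]
  x <- -2 * time  # slope -2 uV/s
  # suppress lm's "essentially perfect fit" note on the exact line
  res <- suppressWarnings(
    trend_slope_average(x, time, rate, lowpass_hz = NULL))
  expect_equal(res$slope, -2, tolerance = 1e-6)
  expect_error(trend_slope_average(x, time, rate, window = c(-0.1, 0),
                                   lowpass_hz = NULL),
               "fewer than 20")
})

test_that("slope significance on white noise is calibrated", {
  rate <- 512
  time <- seq(-2, 0.2, by = 1 / rate)[-1]
  set.seed(61)
  hits <- replicate(500, {
    x <- rnorm(length(time))
    trend_slope_average(x, time, rate, lowpass_hz = NULL)$p < 0.05
  })
  # false-positive rate ~ alpha; binomial SE ~ 0.01, allow 3 SE
  expect_lt(abs(mean(hits) - 0.05), 0.03)
})

test_that("robust and ordinary slopes coincide on clean lines but robust
          resists contamination", {
  rate <- 512
  time <- seq(-2, 0.2, by = 1 / rate)[-1]
  true_slope <- -1.5
  clean <- matrix(rep(true_slope * time, 12), nrow = 12, byrow = TRUE)
  s_clean <- trend_slope_trials(clean, time, rate, lowpass_hz = NULL)
  expect_equal(as.vector(s_clean), rep(true_slope, 12), tolerance = 1e-6)

  # contaminate 10% of samples in some trials with huge spikes
  set.seed(62)
  noisy <- clean + matrix(rnorm(length(clean), 0, 0.3), nrow = 12)
  corrupt <- noisy
  sel <- which(time >= -1)
  for (i in 1:12) {
    bad <- sample(sel, round(length(sel) * 0.1))
    corrupt[i, bad] <- corrupt[i, bad] + 200
  }
  s_rob <- trend_slope_trials(corrupt, time, rate, lowpass_hz = NULL)
  s_ols <- apply(corrupt, 1, function(x) {
    d <- raceRP:::decimate_window(x, time, rate, c(-1, 0), NULL, 10L)
    unname(coef(lm(d$x ~ d$t))[2])
  })
  dev_rob <- mean(abs(s_rob - true_slope))
  dev_ols <- mean(abs(s_ols - true_slope))
  s_noisy <- trend_slope_trials(noisy, time, rate, lowpass_hz = NULL)
  dev_clean <- mean(abs(s_noisy - true_slope))
  expect_lt(dev_rob, 3 * dev_clean)
  expect_gt(dev_ols, 10 * dev_clean)
})

test_that("zero-slope trials yield a calibrated subject test", {
  rate <- 512
  time <- seq(-2, 0.2, by = 1 / rate)[-1]
  set.seed(63)
  sig <- replicate(200, {
    trials <- matrix(rnorm(20 * length(time)), nrow = 20)
    s <- trend_slope_trials(trials, time, rate, lowpass_hz = NULL)
    subject_slope_test(s)$p < 0.05
  })
  expect_lt(abs(mean(sig) - 0.05), 0.05)
})

test_that("cluster test finds nothing in zeros and everything in a strong
          offset", {
  time <- seq(-1, 0.2, by = 1 / 512)
  zeros <- matrix(0, 10, length(time))
  res <- cluster_permutation_vs_zero(zeros, time, n_permutations = 200,
                                     seed = 1)
  expect_identical(nrow(res$clusters), 0L)

  # constant -3 uV over a 1 s span across subjects, low noise
  set.seed(64)
  waves <- matrix(rnorm(18 * length(time), 0, 0.5), 18)
  span <- time >= -1 & time < 0
  waves[, span] <- waves[, span] - 3
  res2 <- cluster_permutation_vs_zero(waves, time, n_permutations = 500,
                                      seed = 2)
  sig <- res2$clusters[res2$clusters$significant &
                         res2$clusters$mass < 0, ]
  expect_gte(nrow(sig), 1L)
  cover <- max(sig$end_s) - min(sig$start_s)
  expect_gte(cover, 0.9 * 1.0)
  expect_true(all(res2$clusters$p >= 1 / 501))
})

test_that("cluster detection is equivariant under a global sign flip", {
  time <- seq(-1, 0, by = 1 / 256)
  set.seed(65)
  waves <- matrix(rnorm(12 * length(time), 0, 1), 12)
  waves[, 100:150] <- waves[, 100:150] + 2
  a <- cluster_permutation_vs_zero(waves, time, n_permutations = 300,
                                   seed = 3)
  b <- cluster_permutation_vs_zero(-waves, time, n_permutations = 300,
                                   seed = 3)
  expect_equal(a$t, -b$t)
  expect_equal(a$clusters$mass, -b$clusters$mass)
  expect_equal(a$clusters$p, b$clusters$p)
})

test_that("cluster test input contracts hold", {
  time <- seq(0, 1, by = 0.01)
  waves <- matrix(rnorm(5 * length(time)), 5)
  expect_error(cluster_permutation_vs_zero(waves, time), "6 subjects")
  waves2 <- matrix(rnorm(8 * length(time)), 8)
  expect_error(cluster_permutation_vs_zero(waves2, time,
                                           n_permutations = 50),
               "100 permutations")
})

test_that("saccade detection: flat EOG, refractory merging, channel
          order", {
  rate <- 512; n <- 30000
  flat <- matrix(0, 4, n)
  expect_length(detect_saccades(flat, rate), 0L)

  # an in-band background oscillation pins the robust scale without the
  # run-length flakiness of Gaussian noise
  eog <- matrix(rep(sin(2 * pi * 40 * seq_len(n) / rate), 4), 4,
                byrow = TRUE)
  burst <- raceRP:::saccade_burst(rate, amp = 60)
  put_burst <- function(m, at) {
    idx <- at:(at + length(burst) - 1L)
    for (ch in 1:4) m[ch, idx] <- m[ch, idx] + burst
    m
  }
  # two bursts 30 ms apart merge into one saccade (closer than the 50 ms
  # refractory gap, given the detection filter's time support)
  e1 <- put_burst(put_burst(eog, 10000L), 10000L + round(0.03 * rate))
  on1 <- detect_saccades(e1, rate)
  expect_identical(sum(on1 > 9500 & on1 < 10600), 1L)
  # 120 ms apart: two distinct saccades
  e2 <- put_burst(put_burst(eog, 20000L), 20000L + round(0.12 * rate))
  on2 <- detect_saccades(e2, rate)
  expect_identical(sum(on2 > 19500 & on2 < 20700), 2L)
  # detection is invariant to channel order
  expect_identical(detect_saccades(e2[4:1, ], rate), on2)
})

test_that("per-trial saccade counts use the pre-response window", {
  rate <- 512; n <- 30000
  set.seed(67)
  data <- rbind(matrix(rnorm(3 * n, 0, 5), 3),
                matrix(rep(sin(2 * pi * 40 * seq_len(n) / rate), 4), 4,
                       byrow = TRUE))
  labels <- c("Cz", "C3", "C4", paste0("EOG", 1:4))
  burst <- raceRP:::saccade_burst(rate, amp = 60)
  resp <- c(10000L, 20000L)
  # one saccade inside trial 1's 500 ms window (256 samples), one before it
  for (at in c(resp[1] - 100L, resp[1] - 400L)) {
    idx <- at:(at + length(burst) - 1L)
    for (ch in 4:7) data[ch, idx] <- data[ch, idx] + burst
  }
  events <- data.frame(sample = c(resp[1] - 512L, resp[1],
                                  resp[2] - 512L, resp[2]),
                       kind = c("stimulus", "response-left",
                                "stimulus", "response-right"),
                       trial = c(1L, 1L, 2L, 2L))
  rec <- eeg_recording(data, rate, labels, events)
  sc <- saccade_count(rec)
  # only the burst 100 samples before the response falls in the window
  expect_identical(sc$saccades, c(1L, 0L))
  expect_identical(sc$trial, 1:2)
})

test_that("consistency grade follows its definition and edge cases", {
  expect_identical(consistency_grade(c(5, 6, 7), c(1, 2, 3)), 1)
  expect_identical(consistency_grade(c(1, 2), c(5, 6)), 0)
  set.seed(68)
  hi <- rep(6, 4000); lo <- rep(2, 4000)
  pick_hi <- runif(4000) < 0.5
  grade <- consistency_grade(ifelse(pick_hi, hi, lo),
                             ifelse(pick_hi, lo, hi))
  expect_lt(abs(grade - 0.5), 3 * sqrt(0.25 / 4000))
  expect_warning(g <- consistency_grade(c(5, 4), c(5, 2)), "tied")
  expect_identical(g, 1)
  expect_error(suppressWarnings(consistency_grade(5, 5)), "no gradable")
})
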