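test_that("zero-drive and noiseless-ramp accumulators behave exactly", {
  # no drive, no noise: stays at 0 forever
  p0 <- accumulator_params(0, 0.5, 0, threshold = 0.3, t_max = 2)
  r0 <- simulate_accumulator(p0)
  expect_true(all(r0$trace == 0))
  expect_true(is.na(r0$crossing))

  # pure linear ramp: I * dt per step, crossing at theta / (I * dt)
  p1 <- accumulator_params(0.3, 0, 0, threshold = 0.3, dt = 0.001)
  r1 <- simulate_accumulator(p1)
  expect_identical(r1$crossing, 1000L)
  expect_equal(r1$rt, 1.0)
  expect_equal(r1$trace, 0.0003 * seq_len(1000), tolerance = 1e-12)
})

test_that("noiseless crossing matches the closed-form first-passage time", {
  # t* = -log(1 - theta k / I) / k, valid when theta k / I < 1
  grid <- expand.grid(I = c(0.15, 0.23, 0.3, 0.4),
                      k = c(0.1, 0.3, 0.52),
                      theta = c(0.2, 0.3))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    t_star <- noiseless_crossing_time(g$I, g$k, g$theta)
    p <- accumulator_params(g$I, g$k, 0, threshold = g$theta)
    r <- simulate_accumulator(p)
    if (is.finite(t_star)) {
      expect_lt(abs(r$rt - t_star), 2 * p$dt)
    } else {
      expect_true(is.na(r$crossing))
    }
  }
  # asymptote below threshold: no crossing ever
  expect_identical(noiseless_crossing_time(0.05, 0.5, 0.3), Inf)
})

test_that("unbounded accumulators never cross and run to t_max", {
  p <- accumulator_params(0.3, 0.2, 0.1, threshold = Inf, t_max = 1)
  r <- simulate_accumulator(p, seed = 1)
  expect_true(is.na(r$crossing))
  expect_length(r$trace, 1000L)
})

test_that("mean noisy trace converges to the noiseless solution", {
  # law of large numbers for the Euler-Maruyama integrator (no threshold)
  p <- accumulator_params(0.25, 0.4, 0.2, threshold = Inf, t_max = 1)
  set.seed(42)
  acc <- numeric(1000L)
  n <- 5000L
  for (i in seq_len(n)) acc <- acc + simulate_accumulator(p)$trace
  m <- acc / n
  t <- seq_len(1000L) * p$dt
  noiseless <- (p$drift / p$leak) * (1 - exp(-p$leak * t))
  # pointwise SE <= c * sqrt(t) / sqrt(n) ~ 0.003; allow 5 SE
  expect_lt(max(abs(m - noiseless)), 0.015)
})

test_that("race between a ramp and a flat accumulator is deterministic", {
  ramp <- accumulator_params(0.3, 0, 0, threshold = 0.3)
  flat <- accumulator_params(0, 0, 0, threshold = 0.3)
  r <- run_race(ramp, flat)
  expect_identical(r$winner, "congruent")
  expect_equal(r$rt, 1.0)
  expect_length(r$traces$incongruent, r$crossing_index)
})

test_that("equal racers win equally often; swapping parameters swaps wins", {
  pa <- accumulator_params(0.24, 0.53, 0.22, threshold = 0.3)
  cond <- condition_params("arbitrary", "easy", pa, pa)
  s <- simulate_condition(cond, 10000, seed = 7)
  # fair race: win fraction 0.5 within a 99% binomial interval
  expect_lt(abs(s$consistency - 0.5), 2.576 * sqrt(0.25 / 10000))

  a <- accumulator_params(0.24, 0.53, 0.22, threshold = 0.3)
  b <- accumulator_params(0.18, 0.53, 0.22, threshold = 0.3)
  s_ab <- simulate_condition(condition_params("arbitrary", "easy", a, b),
                             5000, seed = 11)
  s_ba <- simulate_condition(condition_params("arbitrary", "easy", b, a),
                             5000, seed = 12)
  se <- sqrt(0.25 / 5000)
  expect_lt(abs(s_ab$consistency - (1 - s_ba$consistency)), 4 * se)
})

test_that("rt distribution is invariant across seed blocks", {
  cond <- fit_conditions()[["arbitrary-easy"]]
  s1 <- simulate_condition(cond, 800, seed = 101)
  s2 <- simulate_condition(cond, 800, seed = 202)
  ks <- suppressWarnings(stats::ks.test(s1$rt, s2$rt))
  expect_gt(ks$p.value, 0.01)
})

test_that("deliberate trials decide in Region X while the SMA integrates", {
  # noiseless deliberate trial: Region X wins deterministically and the
  # SMA trace equals the leaky-integrator solution at drift / 1.45
  cg <- accumulator_params(0.23, 0.52, 0, threshold = 0.3)
  ig <- accumulator_params(0.06, 0.52, 0, threshold = 0.3)
  cond <- condition_params("deliberate", "easy", cg, ig)
  tr <- run_trial(cond)
  expect_identical(tr$winner, "congruent")
  expect_equal(tr$rt, tr$crossing_index * 0.001)
  t <- seq_len(tr$crossing_index) * 0.001
  expected_sma <- (0.23 / 1.45 / 0.52) * (1 - exp(-0.52 * t))
  expect_equal(tr$sma_traces$congruent, expected_sma, tolerance = 1e-3)
  # all four traces truncated at the deciding crossing
  lens <- c(lengths(tr$deciding_traces), lengths(tr$sma_traces))
  expect_true(all(lens == tr$crossing_index))
})

test_that("arbitrary trials decide in the SMA race itself", {
  cond <- fit_conditions()[["arbitrary-easy"]]
  tr <- run_trial(cond, seed = 5)
  expect_identical(tr$sma_traces, tr$deciding_traces)
  expect_true(tr$decided)
})

test_that("simulate_condition matches run_trial at n_runs = 1", {
  cond <- fit_conditions()[["arbitrary-hard"]]
  s <- simulate_condition(cond, 1, seed = 9)
  tr <- run_trial(cond, seed = 9)
  expect_equal(s$rt[1], tr$rt)
  expect_identical(s$winner[1], tr$winner)
})

test_that("degenerate parameters with no crossings raise an error", {
  weak <- accumulator_params(0.01, 0.5, 0, threshold = 0.3, t_max = 1)
  cond <- condition_params("arbitrary", "easy", weak, weak)
  expect_error(simulate_condition(cond, 10, seed = 1), "undecided")
})

test_that("parameter tables round-trip through CSV", {
  tab <- default_parameter_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_parameter_table(tab, path)
  expect_equal(read_parameter_table(path), tab)
  expect_error(condition_from_table(tab, "deliberate", "medium"),
               "no unique table entry")
})

test_that("invalid accumulator parameters are rejected", {
  expect_error(accumulator_params(NA, 0.5, 0.1))
  expect_error(accumulator_params(0.2, -0.1, 0.1))
  expect_error(accumulator_params(0.2, 0.5, 0.1, threshold = 0))
  expect_error(accumulator_params(0.2, 0.5, 0.1, dt = 0))
  # deliberate conditions require congruent >= incongruent drift
  expect_error(condition_params(
    "deliberate", "easy",
    accumulator_params(0.06, 0.5, 0.1),
    accumulator_params(0.23, 0.5, 0.1)), "congruent drift")
})
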