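test_that("filter contracts: notch depth, DC removal, passband flatness", {
  rate <- 512; n <- 90000; mid <- 30000:60000
  t <- seq_len(n) / rate
  # 60 Hz line noise is attenuated far beyond 20 dB
  s60 <- sin(2 * pi * 60 * t)
  r60 <- apply_filters(make_recording(s60))
  expect_lt(sd(r60$data[1, mid]) / sd(s60[mid]), 0.1)
  # a 50 uV DC offset is removed by the high-pass
  rdc <- apply_filters(make_recording(rep(50, n)))
  expect_lt(mean(abs(rdc$data[1, mid])), 1)
  # 5 Hz activity passes through unscathed
  s5 <- sin(2 * pi * 5 * t)
  r5 <- apply_filters(make_recording(s5))
  expect_equal(sd(r5$data[1, mid]), sd(s5[mid]), tolerance = 0.05)
  # corners at or above Nyquist are rejected
  expect_error(apply_filters(make_recording(s5), highpass_hz = 300),
               "Nyquist")
  expect_error(apply_filters(make_recording(s5), notch_band = c(250, 280)),
               "Nyquist")
})

test_that("artifact rules flag spikes and flatlines but spare clean EEG", {
  rate <- 512; n <- 40000
  set.seed(3)
  clean <- matrix(30 * sin(2 * pi * 7 * seq_len(n) / rate) +
                    rnorm(n, 0, 5), 1)
  rec <- make_recording(clean, rate)
  expect_false(any(reject_artifacts(rec)))

  # a 120 uV spike marks at least +/- 150 ms around itself
  spiked <- clean; t0 <- 20000L
  spiked[1, t0] <- 120
  mask <- reject_artifacts(make_recording(spiked, rate))
  pad <- round(0.15 * rate)
  expect_true(all(mask[(t0 - pad):(t0 + pad)]))
  # far from the spike (beyond pad + the 200 ms difference window) is clean
  expect_false(mask[t0 - 300L])
  expect_false(mask[t0 + 300L])

  # 200 ms of flat signal triggers the low-activity rule
  flat <- clean
  flat[1, 25000:25102] <- 0.01
  mask2 <- reject_artifacts(make_recording(flat, rate))
  expect_true(any(mask2[25000:25102]))

  # the difference rule: 100 uV swing inside 200 ms
  swingy <- clean
  swingy[1, 30000:30050] <- clean[1, 30000:30050] + 90
  mask3 <- reject_artifacts(make_recording(swingy, rate))
  expect_true(any(mask3[30000:30050]))
})

test_that("behavioral exclusion rules flag the right trials", {
  trials <- data.frame(subject = 1, condition = "a",
                       rt = c(0.15, 11, rep(1, 99), 1.3),
                       valid_key = TRUE)
  set.seed(8)
  trials$rt[3:101] <- 1 + rnorm(99, 0, 0.05)
  trials$valid_key[3] <- FALSE
  out <- exclude_trials(trials)
  expect_identical(out$reason[1], "rt_too_fast")
  expect_identical(out$reason[2], "rt_too_slow")
  expect_identical(out$reason[3], "wrong_key")
  # the 1.3 s trial sits > 3 SD from the surviving-trial mean
  expect_identical(out$reason[nrow(out)], "rt_outlier")
  expect_true(all(out$kept[4:101]))
  # conservation: every trial is kept or carries a reason
  expect_identical(sum(out$kept) + sum(!is.na(out$reason)), nrow(out))
})

test_that("epoching windows, baselining and bounds behave as documented", {
  rate <- 512
  # response-locked [-2, 0.2) at 512 Hz = 1126 samples (half-open)
  expect_length(raceRP:::window_samples(c(-2, 0.2), rate), 1126L)

  # constant channel: all epoch samples are 0 after baselining
  n <- 20000
  rec <- make_event_recording(matrix(7, 2, n), rate, rts = c(1, 1.2),
                              labels = c("Cz", "C3"))
  tr <- events_to_trials(rec$events)
  ep <- epoch_recording(rec, tr)
  expect_true(all(ep$data == 0))
  expect_identical(dim(ep$data)[3], 1126L)

  # linear drift: epoch equals drift minus its mean over the baseline
  drift <- seq_len(n) / rate  # 1 uV per second
  rec2 <- make_event_recording(matrix(drift, 1, n), rate, rts = 2,
                               first_stim_s = 10, labels = "Cz")
  tr2 <- events_to_trials(rec2$events)
  ep2 <- epoch_recording(rec2, tr2)
  stim_s <- tr2$stimulus_sample / rate
  base_mean <- mean(drift[tr2$stimulus_sample +
                            raceRP:::window_samples(c(-1, -0.5), rate)])
  resp_s <- tr2$response_sample
  expected <- drift[resp_s + raceRP:::window_samples(c(-2, 0.2), rate)] -
    base_mean
  expect_equal(ep2$data[1, 1, ], expected, tolerance = 1e-10)

  # baseline subtraction is idempotent: with a response-locked baseline
  # (inside the epoch window), re-subtracting the baseline mean from the
  # finished epoch changes nothing
  ep_r <- epoch_recording(rec2, tr2, baseline_lock = "response")
  boffs <- raceRP:::window_samples(c(-1, -0.5), rate)
  rel_b <- boffs - raceRP:::window_samples(c(-2, 0.2), rate)[1] + 1L
  again <- ep_r$data[1, 1, ] - mean(ep_r$data[1, 1, rel_b])
  expect_equal(again, ep_r$data[1, 1, ], tolerance = 1e-10)

  # epochs that run out of the recording are dropped with a reason
  rec3 <- make_event_recording(matrix(0, 1, 3000), rate, rts = 1,
                               first_stim_s = 0.5, labels = "Cz")
  ep3 <- epoch_recording(rec3, events_to_trials(rec3$events))
  expect_identical(dim(ep3$data)[1], 0L)
  expect_identical(ep3$meta$reason, "out_of_bounds")

  # trials overlapping the artifact mask are dropped with a reason
  mask <- logical(n); mask[rec$events$sample[3]] <- TRUE
  ep4 <- epoch_recording(rec, tr, bad_mask = mask)
  expect_identical(sum(ep4$meta$kept), 1L)
  expect_true("artifact" %in% ep4$meta$reason)
})

test_that("RP amplitude recovers an injected ramp and scales linearly", {
  rate <- 512; n <- 60000
  rts <- rep(2, 8)
  data <- matrix(0, 1, n, dimnames = list("Cz"))
  rec0 <- make_event_recording(data, rate, rts = rts, first_stim_s = 8,
                               spacing_s = 6, labels = "Cz")
  tr <- events_to_trials(rec0$events)
  # inject a ramp from 0 at -1.2 s to -2.5 uV at each response
  len <- round(1.2 * rate)
  ramp <- -2.5 * seq_len(len) / len
  for (s in tr$response_sample)
    rec0$data[1, (s - len + 1L):s] <- ramp
  tr$subject <- 1; tr$condition <- "arbitrary-easy"
  ep <- epoch_recording(rec0, tr)
  rp <- compute_rp(ep, min_trials = 1)
  # analytic mean of the ramp over the half-open [-0.5, 0) window
  offs <- raceRP:::window_samples(c(-0.5, 0), rate)
  expected <- mean(-2.5 * (len + offs) / len)
  expect_equal(rp$summary$mean_amplitude, expected, tolerance = 1e-6)
  expect_false(rp$summary$flagged)  # min_trials = 1

  # linearity: scaling the data scales the RP
  rec2 <- rec0; rec2$data <- 3 * rec2$data
  rp3 <- compute_rp(epoch_recording(rec2, tr), min_trials = 1)
  expect_equal(rp3$summary$mean_amplitude, 3 * expected, tolerance = 1e-6)

  # inclusion criterion: fewer than 30 trials flags the subject
  rp_flag <- compute_rp(ep, min_trials = 30)
  expect_true(rp_flag$summary$flagged)
})

test_that("zero-mean noise averages toward zero at the expected rate", {
  rate <- 512; n <- 80000
  set.seed(21)
  sigma <- 8
  rec <- make_event_recording(matrix(rnorm(n, 0, sigma), 1, n), rate,
                              rts = rep(1.5, 12), first_stim_s = 6,
                              spacing_s = 5, labels = "Cz")
  tr <- events_to_trials(rec$events)
  tr$subject <- 1; tr$condition <- "x"
  rp <- compute_rp(epoch_recording(rec, tr), min_trials = 1)
  # SE of a 12-trial mean of window means; allow 4 SE (baseline noise
  # contributes a comparable term)
  se <- sigma / sqrt(12)
  expect_lt(abs(rp$summary$mean_amplitude), 4 * se)
})

test_that("LRP is zero when C3 = C4 and antisymmetric under hand swap", {
  rate <- 512; n <- 50000
  set.seed(5)
  base <- rnorm(n, 0, 6)
  data <- rbind(Cz = rnorm(n, 0, 6), C3 = base, C4 = base)
  rec <- make_event_recording(data, rate, rts = rep(1.5, 8),
                              first_stim_s = 6, spacing_s = 5,
                              labels = c("Cz", "C3", "C4"))
  tr <- events_to_trials(rec$events)
  tr$subject <- 1
  ep <- epoch_recording(rec, tr)
  lrp <- compute_lrp(ep)
  expect_true(all(abs(lrp$grand) < 1e-10))

  # make C3 and C4 differ, then swap the hand labels: exact sign flip
  rec$data["C3", ] <- rec$data["C3", ] + rnorm(n, 0, 4)
  ep2 <- epoch_recording(rec, tr)
  lrp2 <- compute_lrp(ep2)
  tr_sw <- tr
  tr_sw$hand <- ifelse(tr$hand == "left", "right", "left")
  lrp_sw <- compute_lrp(epoch_recording(rec, tr_sw))
  expect_equal(lrp_sw$grand, -lrp2$grand, tolerance = 1e-10)

  # a hand with no trials is an error
  tr_one <- tr; tr_one$hand <- "left"
  expect_error(compute_lrp(epoch_recording(rec, tr_one)), "hand")
})

test_that("injected lateralized ramps appear in the LRP formula", {
  rate <- 512; n <- 60000
  rts <- rep(1.5, 10)
  data <- matrix(0, 3, n, dimnames = list(c("Cz", "C3", "C4")))
  rec <- make_event_recording(data, rate, rts = rts, first_stim_s = 6,
                              spacing_s = 5,
                              labels = c("Cz", "C3", "C4"))
  tr <- events_to_trials(rec$events)
  tr$subject <- 1
  # -x uV at the contralateral electrode (C4 for left-hand responses)
  # over the final 0.3 s
  x <- 2; len <- round(0.3 * rate)
  ramp <- -x * seq_len(len) / len
  for (i in seq_len(nrow(tr))) {
    ch <- if (tr$hand[i] == "left") "C4" else "C3"
    s <- tr$response_sample[i]
    rec$data[ch, (s - len + 1L):s] <- ramp
  }
  lrp <- compute_lrp(epoch_recording(rec, tr))
  # left trials: C3 - C4 = +ramp magnitude; right trials: -; the
  # difference doubles it, so the LRP at the response reaches +2x
  i0 <- which.min(abs(lrp$time))
  expect_equal(lrp$grand[i0], 2 * x, tolerance = 0.01)
  # and the average reference leaves the difference untouched
  lrp_ref <- compute_lrp(epoch_recording(rereference(rec,
                                                     exclude = character(0)),
                                         tr))
  expect_equal(lrp_ref$grand, lrp$grand, tolerance = 1e-10)
})

test_that("average reference subtracts the scalp mean", {
  rec <- make_recording(rbind(Cz = c(1, 2, 3), C3 = c(4, 5, 6),
                              EOG1 = c(7, 8, 9)),
                        labels = c("Cz", "C3", "EOG1"))
  rr <- rereference(rec)
  expect_equal(rr$data["Cz", ], c(1, 2, 3) - c(2.5, 3.5, 4.5))
  expect_equal(rr$data["EOG1", ], c(7, 8, 9) - c(2.5, 3.5, 4.5))
})
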