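test_that("event schedules have the expected structure and labels", {
  s <- makeEventSchedule(20, 20, 8, 0.25, 3.0, c(45, 90), seed = 1)
  ev <- events(s)
  expect_equal(nrow(ev), 320)
  expect_true(all(diff(ev$onset_s) > 0))
  expect_equal(unique(ev$condition[ev$trial < 20]), "pre")
  expect_equal(unique(ev$condition[ev$trial >= 20]), "drug")
  expect_equal(sort(unique(ev$puff_index)), 0:7)
  # within-series spacing is exactly the inter-puff interval
  d <- diff(ev$onset_s[ev$trial == 3])
  expect_equal(d, rep(3, 7))
})

test_that("minimal schedules and seeded determinism behave", {
  s1 <- makeEventSchedule(1, 0, 1, 0.25, 3.0, c(45, 45), seed = 0)
  expect_equal(nrow(events(s1)), 1)
  s2 <- makeEventSchedule(6, 6, seed = 9)
  s3 <- makeEventSchedule(6, 6, seed = 9)
  expect_identical(events(s2), events(s3))
  s4 <- makeEventSchedule(6, 6, seed = 10)
  expect_false(identical(events(s2)$onset_s, events(s4)$onset_s))
  expect_error(makeEventSchedule(0, 0), "positive")
  expect_error(makeEventSchedule(2, 2, puff_duration = 0), ">")
  expect_error(makeEventSchedule(2, 2, inter_puff_interval = 0.1), ">")
})

test_that("noiseless archetype kernels follow their closed forms", {
  tru <- groundTruth(seed = 1, latent = list(timescale = c(pre = 1),
                                             sd = c(pre = 0)))
  sch <- makeEventSchedule(1, 0, puffs_per_series = 1, seed = 1,
                           first_start = 30)
  pop <- simulatePopulation(sch, tru, noise_sd = 0, t_range = c(0, 80))
  un <- unitTable(tru)
  t <- timeAxis(pop)
  on <- events(sch)$onset_s[1]

  # fast transient back to within 1% of baseline by +0.5 s
  ft <- which(un$archetype == "fast_transient")[1]
  r <- rates(pop)[ft, ]
  v <- r[which.min(abs(t - (on + 0.5)))]
  expect_lt(abs(v - un$baseline[ft]), 0.01 * un$amplitude[ft])

  # delayed persistent decays by 1/e of peak excess after tau_persist
  dp <- which(un$archetype == "delayed_persistent")[1]
  r <- rates(pop)[dp, ]
  pk <- which.max(r)
  peak_excess <- r[pk] - un$baseline[dp]
  v10 <- r[which.min(abs(t - (t[pk] + 10)))] - un$baseline[dp]
  expect_equal(v10, peak_excess / exp(1), tolerance = 0.05)

  # unmodulated unit is flat; all rates non-negative
  um <- which(un$archetype == "unmodulated")[1]
  expect_equal(sd(rates(pop)[um, ]), 0)
  expect_true(all(rates(pop) >= 0))
})

test_that("population simulation is seed-deterministic and validates labels", {
  s1 <- smallSession(seed = 5, n_pre = 2, n_post = 2)
  s2 <- smallSession(seed = 5, n_pre = 2, n_post = 2)
  expect_identical(rates(s1$population), rates(s2$population))
  tru <- groundTruth(seed = 1,
                     params = biphasicParams(tau_persist = c(pre = 10)))
  sch <- makeEventSchedule(1, 1, seed = 1)  # has a "drug" condition
  expect_error(simulatePopulation(sch, tru), "tau_persist")
})

test_that("LFP background follows the configured power law", {
  tru <- groundTruth(seed = 4, factors = list(), oscillations = data.frame())
  sch <- makeEventSchedule(1, 0, seed = 4, first_start = 30)
  lfp <- simulateLfp(sch, tru, duration = 120)
  sp <- multitaperSpectrogram(lfp$signals[1, ], lfp$fs, freq_range = c(2, 80))
  psd <- colMeans(sp$power)
  slope <- coef(lm(log10(psd) ~ log10(sp$freq_hz)))[2]
  expect_equal(unname(slope), -tru@chi, tolerance = 0.15)
})

test_that("planted condition-gated oscillations appear in the right epochs", {
  tru <- groundTruth(seed = 6,
                     oscillations = data.frame(center_hz = 4, bw_hz = 1,
                                               amplitude = 1.5,
                                               condition = "drug"))
  sch <- makeEventSchedule(1, 1, seed = 6, inter_trial_range = c(60, 60),
                           first_start = 60)
  lfp <- simulateLfp(sch, tru)
  tt <- trialTable(sch)
  bandPow <- function(t0, t1) {
    idx <- affectdyn:::windowIdx(lfp$time_s, t0, t1)
    sp <- multitaperSpectrogram(lfp$signals[1, idx], lfp$fs, window = 1,
                                stride = 0.5, freq_range = c(2, 20))
    mean(colMeans(sp$power)[abs(sp$freq_hz - 4) <= 1])
  }
  pre_pow <- bandPow(tt$first_onset[1], tt$last_onset[1])
  drug_pow <- bandPow(tt$first_onset[2], tt$last_onset[2])
  expect_gt(drug_pow / pre_pow, 3)
  expect_error(
    simulateLfp(sch, groundTruth(seed = 1, oscillations = data.frame(
      center_hz = 150, bw_hz = 1, amplitude = 1, condition = NA))),
    "Nyquist")
})

test_that("coupled channel pairs have a constant analytic phase offset", {
  tru <- groundTruth(seed = 8,
                     coupled_pairs = data.frame(i = 1, j = 2,
                                                lag_rad = pi / 3))
  sch <- makeEventSchedule(1, 0, seed = 8, first_start = 30)
  lfp <- simulateLfp(sch, tru, duration = 60)
  pl <- plvOverTime(lfp$signals[1, ], lfp$signals[2, ], 12, 30, lfp$fs)
  expect_gt(mean(pl$plv), 0.95)
})

test_that("eye traces reduce to the model trace in the degenerate case", {
  tru <- groundTruth(seed = 2)
  sch <- makeEventSchedule(2, 2, seed = 2)
  eye <- simulateEyeTraces(sch, tru, blink_amplitude = 0, noise_sd = 0)
  tr1 <- eye[[1]]
  model <- simulateBiphasic(tru@params, tr1$condition, tr1$puff_onsets,
                            0.25, t = tr1$time_s)
  expect_equal(tr1$closure, model$x, tolerance = 1e-12)
  # zero-input params give blinks only
  tru0 <- groundTruth(seed = 2, params = biphasicParams(
    S = 0, tau_broadcast = 0.1, tau_persist = c(pre = 10, drug = 1)))
  eye0 <- simulateEyeTraces(sch, tru0, blink_amplitude = 0.5, noise_sd = 0)
  off_blink <- affectdyn:::windowIdx(eye0[[1]]$time_s, -2, 0)
  expect_true(all(eye0[[1]]$closure[off_blink] == 0))
  expect_gt(max(eye0[[1]]$closure), 0.45)
  # closure bounded in [0, 1]
  eye1 <- simulateEyeTraces(sch, tru, noise_sd = 0.3)
  rng <- range(unlist(lapply(eye1, `[[`, "closure")))
  expect_gte(rng[1], 0); expect_lte(rng[2], 1)
})

test_that("shorter drug persistence lowers post-series eye closure", {
  tru <- groundTruth(seed = 3)   # tau_persist pre = 10, drug = 1
  sch <- makeEventSchedule(3, 3, seed = 3)
  eye <- simulateEyeTraces(sch, tru, noise_sd = 0)
  lastPuffMean <- function(tr) {
    on <- max(tr$puff_onsets)
    mean(tr$closure[affectdyn:::windowIdx(tr$time_s, on + 0.3, on + 0.8)])
  }
  m <- vapply(eye, lastPuffMean, numeric(1))
  cond <- vapply(eye, `[[`, character(1), "condition")
  expect_lt(mean(m[cond == "drug"]), mean(m[cond == "pre"]))
})
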