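test_that("the two-phase closed forms are exact", {
  p <- biphasicParams(S = 1, tau_broadcast = 0.1, tau_persist = c(pre = 10))
  tr <- simulateBiphasic(p, "pre", onsets = 0, durations = 0.25,
                         t = c(0.25, 10.25))
  expect_equal(tr$x[1], 1 - exp(-2.5), tolerance = 1e-12)
  expect_equal(tr$x[2], (1 - exp(-2.5)) / exp(1), tolerance = 1e-12)
  # zero input stays at zero
  p0 <- biphasicParams(S = 0, tau_broadcast = 0.1, tau_persist = c(pre = 10))
  expect_true(all(simulateBiphasic(p0, "pre", 0, 0.25, dt = 0.01,
                                   t_end = 5)$x == 0))
  # near-infinite persistence: per-gap decrement below e^{-2.75/100}
  pl <- biphasicParams(S = 1, tau_broadcast = 0.1,
                       tau_persist = c(pre = 100))
  sch <- puffSeriesSchedule()
  tr2 <- simulateBiphasic(pl, "pre", sch$onsets, sch$durations,
                          t = sch$onsets[-1] - 1e-9)
  dec <- tr2$x[-1] / tr2$x[-length(tr2$x)]
  expect_true(all(dec >= exp(-2.75 / 100) - 1e-6))
  expect_error(simulateBiphasic(p, "pre", c(0, 0.1), 0.25), "overlap")
})

test_that("saturation and phase continuity hold", {
  p <- biphasicParams(S = 2, tau_broadcast = 0.1, tau_persist = c(a = 3))
  # long constant input: monotone approach to S, never exceeded
  tr <- simulateBiphasic(p, "a", 0, durations = 5, dt = 0.001, t_end = 5)
  expect_true(all(diff(tr$x) >= -1e-12))
  expect_true(all(tr$x <= p@S + 1e-12))
  # continuity at every transition of the standard schedule
  sch <- puffSeriesSchedule()
  bounds <- sort(c(sch$onsets, sch$onsets + sch$durations))
  eps <- 1e-9
  tr2 <- simulateBiphasic(p, "a", sch$onsets, sch$durations,
                          t = sort(c(bounds - eps, bounds + eps)))
  jumps <- abs(diff(tr2$x)[seq(1, length(tr2$x) - 1, by = 2)])
  expect_lt(max(jumps), 1e-6)
})

test_that("noiseless fits recover the generating parameters within 1%", {
  sch <- puffSeriesSchedule()
  t <- seq(0, sch$t_end, by = 0.01)
  p <- biphasicParams(S = 1, tau_broadcast = 0.1,
                      tau_persist = c(pre = 10, drug = 1))
  traces <- list(
    pre = simulateBiphasic(p, "pre", sch$onsets, sch$durations, t = t)$x,
    drug = simulateBiphasic(p, "drug", sch$onsets, sch$durations, t = t)$x)
  fit <- fitBiphasic(traces, t, sch$onsets, sch$durations, n_starts = 6)
  expect_equal(unname(fit$S["pre"]), 1, tolerance = 0.01)
  expect_equal(unname(fit$tau_broadcast["pre"]), 0.1, tolerance = 0.01)
  expect_equal(unname(fit$tau_persist["pre"]), 10, tolerance = 0.01)
  expect_equal(unname(fit$tau_persist["drug"]), 1, tolerance = 0.01)
  expect_true(fit$converged)
})

test_that("multi-start fitting is identifiable on the standard schedule", {
  # different seeds (hence different start jitter) agree to 4 significant
  # digits on noiseless data
  sch <- puffSeriesSchedule()
  t <- seq(0, sch$t_end, by = 0.01)
  p <- biphasicParams(S = 0.8, tau_broadcast = 0.15,
                      tau_persist = c(pre = 6))
  traces <- list(pre = simulateBiphasic(p, "pre", sch$onsets,
                                        sch$durations, t = t)$x)
  f1 <- fitBiphasic(traces, t, sch$onsets, sch$durations, n_starts = 5,
                    seed = 1)
  f2 <- fitBiphasic(traces, t, sch$onsets, sch$durations, n_starts = 5,
                    seed = 99)
  expect_equal(f1$tau_persist, f2$tau_persist, tolerance = 1e-4)
  expect_equal(f1$S, f2$S, tolerance = 1e-4)
})

test_that("a constant-zero trace drives S to the bound with a flag", {
  sch <- puffSeriesSchedule(tail_s = 10)
  t <- seq(0, sch$t_end, by = 0.02)
  fit <- fitBiphasic(list(pre = numeric(length(t))), t, sch$onsets,
                     sch$durations, n_starts = 3)
  expect_lt(fit$S[["pre"]], 1e-3)
  expect_true(fit$at_bound)
  expect_error(fitBiphasic(list(pre = c(1, NA, NA)), c(0, 1, 2), 0, 0.25),
               "fewer data points")
})

test_that("masked samples are excluded from the fit residual", {
  sch <- puffSeriesSchedule()
  t <- seq(0, sch$t_end, by = 0.01)
  p <- biphasicParams(S = 1, tau_broadcast = 0.1, tau_persist = c(pre = 5))
  x <- simulateBiphasic(p, "pre", sch$onsets, sch$durations, t = t)$x
  xm <- x
  for (on in sch$onsets) {
    idx <- affectdyn:::windowIdx(t, on, on + 0.75)
    xm[idx] <- NA            # blink-mask convention for behavioural fits
  }
  fit <- fitBiphasic(list(pre = xm), t, sch$onsets, sch$durations,
                     n_starts = 5)
  expect_equal(unname(fit$tau_persist["pre"]), 5, tolerance = 0.01)
})

test_that("variance explained behaves at its anchors", {
  sch <- puffSeriesSchedule()
  t <- seq(0, sch$t_end, by = 0.02)
  p <- biphasicParams(S = 1, tau_broadcast = 0.1,
                      tau_persist = c(pre = 10, drug = 1))
  traces <- list(
    pre = simulateBiphasic(p, "pre", sch$onsets, sch$durations, t = t)$x,
    drug = simulateBiphasic(p, "drug", sch$onsets, sch$durations, t = t)$x)
  full <- fitBiphasic(traces, t, sch$onsets, sch$durations, n_starts = 5)
  null <- fitBiphasic(traces, t, sch$onsets, sch$durations, free = "none",
                      n_starts = 5)
  ev <- varianceExplained(traces, full, null)
  expect_gt(ev, 0.99)          # model == data: EV at its ceiling
  # model == null prediction: EV of the null against itself is 0
  expect_equal(varianceExplained(traces, null, null), 0)
})
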