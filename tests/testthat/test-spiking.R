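test_that("modulation screening keeps its null false-positive rate low", {
  # unmodulated units under the 5-test battery: flagged rate stays near
  # 1 - (1 - 0.01)^5 with slack for window correlation
  sch <- makeEventSchedule(4, 0, puffs_per_series = 4, seed = 61,
                           inter_trial_range = c(20, 25), first_start = 20)
  set.seed(61)
  n_units <- 150
  t <- seq(0, max(events(sch)$onset_s) + 10, by = 0.02)
  R <- matrix(rnorm(n_units * length(t), 5, 1), n_units)
  act <- populationActivity(R, t, 0.02)
  flags <- significantModulation(act, sch)
  expect_lte(mean(flags), 0.07)
})

test_that("planted responses are flagged and constants never crash", {
  sess <- smallSession(seed = 62, n_pre = 4, n_post = 0)
  flags <- significantModulation(sess$population, sess$schedule)
  un <- unitTable(sess$truth)
  ft <- un$unit[un$archetype == "fast_transient"]
  expect_true(all(flags[ft]))
  # constant-rate unit: not flagged, no crash
  t <- timeAxis(sess$population)
  actc <- populationActivity(rbind(const = rep(3, length(t))), t,
                             binWidth(sess$population))
  expect_false(significantModulation(actc, sess$schedule)[["const"]])
})

test_that("response clustering separates planted archetypes", {
  # two archetypes, noiseless: two clusters with perfect purity
  tru <- groundTruth(seed = 63, n_units = 20,
                     mix = c(fast_transient = 0.5,
                             delayed_persistent = 0.5),
                     latent = list(timescale = c(pre = 1), sd = c(pre = 0)))
  sch <- makeEventSchedule(2, 0, seed = 63)
  pop <- simulatePopulation(sch, tru, noise_sd = 0)
  cl <- clusterResponses(pop, sch, k = 2)
  un <- unitTable(tru)
  tab <- table(cl$labels, un$archetype)
  expect_equal(max(tab["1", ]) + max(tab["2", ]), 20)   # purity 1
  # transient cluster decays before the persistent cluster
  lab_ft <- cl$labels[un$unit[un$archetype == "fast_transient"][1]]
  expect_equal(unname(lab_ft), 1L)   # ordered by decay time
  # identical units force the single-cluster path
  t <- timeAxis(pop)
  one <- rates(pop)[rep(1, 12), ]
  rownames(one) <- sprintf("u%02d", 1:12)
  actI <- populationActivity(one, t, binWidth(pop))
  clI <- clusterResponses(actI, sch, k = NULL)
  expect_equal(clI$k, 1L)
  expect_error(clusterResponses(pop[1:5, ], sch), "10 units")
})

test_that("archetype mixtures cluster well at moderate noise", {
  tru <- groundTruth(seed = 64, n_units = 40,
                     mix = c(fast_transient = 0.3, fast_persistent = 0.25,
                             delayed_persistent = 0.25, suppressed = 0.2),
                     latent = list(timescale = c(pre = 1), sd = c(pre = 0)))
  sch <- makeEventSchedule(4, 0, seed = 64)
  pop <- simulatePopulation(sch, tru, noise_sd = 1)   # peak/noise = 4
  cl <- clusterResponses(pop, sch, k = 4)
  un <- unitTable(tru)
  # adjusted Rand index against the planted archetypes
  ari <- function(a, b) {
    tab <- table(a, b)
    sij <- sum(choose(tab, 2)); si <- sum(choose(rowSums(tab), 2))
    sj <- sum(choose(colSums(tab), 2)); n2 <- choose(sum(tab), 2)
    exp_ <- si * sj / n2
    (sij - exp_) / ((si + sj) / 2 - exp_)
  }
  expect_gte(ari(cl$labels, un$archetype), 0.8)
})

test_that("region-cluster composition flags only true enrichment", {
  set.seed(65)
  # uniform assignment: no flags expected in most runs
  hits <- vapply(1:30, function(i) {
    lab <- sample(1:4, 120, replace = TRUE)
    reg <- rep(c("A", "B", "C"), each = 40)
    any(clusterRegionComposition(lab, reg)$flagged)
  }, logical(1))
  expect_lte(mean(hits), 0.2)
  # a region fully concentrated in one of 4 clusters is flagged
  lab <- c(rep(1L, 40), sample(1:4, 40, replace = TRUE))
  reg <- rep(c("conc", "unif"), each = 40)
  out <- clusterRegionComposition(lab, reg)
  expect_true(out$flagged[out$region == "conc" & out$cluster == 1])
  # a single cluster in total is degenerate: no flags
  out1 <- clusterRegionComposition(rep(1L, 30), rep(c("A", "B"), 15))
  expect_false(any(out1$flagged))
})

# build a deterministic-rate region whose d' trace has a step rise at
# `rise_at` and exponential decay `tau`, from puff-replicate traces
rampRegion <- function(rise_at = 0.07, tau = 0.3, amp = 5, noise = 0.15,
                       peak_at = rise_at, seed = 66, puffs = 2,
                       series = 6) {
  sch <- makeEventSchedule(series, 0, puffs_per_series = puffs,
                           seed = seed, inter_trial_range = c(15, 15),
                           first_start = 10)
  t <- seq(0, max(events(sch)$onset_s) + 10, by = 0.01)
  x <- numeric(length(t))
  for (on in events(sch)$onset_s) {
    idx <- affectdyn:::windowIdx(t, on + rise_at, on + rise_at + 8 * tau)
    x[idx] <- x[idx] + amp * exp(-(t[idx] - (on + peak_at)) / tau)
  }
  set.seed(seed)
  # ride on a positive baseline so rectification cannot distort the decay
  R <- 2 + matrix(rep(x, each = 12), 12) + rnorm(12 * length(t), 0, noise)
  rownames(R) <- sprintf("u%02d", 1:12)
  act <- populationActivity(pmax(R, 0), t, 0.01,
                            siteData = data.frame(region = rep("R1", 12)))
  list(act = act, sch = sch,
       labels = setNames(rep(1L, 12), rownames(R)))
}

test_that("decay-to-25% follows the closed form within one bin", {
  # exact synthetic d' trace: step to 2 at 0.07 s, then exp(-t/0.3)
  time_s <- seq(-1, 2, by = 0.01)
  d <- ifelse(time_s >= 0.07, 2 * exp(-(time_s - 0.07) / 0.3), 0)
  out <- riseDecayFromDprime(d, time_s)
  expect_false(out$excluded)
  expect_equal(out$decay, 0.07 + 0.3 * log(4), tolerance = 0.011)
  expect_equal(out$rise, 0.07, tolerance = 0.011)
  expect_lte(out$rise, out$peak_t)
  expect_lte(out$peak_t, out$decay)
})

test_that("rise/decay exclusion rules fire on constructed edge cases", {
  time_s <- seq(-1, 2, by = 0.01)
  # peak d' of 1.0 is under the 1.3 floor
  d_low <- ifelse(time_s >= 0.07, exp(-(time_s - 0.07) / 0.3), 0)
  expect_true(riseDecayFromDprime(d_low, time_s)$excluded)
  # peak at 0.9 s breaches the 750 ms latency ceiling
  d_late <- ifelse(time_s >= 0.9, 2 * exp(-(time_s - 0.9) / 0.3), 0)
  expect_true(riseDecayFromDprime(d_late, time_s)$excluded)
  # a trace that never recrosses the threshold flags its decay undefined
  d_flat <- ifelse(time_s >= 0.07, 2, 0)
  out <- riseDecayFromDprime(d_flat, time_s)
  expect_false(out$excluded)
  expect_true(is.na(out$decay))
})

test_that("regional rise/decay recovers the planted kinetics", {
  rr <- rampRegion(amp = 0.25, series = 20)  # peak d' in the 3-6 range
  out <- riseDecayTimes(rr$act, rr$sch, rr$labels, n_boot = 50)
  expect_equal(nrow(out), 1)
  expect_equal(out$decay_s, 0.07 + 0.3 * log(4), tolerance = 0.2)
  expect_lte(out$rise_s, out$decay_s)
  expect_true(is.finite(out$decay_lo) && out$decay_lo <= out$decay_s)
  # huge noise pushes the peak below the floor: region dropped
  rr_low <- rampRegion(amp = 0.02, noise = 1)
  expect_equal(nrow(riseDecayTimes(rr_low$act, rr_low$sch, rr_low$labels,
                                   n_boot = 0)), 0)
})

test_that("planted regional decay constants are recovered in order", {
  taus <- c(R1 = 0.1, R2 = 0.3, R3 = 1.0)
  # low noise, one puff per series, many replicates (the d' denominator
  # is a per-bin variance across replicates, so precision needs trials):
  # decay follows the closed form
  acts <- lapply(names(taus), function(r)
    rampRegion(tau = taus[[r]], amp = 0.3, noise = 0.02, puffs = 1,
               series = 60, seed = 70 + match(r, names(taus))))
  decs <- vapply(seq_along(taus), function(i) {
    rr <- acts[[i]]
    riseDecayTimes(rr$act, rr$sch, rr$labels, n_boot = 0)$decay_s
  }, numeric(1))
  expect_false(is.unsorted(decs))
  # closed form decay-to-25% = rise_at + tau * ln 4, up to the first-
  # crossing bias of a finitely-sampled per-bin variance denominator
  expect_equal(decs, unname(0.07 + taus * log(4)), tolerance = 0.15)
  # at realistic noise the ordering is preserved
  actsN <- lapply(names(taus), function(r)
    rampRegion(tau = taus[[r]], amp = 0.3, noise = 0.15, puffs = 1,
               series = 60, seed = 80 + match(r, names(taus))))
  decsN <- vapply(seq_along(taus), function(i) {
    rr <- actsN[[i]]
    riseDecayTimes(rr$act, rr$sch, rr$labels, n_boot = 0)$decay_s
  }, numeric(1))
  expect_false(is.unsorted(decsN))
})

test_that("drug shortens regional decay but not rise", {
  tru <- groundTruth(seed = 67, n_units = 30,
                     params = biphasicParams(
                       tau_persist = c(pre = 1, drug = 0.3)),
                     mix = c(fast_persistent = 1),
                     regions = c("A", "B"),
                     latent = list(timescale = c(pre = 1, drug = 1),
                                   sd = c(pre = 0, drug = 0)))
  sch <- makeEventSchedule(5, 5, seed = 67)
  pop <- simulatePopulation(sch, tru, noise_sd = 0.3)
  lab <- setNames(rep(1L, 30), unitTable(tru)$unit)
  pre <- riseDecayTimes(pop, sch, lab, condition = "pre", n_boot = 0)
  drug <- riseDecayTimes(pop, sch, lab, condition = "drug", n_boot = 0)
  shared <- intersect(pre$region[!is.na(pre$decay_s)],
                      drug$region[!is.na(drug$decay_s)])
  expect_gt(length(shared), 0)
  pre <- pre[match(shared, pre$region), ]
  drug <- drug[match(shared, drug$region), ]
  expect_true(all(drug$decay_s < pre$decay_s))
  expect_lt(max(abs(drug$rise_s - pre$rise_s)), 0.1)
})
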