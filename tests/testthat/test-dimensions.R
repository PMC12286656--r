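# direct-arithmetic oracle for a one-site coding weight
rawWeight <- function(mt, vt, mr, vr) (mt - mr) / sqrt(vt + vr)

test_that("coding weights follow the standardized-difference formula", {
  # one site, alternating event values: target mean 2 var 1, ref mean 1 var 1
  bw <- 0.1
  t <- seq(0, 19.9, by = bw)
  onsets <- seq(2, 18, by = 2)
  x <- numeric(length(t))
  for (e in seq_along(onsets)) {
    tgt <- affectdyn:::windowIdx(t, onsets[e] + 0.1, onsets[e] + 0.6)
    ref <- affectdyn:::windowIdx(t, onsets[e] - 0.6, onsets[e] - 0.1)
    x[tgt] <- 2 + (e %% 2) * 2 - 1     # alternating 1, 3: mean 2, var ~1
    x[ref] <- 1 + (e %% 2) * 2 - 1     # alternating 0, 2: mean 1, var ~1
  }
  act <- populationActivity(rbind(site1 = x), t, bw)
  d <- codingDimension(act, onsets, target = c(0.1, 0.6),
                       reference = c(-0.6, -0.1), normalization = "unit_norm")
  # one site: normalization maps any weight to +-1; check the raw sign
  expect_equal(unname(dimWeights(d)), 1)
  # oracle on the same numbers: 1/sqrt(2)
  ev_t <- c(eventWindowMeans(act, onsets, c(0.1, 0.6)))
  ev_r <- c(eventWindowMeans(act, onsets, c(-0.6, -0.1)))
  w_raw <- rawWeight(mean(ev_t), var(ev_t), mean(ev_r), var(ev_r))
  expect_equal(w_raw, (2 - 1) / sqrt(var(ev_t) + var(ev_r)),
               tolerance = 0.05)
  expect_equal(w_raw, 1 / sqrt(2), tolerance = 0.1)
})

test_that("degenerate and symmetric weight cases behave", {
  bw <- 0.1
  t <- seq(0, 19.9, by = bw)
  onsets <- seq(2, 18, by = 2)
  flat <- populationActivity(rbind(a = rep(1, length(t)),
                                   b = rep(1, length(t))), t, bw)
  expect_error(codingDimension(flat, onsets, c(0.1, 0.6), c(-0.6, -0.1)),
               "degenerate")
  # two identical informative sites: equal weights of 0.5 under sum_abs
  x <- numeric(length(t))
  for (e in seq_along(onsets))
    x[affectdyn:::windowIdx(t, onsets[e], onsets[e] + 0.5)] <-
      1 + 0.3 * (e %% 2)
  act <- populationActivity(rbind(a = x, b = x), t, bw)
  d <- codingDimension(act, onsets, c(0, 0.5), c(-0.5, 0),
                       normalization = "sum_abs")
  expect_equal(unname(dimWeights(d)), c(0.5, 0.5))
  expect_error(codingDimension(act, onsets, c(0, 0.5), c(-0.2, 0.2)),
               "overlap")
})

test_that("orthogonalization is exact Gram-Schmidt", {
  mk <- function(w) methods::new("CodingDimension",
    weights = setNames(w / sqrt(sum(w^2)), c("a", "b")),
    normalization = "unit_norm", target_window = c(0, 1),
    reference_window = c(-1, 0), condition = "pre")
  d <- mk(c(1, 1)); n <- mk(c(1, 0))
  o <- orthogonalize(d, n)
  expect_equal(unname(dimWeights(o)), c(0, 1), tolerance = 1e-12)
  # orthogonal inputs unchanged; parallel inputs error
  o2 <- orthogonalize(mk(c(0, 1)), n)
  expect_equal(unname(dimWeights(o2)), c(0, 1))
  expect_error(orthogonalize(d, d), "parallel")
})

test_that("projections reduce to the site trace for a single-site dimension", {
  bw <- 0.1
  t <- seq(0, 39.9, by = bw)
  set.seed(51)
  x <- rnorm(length(t))
  act <- populationActivity(rbind(s = x), t, bw)
  d <- methods::new("CodingDimension", weights = c(s = 1),
                    normalization = "unit_norm", target_window = c(0, 1),
                    reference_window = c(-1, 0), condition = "pre")
  onsets <- c(10, 20, 30)
  pr <- projectActivity(act, d, onsets, window = c(-0.5, 1.5),
                        zscore_window = c(-0.5, 1.5))
  # each row is the z-scored, baseline-subtracted site trace
  i0 <- affectdyn:::.binAt(t, onsets[1] - 0.5)
  seg <- x[i0:(i0 + ncol(pr$proj) - 1)]
  seg <- (seg - mean(seg)) / sd(seg)
  seg <- seg - mean(seg[affectdyn:::windowIdx(pr$time_s, -0.5, 0)])
  expect_equal(pr$proj[1, ], seg, tolerance = 1e-10)
  # missing sites are an explicit error
  d2 <- methods::new("CodingDimension", weights = c(zz = 1),
                     normalization = "unit_norm", target_window = c(0, 1),
                     reference_window = c(-1, 0), condition = "pre")
  expect_error(projectActivity(act, d2, onsets), "missing")
})

test_that("d-prime traces follow their closed form", {
  set.seed(52)
  n_ev <- 200
  time_s <- seq(-1, 1.9, by = 0.1)
  base <- matrix(rnorm(n_ev * length(time_s)), n_ev)
  d0 <- dprimeTrace(base, time_s)
  expect_lt(max(abs(d0$d_prime[time_s > 0]), na.rm = TRUE), 0.35)
  # mean shift of 1 with unit variances gives d' near 1; doubling doubles
  shift <- base
  shift[, time_s >= 0.5 & time_s < 1.0] <-
    shift[, time_s >= 0.5 & time_s < 1.0] + 1
  d1 <- dprimeTrace(shift, time_s)
  win <- time_s >= 0.5 & time_s < 1.0
  expect_equal(mean(d1$d_prime[win]), 1, tolerance = 0.15)
  shift2 <- base
  shift2[, win] <- shift2[, win] + 2
  d2 <- dprimeTrace(shift2, time_s)
  expect_equal(mean(d2$d_prime[win]) / mean(d1$d_prime[win]), 2,
               tolerance = 0.05)
})

test_that("the emotion-like dimension isolates persistent units", {
  sess <- smallSession(seed = 53, n_pre = 5, n_post = 0)
  mod <- significantModulation(sess$population, sess$schedule)
  act <- sess$population[mod, ]
  ed <- emotionDimension(act, sess$schedule)
  # exact orthogonality to the fast dimension
  expect_lt(abs(sum(dimWeights(ed$emotion) * dimWeights(ed$fast))), 1e-10)
  # top-decile weights recover planted persistent units
  w <- sort(abs(dimWeights(ed$emotion)), decreasing = TRUE)
  un <- unitTable(sess$truth)
  top <- names(w)[seq_len(ceiling(0.1 * length(w)))]
  pers <- un$unit[un$archetype %in% c("fast_persistent",
                                      "delayed_persistent")]
  expect_gte(mean(top %in% pers), 0.8)
  # a noiseless population with only fast-transient units degenerates:
  # nothing separates post-series from pre-series state
  tru0 <- groundTruth(seed = 55, n_units = 12,
                      mix = c(fast_transient = 1),
                      latent = list(timescale = c(pre = 1), sd = c(pre = 0)))
  sch0 <- makeEventSchedule(3, 0, seed = 55)
  pop0 <- simulatePopulation(sch0, tru0, noise_sd = 0)
  expect_error(emotionDimension(pop0, sch0), "degenerate")
})

test_that("sum_abs projections ignore zero-weight sites", {
  bw <- 0.1
  t <- seq(0, 39.9, by = bw)
  set.seed(54)
  x <- rnorm(length(t))
  act1 <- populationActivity(rbind(a = x), t, bw)
  act2 <- populationActivity(rbind(a = x, z = rnorm(length(t))), t, bw)
  d1 <- methods::new("CodingDimension", weights = c(a = 1),
                     normalization = "sum_abs", target_window = c(0, 1),
                     reference_window = c(-1, 0), condition = "pre")
  d2 <- methods::new("CodingDimension", weights = c(a = 1, z = 0),
                     normalization = "sum_abs", target_window = c(0, 1),
                     reference_window = c(-1, 0), condition = "pre")
  pr1 <- projectActivity(act1, d1, c(10, 20))
  pr2 <- projectActivity(act2, d2, c(10, 20))
  expect_equal(pr1$proj, pr2$proj, tolerance = 1e-12)
})
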