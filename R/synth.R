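# Seeded synthetic-session generator. Every planted structure is recorded
# in a GroundTruth object so each downstream analysis can be validated
# against what was generated.

ARCHETYPES <- c("fast_transient", "fast_persistent", "delayed_persistent",
                "suppressed", "unmodulated")

#' Construct the ground truth of a synthetic session
#'
#' Defines everything the generator plants: two-phase model parameters,
#' per-unit response archetypes with regions, evoked spectrotemporal
#' factors, band-limited oscillations gated by condition, phase-coupled
#' channel pairs, and the shared slow latent that couples persistent units
#' at baseline.
#'
#' @param params \code{\linkS4class{BiphasicParams}}; the per-condition
#'   \code{tau_persist} drives persistent-unit decay and the affective eye
#'   closure
#' @param n_units number of simulated units
#' @param regions region labels cycled across units
#' @param mix named proportions over the five archetypes
#' @param amplitude peak rate excess of modulated units (spikes/s)
#' @param baseline baseline rate (spikes/s)
#' @param n_channels number of LFP-like channels
#' @param factors list of planted evoked factors; each a list with
#'   \code{center_hz}, \code{t_start}, \code{t_dur}, \code{amplitude},
#'   \code{sign} ("positive" or "negative") and \code{loadings}
#'   (length \code{n_channels})
#' @param oscillations data.frame with \code{center_hz}, \code{bw_hz},
#'   \code{amplitude}, \code{condition} (label, or NA for always on)
#' @param coupled_pairs data.frame with \code{i}, \code{j},
#'   \code{lag_rad}, and optionally \code{low}/\code{high} band edges
#' @param latent list with named numerics \code{timescale} (s) and
#'   \code{sd} per condition, for the shared latent added to persistent
#'   units; set \code{sd = 0} to disable
#' @param chi aperiodic exponent of the 1/f^chi LFP background
#' @param seed master integer seed
#' @return a \code{\linkS4class{GroundTruth}}
#' @export
groundTruth <- function(params = biphasicParams(),
                        n_units = 40,
                        regions = c("AMY", "HPC", "PFC", "TH", "VIS"),
                        mix = c(fast_transient = 0.25, fast_persistent = 0.2,
                                delayed_persistent = 0.2, suppressed = 0.1,
                                unmodulated = 0.25),
                        amplitude = 4, baseline = 5,
                        n_channels = 8,
                        factors = list(),
                        oscillations = data.frame(),
                        coupled_pairs = data.frame(),
                        latent = list(timescale = c(pre = 1, drug = 0.3),
                                      sd = c(pre = 1.5, drug = 0.5)),
                        chi = 2, seed = 1L) {
  stopifnot(all(names(mix) %in% ARCHETYPES), n_units >= 1)
  mix <- mix / sum(mix)
  counts <- diff(round(cumsum(c(0, mix)) * n_units))
  archetype <- rep(names(mix), counts)
  if (length(archetype) < n_units)
    archetype <- c(archetype, rep("unmodulated", n_units - length(archetype)))
  # deterministic interleave so every region receives every archetype
  units <- data.frame(
    unit = sprintf("u%03d", seq_len(n_units)),
    region = rep_len(regions, n_units),
    archetype = archetype,
    amplitude = ifelse(archetype == "suppressed", -0.5 * amplitude,
                       ifelse(archetype == "unmodulated", 0, amplitude)),
    baseline = baseline)
  if (nrow(oscillations) && any(oscillations$center_hz <= 0))
    stop("oscillation center frequencies must be positive")
  new("GroundTruth", params = params, units = units, factors = factors,
      oscillations = oscillations, coupled_pairs = coupled_pairs,
      latent = latent, chi = chi, seed = as.integer(seed))
}

#' Generate a puff-series event schedule
#'
#' Series of \code{puffs_per_series} puffs at a fixed inter-puff interval,
#' repeated over trials with seeded uniform inter-trial gaps; trials up to
#' \code{n_trials_pre} are labelled \code{"pre"} and subsequent trials
#' \code{"drug"} (override with \code{conditions}).
#'
#' @param n_trials_pre,n_trials_post trial counts before and after the
#'   infusion transition
#' @param puffs_per_series puffs per series
#' @param puff_duration puff duration, seconds
#' @param inter_puff_interval onset-to-onset interval within a series,
#'   seconds; must exceed \code{puff_duration}
#' @param inter_trial_range two-element range (seconds) of the uniform gap
#'   between a series' last puff offset and the next series' first onset
#' @param seed integer seed for the gap draws
#' @param first_start onset of the very first puff (seconds); the preceding
#'   quiet span is the session baseline epoch
#' @param conditions optional per-trial condition labels
#'   (length \code{n_trials_pre + n_trials_post})
#' @return an \code{\linkS4class{EventSchedule}}
#' @export
makeEventSchedule <- function(n_trials_pre = 20, n_trials_post = 20,
                              puffs_per_series = 8, puff_duration = 0.25,
                              inter_puff_interval = 3.0,
                              inter_trial_range = c(45, 90), seed = 1L,
                              first_start = 150, conditions = NULL) {
  n_trials <- n_trials_pre + n_trials_post
  if (n_trials < 1 || puffs_per_series < 1)
    stop("trial and puff counts must be positive")
  if (puff_duration <= 0 || inter_puff_interval <= puff_duration)
    stop("need inter_puff_interval > puff_duration > 0")
  if (n_trials_pre < 0 || n_trials_post < 0)
    stop("trial counts must be non-negative")
  if (is.null(conditions))
    conditions <- c(rep("pre", n_trials_pre), rep("drug", n_trials_post))
  stopifnot(length(conditions) == n_trials)

  set.seed(substreamSeed(seed, "events"))
  gaps <- runif(n_trials, inter_trial_range[1], inter_trial_range[2])
  series_len <- (puffs_per_series - 1) * inter_puff_interval + puff_duration
  rows <- vector("list", n_trials)
  start <- first_start
  for (tr in seq_len(n_trials)) {
    onsets <- start + (seq_len(puffs_per_series) - 1) * inter_puff_interval
    rows[[tr]] <- data.frame(
      onset_s = onsets, duration_s = puff_duration, trial = tr - 1L,
      puff_index = seq_len(puffs_per_series) - 1L,
      condition = conditions[tr])
    start <- start + series_len + gaps[tr]
  }
  new("EventSchedule", events = do.call(rbind, rows))
}

# condition label in effect at arbitrary session times, from trial blocks
conditionAtTime <- function(schedule, t, pad = 35) {
  tt <- trialTable(schedule)
  breaks <- c(-Inf, tt$first_onset[-1] - pad, Inf)
  tt$condition[findInterval(t, breaks)]
}

# difference-of-exponentials kernel, peak-normalized to `amp`
.doeKernel <- function(t, tau_r, tau_d, amp) {
  tpk <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  pk <- exp(-tpk / tau_d) - exp(-tpk / tau_r)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- amp * (exp(-t[pos] / tau_d) - exp(-t[pos] / tau_r)) / pk
  out
}

.archetypeTaus <- function(archetype, tau_persist) {
  switch(archetype,
         fast_transient = c(0.02, 0.08),
         fast_persistent = c(0.02, tau_persist),
         delayed_persistent = c(0.3, tau_persist),
         suppressed = c(0.02, 0.1),
         unmodulated = c(0.02, 0.08))
}

#' Simulate population firing rates
#'
#' Each unit's rate is baseline + an archetype-specific
#' difference-of-exponentials kernel convolved with the event train +
#' (for persistent archetypes) a shared slow latent + i.i.d. Gaussian
#' noise, rectified at zero. Persistent archetypes decay with the
#' condition-specific \code{tau_persist} of the ground-truth model
#' parameters, so the "drug" condition shortens their persistence.
#'
#' @param schedule an \code{\linkS4class{EventSchedule}}
#' @param truth a \code{\linkS4class{GroundTruth}}
#' @param bin_width bin width, seconds
#' @param noise_sd per-bin Gaussian noise SD (rate units)
#' @param t_range session time span covered (seconds); default covers the
#'   schedule with 60 s margins
#' @return a \code{\linkS4class{PopulationActivity}}
#' @export
simulatePopulation <- function(schedule, truth, bin_width = 0.01,
                               noise_sd = 0.5, t_range = NULL) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  ev <- events(schedule)
  condset <- unique(ev$condition)
  if (!all(condset %in% names(truth@params@tau_persist)))
    stop("schedule conditions missing from ground-truth tau_persist")
  if (is.null(t_range))
    t_range <- c(max(0, min(ev$onset_s) - 60), max(ev$onset_s) + 60)
  time_s <- seq(t_range[1], t_range[2], by = bin_width)
  nt <- length(time_s)
  un <- truth@units
  n_units <- nrow(un)

  # shared latent: AR(1)/OU with condition-dependent timescale and sd
  lat <- truth@latent
  latent <- numeric(nt)
  if (!is.null(lat$sd) && any(lat$sd > 0)) {
    set.seed(substreamSeed(truth@seed, "latent"))
    cond_bin <- conditionAtTime(schedule, time_s)
    ts_bin <- lat$timescale[cond_bin]
    sd_bin <- lat$sd[cond_bin]
    ts_bin[is.na(ts_bin)] <- mean(lat$timescale)
    sd_bin[is.na(sd_bin)] <- 0
    phi <- exp(-bin_width / ts_bin)
    innov <- rnorm(nt)
    for (i in 2:nt)
      latent[i] <- phi[i] * latent[i - 1] +
        sqrt(1 - phi[i]^2) * sd_bin[i] * innov[i]
  }

  set.seed(substreamSeed(truth@seed, "rates"))
  R <- matrix(0, n_units, nt)
  tau_p <- truth@params@tau_persist
  for (u in seq_len(n_units)) {
    r <- rep(un$baseline[u], nt)
    if (un$archetype[u] != "unmodulated" && un$amplitude[u] != 0) {
      for (e in seq_len(nrow(ev))) {
        taus <- .archetypeTaus(un$archetype[u], tau_p[[ev$condition[e]]])
        support <- min(8 * taus[2] + 1, 90)
        i0 <- max(1L, .binAt(time_s, ev$onset_s[e]))
        i1 <- min(nt, i0 + ceiling(support / bin_width))
        if (i1 >= i0) {
          idx <- i0:i1
          r[idx] <- r[idx] + .doeKernel(time_s[idx] - ev$onset_s[e],
                                        taus[1], taus[2], un$amplitude[u])
        }
      }
    }
    if (un$archetype[u] %in% c("fast_persistent", "delayed_persistent"))
      r <- r + latent
    if (noise_sd > 0) r <- r + rnorm(nt, 0, noise_sd)
    R[u, ] <- pmax(r, 0)
  }
  rownames(R) <- un$unit
  populationActivity(R, time_s, bin_width,
                     siteData = un[, c("unit", "region", "archetype")])
}

# spectrally shaped 1/f^chi noise, unit variance; generated at a highly
# composite FFT length and truncated
.oneOverFNoise <- function(n, fs, chi) {
  m <- stats::nextn(n, c(2, 3, 5))
  w <- rnorm(m)
  W <- fft(w)
  f <- c(0, seq_len(m - 1)) * fs / m
  f <- pmin(f, fs - f)          # two-sided frequency magnitude
  shape <- ifelse(f > 0, f^(-chi / 2), 0)
  x <- Re(fft(W * shape, inverse = TRUE) / m)[seq_len(n)]
  x / sd(x)
}

#' Simulate multichannel LFP-like signals
#'
#' Each channel is a 1/f^chi background plus planted narrowband
#' oscillations gated by their condition, plus evoked spectrotemporal
#' bursts after each puff scaled by planted per-channel factor loadings,
#' plus a shared narrowband source with a fixed phase lag for coupled
#' channel pairs.
#'
#' @param schedule an \code{\linkS4class{EventSchedule}}
#' @param truth a \code{\linkS4class{GroundTruth}}
#' @param fs sampling rate, Hz (>= 200)
#' @param duration total duration, seconds; default covers the schedule
#' @return list with \code{signals} (channels x samples matrix),
#'   \code{fs}, \code{time_s}
#' @export
simulateLfp <- function(schedule, truth, fs = 200, duration = NULL) {
  if (fs < 200) stop("fs must be >= 200 Hz")
  ev <- events(schedule)
  if (is.null(duration)) duration <- max(ev$onset_s) + 30
  if (duration < max(ev$onset_s)) stop("duration does not cover the schedule")
  osc <- truth@oscillations
  if (nrow(osc) && any(osc$center_hz >= fs / 2))
    stop("planted oscillation frequency above Nyquist")
  nch <- max(8, vapply(truth@factors, function(f) length(f$loadings), 1L), 0)
  if (length(truth@factors))
    nch <- length(truth@factors[[1]]$loadings)
  n <- floor(duration * fs)
  time_s <- seq_len(n) / fs
  set.seed(substreamSeed(truth@seed, "lfp"))
  X <- matrix(0, nch, n)
  for (ch in seq_len(nch)) X[ch, ] <- .oneOverFNoise(n, fs, truth@chi)

  cond_t <- conditionAtTime(schedule, time_s)
  if (nrow(osc)) {
    for (k in seq_len(nrow(osc))) {
      gate <- if (is.na(osc$condition[k])) rep(1, n)
              else as.numeric(cond_t == osc$condition[k])
      chs <- if (!is.null(osc$channel) && !is.na(osc$channel[k]))
               osc$channel[k] else seq_len(nch)
      ph <- runif(length(chs), 0, 2 * pi)
      for (i in seq_along(chs))
        X[chs[i], ] <- X[chs[i], ] +
          osc$amplitude[k] * gate * sin(2 * pi * osc$center_hz[k] * time_s +
                                        ph[i])
    }
  }

  if (length(truth@factors)) {
    for (f in truth@factors) {
      sgn <- if (!is.null(f$sign)) f$sign else "positive"
      env <- numeric(n)
      for (on in ev$onset_s) {
        idx <- windowIdx(time_s, on + f$t_start, on + f$t_start + f$t_dur)
        if (length(idx))
          env[idx] <- env[idx] +
            0.5 * (1 - cos(2 * pi * seq_along(idx) / length(idx)))
      }
      carrier <- sin(2 * pi * f$center_hz * time_s)
      if (sgn == "positive") {
        for (ch in seq_len(nch))
          X[ch, ] <- X[ch, ] + f$amplitude * f$loadings[ch] * env * carrier
      } else {
        # standing oscillation whose amplitude dips after each puff
        for (ch in seq_len(nch))
          X[ch, ] <- X[ch, ] + f$amplitude *
            pmax(0, 1 - f$loadings[ch] * env) * carrier
      }
    }
  }

  cp <- truth@coupled_pairs
  if (nrow(cp)) {
    for (k in seq_len(nrow(cp))) {
      lo <- if (!is.null(cp$low)) cp$low[k] else 12
      hi <- if (!is.null(cp$high)) cp$high[k] else 30
      src <- bandpassFiltfilt(rnorm(n), lo, hi, fs)
      src <- src / sd(src)
      lagged <- Re(analyticSignal(src) * exp(-1i * cp$lag_rad[k]))
      X[cp$i[k], ] <- X[cp$i[k], ] + src
      X[cp$j[k], ] <- X[cp$j[k], ] + lagged
    }
  }
  rownames(X) <- sprintf("ch%02d", seq_len(nch))
  list(signals = X, fs = fs, time_s = time_s)
}

#' Simulate per-trial eye-closure traces
#'
#' Closure(t) = the two-phase model state driven by the trial's puff train
#' (the affective component, using the trial condition's
#' \code{tau_persist}) + a stereotyped raised-cosine blink after each puff
#' onset + Gaussian noise, clipped to [0, 1]. With
#' \code{blink_amplitude = 0} and \code{noise_sd = 0} the trace equals the
#' model simulation exactly (for S <= 1).
#'
#' @param schedule an \code{\linkS4class{EventSchedule}}
#' @param truth a \code{\linkS4class{GroundTruth}}
#' @param fs trace sampling rate, Hz
#' @param blink_amplitude peak closure of the reflexive blink, in [0, 1]
#' @param blink_duration blink kernel duration, seconds
#' @param noise_sd Gaussian noise SD (closure units)
#' @param pre_s seconds of trace before the first puff of each series
#' @param tail_s seconds of trace after the last puff of each series
#' @return list of per-trial traces, each a list with \code{time_s}
#'   (relative to the series' first puff), \code{closure}, \code{trial},
#'   \code{condition}, \code{fs}, \code{puff_onsets} (relative)
#' @export
simulateEyeTraces <- function(schedule, truth, fs = 100,
                              blink_amplitude = 0.6, blink_duration = 0.4,
                              noise_sd = 0.02, pre_s = 2, tail_s = 40) {
  if (blink_amplitude < 0 || blink_amplitude > 1)
    stop("blink_amplitude must be in [0, 1]")
  ev <- events(schedule)
  set.seed(substreamSeed(truth@seed, "eye"))
  out <- lapply(split(ev, ev$trial), function(d) {
    t0 <- min(d$onset_s)
    rel_on <- d$onset_s - t0
    t <- seq(-pre_s, max(rel_on) + d$duration_s[1] + tail_s, by = 1 / fs)
    tr <- simulateBiphasic(truth@params, d$condition[1], rel_on,
                           d$duration_s, t = t)
    closure <- tr$x
    if (blink_amplitude > 0) {
      for (on in rel_on) {
        idx <- windowIdx(t, on, on + blink_duration)
        closure[idx] <- closure[idx] + blink_amplitude * 0.5 *
          (1 - cos(2 * pi * (t[idx] - on) / blink_duration))
      }
    }
    if (noise_sd > 0) closure <- closure + rnorm(length(t), 0, noise_sd)
    list(time_s = t, closure = pmin(pmax(closure, 0), 1),
         trial = d$trial[1], condition = d$condition[1], fs = fs,
         puff_onsets = rel_on)
  })
  names(out) <- NULL
  out
}

#' Simulate a complete synthetic session
#'
#' Convenience wrapper generating the event schedule, population rates,
#' LFP-like signals and eye traces from one ground truth and seed.
#'
#' @param truth a \code{\linkS4class{GroundTruth}}; its seed drives all
#'   randomness
#' @param n_trials_pre,n_trials_post trial counts
#' @param with_lfp,with_eye,with_rates stage switches
#' @param ... passed to \code{\link{makeEventSchedule}}
#' @return list with \code{schedule}, \code{truth} and the requested
#'   components (\code{population}, \code{lfp}, \code{eye})
#' @export
simulateSession <- function(truth = groundTruth(),
                            n_trials_pre = 20, n_trials_post = 20,
                            with_rates = TRUE, with_lfp = FALSE,
                            with_eye = TRUE, ...) {
  schedule <- makeEventSchedule(n_trials_pre, n_trials_post,
                                seed = truth@seed, ...)
  out <- list(schedule = schedule, truth = truth)
  if (with_rates) out$population <- simulatePopulation(schedule, truth)
  if (with_lfp) out$lfp <- simulateLfp(schedule, truth)
  if (with_eye) out$eye <- simulateEyeTraces(schedule, truth)
  out
}
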