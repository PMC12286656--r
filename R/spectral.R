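# Multitaper peri-event spectrograms with double z-scoring, and
# band-limited Hilbert power envelopes.

.dpssCache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Tapers are eigenvectors of the standard symmetric tridiagonal matrix for
#' the given time-bandwidth product, normalized to unit energy. For long
#' windows (n > 1024) tapers are computed at n = 1024 and spline-resampled,
#' the usual approximation for spectral estimation. Results are cached.
#'
#' @param n window length in samples
#' @param nw time-bandwidth product
#' @param k number of tapers (default \code{floor(2 nw) - 1})
#' @return n x k matrix, one taper per column
#' @export
dpssTapers <- function(n, nw, k = max(1, floor(2 * nw) - 1)) {
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.dpssCache[[key]])) return(.dpssCache[[key]])
  n0 <- min(n, 1024L)
  W <- nw / n0
  i <- seq_len(n0) - 1
  dg <- ((n0 - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
  od <- i[-1] * (n0 - i[-1]) / 2
  Tm <- diag(dg)
  Tm[cbind(seq_len(n0 - 1), seq_len(n0 - 1) + 1)] <- od
  Tm[cbind(seq_len(n0 - 1) + 1, seq_len(n0 - 1))] <- od
  eg <- eigen(Tm, symmetric = TRUE)
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  # polarity convention: symmetric tapers have positive mean, others a
  # positive initial slope
  for (j in seq_len(k)) {
    s <- sum(V[, j])
    if (abs(s) > 1e-8) { if (s < 0) V[, j] <- -V[, j] }
    else if (sum(V[seq_len(n0 %/% 2), j]) < 0) V[, j] <- -V[, j]
  }
  if (n > n0) {
    x0 <- seq(0, 1, length.out = n0)
    x1 <- seq(0, 1, length.out = n)
    V <- apply(V, 2, function(v) spline(x0, v, xout = x1)$y)
  }
  V <- apply(V, 2, function(v) v / sqrt(sum(v^2)))
  .dpssCache[[key]] <- V
  V
}

#' Multitaper spectrogram
#'
#' Sliding-window multitaper power estimate. Power in each window is the
#' average over \code{floor(2 time_bandwidth) - 1} DPSS tapers (3 tapers at
#' the default time-bandwidth of 2) of the squared Fourier magnitude of the
#' mean-removed, tapered window. Window timestamps are window centers.
#'
#' @param x numeric signal
#' @param fs sampling rate, Hz
#' @param time_bandwidth time-bandwidth product
#' @param window window width, seconds
#' @param stride window step, seconds
#' @param freq_range frequency axis limits, Hz
#' @param t0 time of the first sample (seconds)
#' @return list of class \code{Spectrogram}: \code{power} (time x freq),
#'   \code{time_s}, \code{freq_hz}, \code{fs}, \code{stride}
#' @export
multitaperSpectrogram <- function(x, fs, time_bandwidth = 2, window = 0.4,
                                  stride = 0.05, freq_range = c(1, 100),
                                  t0 = 0) {
  nwin <- round(window * fs)
  if (nwin < 8) stop("window too short: need window * fs >= 8 samples")
  if (stride > window) stop("stride must not exceed window")
  n <- length(x)
  if (n < nwin) stop("signal shorter than one window: empty output")
  hop <- max(1L, round(stride * fs))
  starts <- seq(1L, n - nwin + 1L, by = hop)
  V <- dpssTapers(nwin, time_bandwidth)
  freqs <- (seq_len(nwin) - 1) * fs / nwin
  keep <- which(freqs >= freq_range[1] & freqs <= min(freq_range[2], fs / 2))
  P <- matrix(0, length(starts), length(keep))
  for (w in seq_along(starts)) {
    seg <- x[starts[w]:(starts[w] + nwin - 1L)]
    seg <- seg - mean(seg)
    Ft <- mvfft(V * seg)
    P[w, ] <- (2 / fs) * rowMeans(Mod(Ft[keep, , drop = FALSE])^2)
  }
  structure(list(power = P,
                 time_s = t0 + (starts - 1 + nwin / 2) / fs,
                 freq_hz = freqs[keep], fs = fs, stride = hop / fs),
            class = "Spectrogram")
}

#' @export
print.Spectrogram <- function(x, ...) {
  cat(sprintf("Spectrogram: %d windows x %d freqs (%.1f-%.1f Hz), stride %.3g s\n",
              nrow(x$power), ncol(x$power), min(x$freq_hz), max(x$freq_hz),
              x$stride))
  invisible(x)
}

#' Double z-scored peri-event tensor
#'
#' First z-scores the spectrogram at each frequency against a long session
#' baseline epoch, then cuts a window around each event and z-scores it
#' again at each frequency against that event's immediately preceding
#' baseline. Frequencies with zero baseline variance are flagged and
#' excluded.
#'
#' @param spec a \code{Spectrogram}
#' @param events an \code{\linkS4class{EventSchedule}}, or numeric onsets
#' @param session_baseline half-open epoch (seconds) for the session
#'   z-score; the conventional choice is the 120 s preceding the first
#'   series
#' @param per_event_baseline seconds of pre-event baseline for the second
#'   z-score
#' @param event_window half-open peri-event window, seconds from onset
#' @param channel,condition provenance; condition defaults to the
#'   schedule's per-event labels
#' @return a \code{\linkS4class{PeriEventTensor}}; excluded frequencies in
#'   \code{attr(, "excluded_freqs")}
#' @export
doubleZscore <- function(spec, events, session_baseline,
                         per_event_baseline = 1.5,
                         event_window = c(-0.5, 2), channel = "ch",
                         condition = NULL) {
  if (is(events, "EventSchedule")) {
    ev <- events(events)
    onsets <- ev$onset_s
    if (is.null(condition)) condition <- ev$condition
  } else {
    onsets <- events
    if (is.null(condition)) condition <- rep("pre", length(onsets))
  }
  tt <- spec$time_s
  P <- spec$power
  bidx <- windowIdx(tt, session_baseline[1], session_baseline[2])
  if (length(bidx) < 2) stop("session baseline epoch has too few windows")
  mu <- colMeans(P[bidx, , drop = FALSE])
  sdv <- apply(P[bidx, , drop = FALSE], 2, sd)
  bad <- sdv == 0
  Z <- sweep(sweep(P, 2, mu), 2, ifelse(bad, 1, sdv), "/")

  nb <- max(1L, floor((event_window[2] - event_window[1]) / spec$stride))
  vals <- array(NA_real_, c(length(onsets), nb, ncol(P)))
  for (e in seq_along(onsets)) {
    i0 <- which(tt >= onsets[e] + event_window[1])[1]
    if (is.na(i0) || i0 + nb - 1 > nrow(Z))
      stop("event ", e, " window extends beyond the spectrogram")
    pb <- windowIdx(tt, onsets[e] - per_event_baseline, onsets[e])
    if (length(pb) < 2) stop("event ", e, " lacks a pre-event baseline")
    m2 <- colMeans(Z[pb, , drop = FALSE])
    s2 <- apply(Z[pb, , drop = FALSE], 2, sd)
    bad <- bad | s2 == 0
    vals[e, , ] <- sweep(sweep(Z[i0:(i0 + nb - 1), , drop = FALSE], 2, m2),
                         2, ifelse(s2 == 0, 1, s2), "/")
  }
  keep <- which(!bad)
  if (length(keep) == 0) stop("all frequencies excluded (zero variance)")
  out <- periEventTensor(vals[, , keep, drop = FALSE],
                         time_s = event_window[1] +
                           spec$stride * (seq_len(nb) - 1),
                         freq_hz = spec$freq_hz[keep],
                         channel = channel, condition = condition)
  attr(out, "excluded_freqs") <- spec$freq_hz[bad]
  out
}

#' Canonical frequency bands
#'
#' The seven bands used throughout: delta 1-4, theta 4-8, alpha 8-12,
#' beta 12-30, low gamma 30-50, high gamma 65-95 Hz, and broadband
#' (unfiltered, coded NA).
#' @return data.frame with \code{name}, \code{low}, \code{high}
#' @export
canonicalBands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "low_gamma",
                      "high_gamma", "broadband"),
             low = c(1, 4, 8, 12, 30, 65, NA),
             high = c(4, 8, 12, 30, 50, 95, NA))
}

#' Band-limited power envelope
#'
#' Zero-phase fifth-order Butterworth band-pass (applied forward and
#' backward), squared magnitude of the analytic signal, then z-scored over
#' the given epoch.
#'
#' @param x numeric signal
#' @param low,high band edges, Hz (both NA for broadband: no filtering)
#' @param fs sampling rate, Hz
#' @param zscore_epoch half-open epoch (seconds from signal start) over
#'   which to z-score; NULL for the whole signal; NA to skip z-scoring
#' @param t0 time of the first sample
#' @return list with \code{power}, \code{time_s}, \code{fs}
#' @export
bandEnvelope <- function(x, low, high, fs, zscore_epoch = NULL, t0 = 0) {
  if (!is.na(low) && (low <= 0 || high >= fs / 2))
    stop("band edges outside (0, fs/2)")
  xf <- if (is.na(low)) x else bandpassFiltfilt(x, low, high, fs)
  p <- Mod(analyticSignal(xf))^2
  time_s <- t0 + (seq_along(x) - 1) / fs
  if (!(length(zscore_epoch) == 1 && is.na(zscore_epoch))) {
    idx <- if (is.null(zscore_epoch)) seq_along(p)
           else windowIdx(time_s, zscore_epoch[1], zscore_epoch[2])
    if (length(idx) < 2) stop("z-score epoch is empty")
    p <- (p - mean(p[idx])) / sd(p[idx])
  }
  list(power = p, time_s = time_s, fs = fs)
}
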