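# Baseline intrinsic-timescale estimation, sliding-window phase-locking
# value, and persistent-subnetwork coupling change.

#' Intrinsic timescale of a baseline activity trace
#'
#' Computes the autocorrelation of the whole (mean-subtracted) series with
#' biased normalization, then fits \code{a * exp(-lag/b) + c} from the
#' autocorrelation peak to \code{max_lag} seconds to its right,
#' initialized at \code{(a, b, c) = (1, 0.2, 0)}. The fitted \code{b} is
#' the timescale; fits with \code{b} under two samples are flagged
#' non-converged.
#'
#' @param x numeric series (a stationary baseline segment)
#' @param dt sample interval, seconds
#' @param max_lag fit extent right of the peak, seconds
#' @param init initialization \code{c(a, b, c)}
#' @return a \code{\linkS4class{TimescaleFit}}
#' @export
intrinsicTimescale <- function(x, dt, max_lag = 2.5, init = c(1, 0.2, 0)) {
  n <- length(x)
  if (n * dt < 4 * max_lag)
    stop("series shorter than 4 * max_lag; unstable autocorrelation")
  nl <- min(n - 2, round(max_lag / dt))
  ac <- as.vector(acf(x, lag.max = nl, plot = FALSE,
                      demean = TRUE)$acf)     # biased (divide by n)
  lag_s <- dt * (seq_along(ac) - 1)            # peak is at lag 0
  fit <- tryCatch(
    nls.lm(par = init, lower = c(-Inf, dt / 10, -Inf),
           fn = function(p) p[1] * exp(-lag_s / p[2]) + p[3] - ac,
           control = nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(new("TimescaleFit", a = NA_real_, b = NA_real_, c = NA_real_,
               converged = FALSE))
  p <- fit$par
  conv <- fit$info %in% 1:4 && p[2] >= 2 * dt
  new("TimescaleFit", a = p[1], b = p[2], c = p[3], converged = conv)
}

#' Sliding-window phase-locking value
#'
#' Band-passes both signals with a zero-phase fifth-order Butterworth
#' filter, extracts analytic phases, and computes per window the magnitude
#' of the circular mean of the phase differences.
#'
#' @param x,y equal-length signals
#' @param low,high band edges, Hz
#' @param fs sampling rate, Hz
#' @param window window length, seconds
#' @param stride window step, seconds (defaults to the window length:
#'   non-overlapping)
#' @return list with \code{plv}, \code{time_s} (window centers)
#' @export
plvOverTime <- function(x, y, low, high, fs, window = 5, stride = window) {
  stopifnot(length(x) == length(y))
  nw <- round(window * fs)
  if (nw > length(x)) stop("window longer than the signals")
  phx <- Arg(analyticSignal(bandpassFiltfilt(x, low, high, fs)))
  phy <- Arg(analyticSignal(bandpassFiltfilt(y, low, high, fs)))
  z <- exp(1i * (phx - phy))
  starts <- seq(1L, length(x) - nw + 1L, by = max(1L, round(stride * fs)))
  plv <- vapply(starts, function(s) Mod(mean(z[s:(s + nw - 1L)])),
                numeric(1))
  list(plv = plv, time_s = (starts - 1 + nw / 2) / fs)
}

#' Pairwise baseline correlations
#'
#' Pearson correlation between every pair of sites within each pre-series
#' baseline window (the 30 s before each series by default), averaged
#' within condition. Zero-variance sites yield NA for their pairs.
#'
#' @param activity a \code{\linkS4class{PopulationActivity}}
#' @param schedule an \code{\linkS4class{EventSchedule}}
#' @param window_s baseline window length before each series' first puff,
#'   seconds
#' @return list of class \code{CouplingResult}: \code{mean_r} (named list
#'   of site x site matrices per condition), \code{n_windows} per
#'   condition, \code{sites}
#' @export
pairwiseCorrelations <- function(activity, schedule, window_s = 30) {
  t <- timeAxis(activity)
  R <- rates(activity)
  tt <- trialTable(schedule)
  out <- list(); nw <- list()
  for (cn in unique(tt$condition)) {
    starts <- tt$first_onset[tt$condition == cn]
    mats <- list()
    for (s in starts) {
      idx <- windowIdx(t, s - window_s, s)
      if (length(idx) < 10) next
      M <- t(R[, idx, drop = FALSE])
      sds <- apply(M, 2, sd)
      cm <- suppressWarnings(cor(M))
      cm[sds == 0, ] <- NA; cm[, sds == 0] <- NA
      mats[[length(mats) + 1]] <- cm
    }
    if (length(mats) == 0) stop("no usable baseline windows for ", cn)
    out[[cn]] <- Reduce("+", mats) / length(mats)
    nw[[cn]] <- length(mats)
  }
  structure(list(mean_r = out, n_windows = nw, sites = rownames(R)),
            class = "CouplingResult")
}

#' Persistent-subnetwork coupling change
#'
#' Ranks sites by absolute coding-dimension weight, takes the top
#' \code{(100 - top_percentile)}% as the subnetwork, restricts coupling to
#' edges with both endpoints inside it, and summarizes the infusion
#' condition against the pre-infusion reference: \code{"corr_normalize"}
#' divides the mean correlation by the pre-infusion mean,
#' \code{"plv_zscore"} z-scores each edge's infusion values against its
#' pre-infusion windows and averages.
#'
#' @param coupling a \code{CouplingResult} (for \code{"corr_normalize"}),
#'   or a list per condition of edge x window PLV matrices (for
#'   \code{"plv_zscore"})
#' @param dim a \code{\linkS4class{CodingDimension}} over the same sites
#' @param infusion,reference condition labels
#' @param top_percentile percentile cut on |weight| (90 keeps the top
#'   tenth; 0 keeps everything)
#' @param mode \code{"corr_normalize"} or \code{"plv_zscore"}
#' @return list with \code{change} (scalar), \code{members},
#'   \code{mode}
#' @export
subnetworkCouplingChange <- function(coupling, dim, infusion = "drug",
                                     reference = "pre",
                                     top_percentile = 90,
                                     mode = c("corr_normalize",
                                              "plv_zscore")) {
  mode <- match.arg(mode)
  w <- abs(dim@weights)
  thr <- quantile(w, top_percentile / 100)
  members <- names(w)[w >= thr]
  if (length(members) < 2) stop("subnetwork smaller than 2 sites")
  if (mode == "corr_normalize") {
    stopifnot(inherits(coupling, "CouplingResult"))
    sub <- function(cm) {
      m <- cm[members, members]
      mean(m[upper.tri(m)], na.rm = TRUE)
    }
    ref <- sub(coupling$mean_r[[reference]])
    if (!is.finite(ref) || ref == 0) stop("degenerate reference coupling")
    change <- sub(coupling$mean_r[[infusion]]) / ref
  } else {
    # coupling: per condition, edges x windows PLV with edge names "a|b"
    ref <- coupling[[reference]]; inf <- coupling[[infusion]]
    keep <- vapply(strsplit(rownames(ref), "|", fixed = TRUE),
                   function(p) all(p %in% members), logical(1))
    if (sum(keep) == 0) stop("no edges inside the subnetwork")
    mu <- rowMeans(ref[keep, , drop = FALSE])
    sdv <- apply(ref[keep, , drop = FALSE], 1, sd)
    z <- (rowMeans(inf[keep, , drop = FALSE]) - mu) /
      ifelse(sdv > 0, sdv, 1)
    change <- mean(z)
  }
  list(change = change, members = members, mode = mode)
}
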