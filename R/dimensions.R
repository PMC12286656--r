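# Population coding dimensions (fast / persistent / emotion-like),
# nuisance orthogonalization, and projection time series. One generic code
# path serves both unit firing rates and channel band-power envelopes.

# events x sites matrix of window means relative to each onset
eventWindowMeans <- function(activity, onsets, window) {
  t <- timeAxis(activity)
  R <- rates(activity)
  bw <- binWidth(activity)
  nb <- max(1L, floor((window[2] - window[1]) / bw))
  i0 <- .binAt(t, onsets + window[1])
  if (any(i0 < 1) || any(i0 + nb - 1 > ncol(R)))
    stop("event window [", window[1], ",", window[2],
         ") extends beyond the recording")
  out <- matrix(NA_real_, length(onsets), nrow(R),
                dimnames = list(NULL, rownames(R)))
  for (e in seq_along(onsets))
    out[e, ] <- rowMeans(R[, i0[e]:(i0[e] + nb - 1L), drop = FALSE])
  out
}

#' Construct a coding dimension
#'
#' Per-site weight
#' \code{(mean_target - mean_reference) / sqrt(var_target + var_reference)}
#' with means and variances taken across events, then normalized to unit
#' L2 norm (\code{"unit_norm"}) or unit sum of absolute weights
#' (\code{"sum_abs"}). Sites with zero pooled variance get weight 0.
#'
#' @param activity a \code{\linkS4class{PopulationActivity}}
#' @param onsets event onsets (seconds, session clock)
#' @param target,reference half-open windows (seconds from onset); must
#'   not overlap
#' @param normalization \code{"unit_norm"} or \code{"sum_abs"}
#' @param condition training-condition label recorded in the result
#' @return a \code{\linkS4class{CodingDimension}}
#' @export
codingDimension <- function(activity, onsets, target, reference,
                            normalization = c("unit_norm", "sum_abs"),
                            condition = "pre") {
  normalization <- match.arg(normalization)
  if (length(onsets) < 2) stop("need at least 2 events")
  if (max(target[1], reference[1]) < min(target[2], reference[2]))
    stop("target and reference windows overlap")
  Mt <- eventWindowMeans(activity, onsets, target)
  Mr <- eventWindowMeans(activity, onsets, reference)
  mt <- colMeans(Mt); mr <- colMeans(Mr)
  vt <- apply(Mt, 2, var); vr <- apply(Mr, 2, var)
  pooled <- vt + vr
  w <- ifelse(pooled > 0, (mt - mr) / sqrt(pooled), 0)
  if (all(w == 0)) stop("all sites have zero variance: degenerate dimension")
  w <- .normalizeWeights(w, normalization)
  new("CodingDimension", weights = w, normalization = normalization,
      target_window = target, reference_window = reference,
      condition = condition)
}

.normalizeWeights <- function(w, mode) {
  nrm <- switch(mode, unit_norm = sqrt(sum(w^2)), sum_abs = sum(abs(w)),
                none = 1)
  if (nrm == 0) stop("zero-norm weight vector")
  w / nrm
}

#' Orthogonalize a coding dimension against a nuisance dimension
#'
#' Removes the component of \code{dim} along \code{nuisance}
#' (Gram-Schmidt, equivalent to thin QR) and re-normalizes under
#' \code{dim}'s mode.
#'
#' @param dim,nuisance \code{\linkS4class{CodingDimension}} objects over
#'   the same sites
#' @return a \code{\linkS4class{CodingDimension}}
#' @export
orthogonalize <- function(dim, nuisance) {
  w <- dim@weights; u <- nuisance@weights
  if (!identical(names(w), names(u))) stop("site sets differ")
  uh <- u / sqrt(sum(u^2))
  r <- w - sum(w * uh) * uh
  if (sqrt(sum(r^2)) < 1e-10 * sqrt(sum(w^2)))
    stop("dimension is parallel to the nuisance: zero vector after removal")
  new("CodingDimension", weights = .normalizeWeights(r, dim@normalization),
      normalization = dim@normalization, target_window = dim@target_window,
      reference_window = dim@reference_window, condition = dim@condition)
}

#' Project population activity onto a coding dimension
#'
#' Linear projection per time bin; the per-event projection window is
#' z-scored within \code{zscore_window} and baseline-subtracted over
#' \code{baseline_window} (both relative to onset). With
#' \code{zscore = "session"} the continuous projection is z-scored once
#' over the whole session instead of per event.
#'
#' @param activity a \code{\linkS4class{PopulationActivity}} containing at
#'   least the dimension's sites (a mismatch is an error, never a silent
#'   subset)
#' @param dim a \code{\linkS4class{CodingDimension}}
#' @param onsets event onsets (seconds)
#' @param window half-open peri-event window returned (seconds from onset)
#' @param zscore_window,baseline_window half-open windows for
#'   normalization
#' @param zscore \code{"per_event"} or \code{"session"}
#' @return list with \code{proj} (events x bins), \code{time_s}
#'   (relative to onset)
#' @export
projectActivity <- function(activity, dim, onsets, window = c(-0.5, 2),
                            zscore_window = c(-0.5, 1.5),
                            baseline_window = c(-0.5, 0),
                            zscore = c("per_event", "session", "none")) {
  zscore <- match.arg(zscore)
  R <- rates(activity)
  w <- dim@weights
  if (!all(names(w) %in% rownames(R)))
    stop("dimension sites missing from activity: ",
         paste(setdiff(names(w), rownames(R)), collapse = ", "))
  p <- as.vector(w %*% R[names(w), , drop = FALSE])
  t <- timeAxis(activity)
  if (zscore == "session") p <- (p - mean(p)) / sd(p)
  bw <- binWidth(activity)
  nb <- max(1L, floor((window[2] - window[1]) / bw))
  proj <- matrix(NA_real_, length(onsets), nb)
  rel_t <- window[1] + bw * (seq_len(nb) - 1)
  i0v <- .binAt(t, onsets + window[1])
  if (any(i0v < 1) || any(i0v + nb - 1 > length(p)))
    stop("an event window extends beyond the recording")
  for (e in seq_along(onsets)) {
    seg <- p[i0v[e]:(i0v[e] + nb - 1)]
    if (zscore == "per_event") {
      zi <- windowIdx(rel_t, zscore_window[1], zscore_window[2])
      s <- sd(seg[zi])
      seg <- (seg - mean(seg[zi])) / if (s > 0) s else 1
    }
    bi <- windowIdx(rel_t, baseline_window[1], baseline_window[2])
    proj[e, ] <- seg - mean(seg[bi])
  }
  list(proj = proj, time_s = rel_t)
}

#' Continuous projection onto a coding dimension
#'
#' @param activity a \code{\linkS4class{PopulationActivity}}
#' @param dim a \code{\linkS4class{CodingDimension}}
#' @return numeric series, one value per time bin
#' @export
projectContinuous <- function(activity, dim) {
  R <- rates(activity)
  w <- dim@weights
  if (!all(names(w) %in% rownames(R)))
    stop("dimension sites missing from activity")
  as.vector(w %*% R[names(w), , drop = FALSE])
}

#' Emotion-like neural dimension
#'
#' A coding dimension separating the post-series state (1 s window
#' starting 5 s after the last puff of each series) from the pre-series
#' baseline (750 ms window ending 250 ms before the first puff),
#' orthogonalized against a fast per-puff nuisance dimension built from
#' the saturation phase (the last 4 eligible trials; 200 ms after vs
#' 200 ms before each puff onset), and unit-normalized. Supply activity
#' restricted to puff-modulated sites.
#'
#' @param activity a \code{\linkS4class{PopulationActivity}}
#' @param schedule an \code{\linkS4class{EventSchedule}}
#' @param condition trials of this condition are used (default "pre")
#' @return list with \code{emotion} and \code{fast}
#'   \code{\linkS4class{CodingDimension}} objects
#' @export
emotionDimension <- function(activity, schedule, condition = "pre") {
  tt <- trialTable(schedule)
  tt <- tt[tt$condition == condition, , drop = FALSE]
  if (nrow(tt) < 2) stop("need at least 2 series in condition ", condition)
  post_on <- tt$last_onset
  pre_on <- tt$first_onset
  # raw emotion dimension: post-series vs pre-series windows
  Mt <- eventWindowMeans(activity, post_on, c(5, 6))
  Mr <- eventWindowMeans(activity, pre_on, c(-1, -0.25))
  mt <- colMeans(Mt); mr <- colMeans(Mr)
  pooled <- apply(Mt, 2, var) + apply(Mr, 2, var)
  w <- ifelse(pooled > 0, (mt - mr) / sqrt(pooled), 0)
  if (all(w == 0)) stop("degenerate emotion dimension")
  raw <- new("CodingDimension", weights = .normalizeWeights(w, "unit_norm"),
             normalization = "unit_norm", target_window = c(5, 6),
             reference_window = c(-1, -0.25), condition = condition)
  # fast nuisance from the saturation phase (last 4 series)
  ev <- events(schedule)
  last4 <- tail(sort(tt$trial), 4)
  puff_on <- ev$onset_s[ev$trial %in% last4]
  fast <- codingDimension(activity, puff_on, target = c(0, 0.2),
                          reference = c(-0.2, 0),
                          normalization = "unit_norm",
                          condition = condition)
  emo <- orthogonalize(raw, fast)
  list(emotion = emo, fast = fast)
}

#' Detectability (d') time series of event-aligned projections
#'
#' Per time bin, \code{d' = (mean_bin - mean_baseline) /
#' sqrt((var_bin + var_baseline) / 2)}, with means and variances across
#' events; the baseline statistics pool every (event, bin) sample of the
#' baseline window so that its variance is on the same per-bin scale as
#' the numerator's. Bins with zero pooled variance are flagged (NA).
#'
#' @param proj events x bins projection matrix
#' @param time_s bin times relative to onset
#' @param baseline half-open baseline window (seconds from onset)
#' @return list with \code{d_prime}, \code{time_s}, \code{flagged}
#' @export
dprimeTrace <- function(proj, time_s, baseline = c(-1, 0)) {
  stopifnot(nrow(proj) >= 2)
  bi <- windowIdx(time_s, baseline[1], baseline[2])
  if (length(bi) == 0) stop("baseline window empty")
  b <- c(proj[, bi, drop = FALSE])
  mb <- mean(b); vb <- var(b)
  m <- colMeans(proj); v <- apply(proj, 2, var)
  pooled <- (v + vb) / 2
  d <- ifelse(pooled > 0, (m - mb) / sqrt(pooled), NA_real_)
  list(d_prime = d, time_s = time_s, flagged = pooled == 0)
}
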