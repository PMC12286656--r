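# Eye-closure quantification: baseline normalization, early/late window
# summaries, and blink-masked per-condition affective traces for model
# fitting.

#' Normalize an eye trace to its pre-trial baseline
#'
#' Subtracts the mean closure over the baseline window and rescales by
#' \code{1 / (1 - reference_baseline)}, where the reference baseline is the
#' pre-trial closure averaged over the first two trials of the session
#' (when the eye should be fully open).
#'
#' @param trace an eye trace (list with \code{time_s}, \code{closure})
#' @param baseline_window half-open window (seconds, relative time) before
#'   the first event
#' @param reference_baseline scalar in [0, 1)
#' @return the trace with normalized \code{closure}
#' @export
normalizeTrace <- function(trace, baseline_window = c(-2, 0),
                           reference_baseline = 0) {
  if (reference_baseline >= 1)
    stop("reference_baseline >= 1: degenerate normalization")
  if (reference_baseline < 0) stop("reference_baseline must be >= 0")
  b <- windowMean(trace$closure, trace$time_s, baseline_window)
  trace$closure <- (trace$closure - b) / (1 - reference_baseline)
  trace
}

#' Early/late closure summary for one puff
#'
#' Means over half-open windows relative to the puff onset, and their
#' late/early ratio. The ratio is flagged undefined (NA with
#' \code{ratio_defined = FALSE}) when the early mean is not positive;
#' undefined ratios are excluded downstream rather than propagated.
#'
#' @param trace an eye trace
#' @param puff_onset onset (seconds, trace time)
#' @param early,late half-open windows (seconds after onset)
#' @return data.frame with \code{early_mean}, \code{late_mean},
#'   \code{late_over_early}, \code{ratio_defined}
#' @export
windowSummary <- function(trace, puff_onset, early = c(0.1, 0.2),
                          late = c(0.3, 0.8)) {
  em <- windowMean(trace$closure, trace$time_s, puff_onset + early)
  lm_ <- windowMean(trace$closure, trace$time_s, puff_onset + late)
  ok <- em > 0
  data.frame(early_mean = em, late_mean = lm_,
             late_over_early = if (ok) lm_ / em else NA_real_,
             ratio_defined = ok)
}

#' Per-trial closure summaries for a session
#'
#' Applies \code{\link{windowSummary}} to every puff of every trial and
#' averages within trial. The first trial is excluded by default.
#'
#' @param traces list of eye traces (as from \code{simulateEyeTraces})
#' @param early,late windows passed to \code{\link{windowSummary}}
#' @param drop_first drop the first trial of the session
#' @return data.frame with one row per trial: \code{trial},
#'   \code{condition}, \code{early}, \code{late}, \code{ratio},
#'   \code{n_undefined}
#' @export
closureSummary <- function(traces, early = c(0.1, 0.2), late = c(0.3, 0.8),
                           drop_first = TRUE) {
  rows <- lapply(traces, function(tr) {
    per <- do.call(rbind, lapply(tr$puff_onsets, function(on)
      windowSummary(tr, on, early, late)))
    data.frame(trial = tr$trial, condition = tr$condition,
               early = mean(per$early_mean), late = mean(per$late_mean),
               ratio = mean(per$late_over_early[per$ratio_defined]),
               n_undefined = sum(!per$ratio_defined))
  })
  out <- do.call(rbind, rows)
  if (drop_first) out <- out[out$trial != min(out$trial), , drop = FALSE]
  n_und <- sum(out$n_undefined)
  if (n_und > 0)
    message("closureSummary: ", n_und, " undefined late/early ratios dropped")
  rownames(out) <- NULL
  out
}

#' Blink-masked mean affective trace per condition
#'
#' Marks samples within \code{blink_mask} seconds after each puff onset as
#' missing, then averages the remaining samples across trials within each
#' condition. The result (with the reflexive blink removed) is the target
#' trace for fitting the two-phase model to behaviour.
#'
#' @param traces list of eye traces aligned to series start (first puff at
#'   t = 0), sharing one time axis and puff-onset template
#' @param blink_mask seconds masked after each puff onset
#' @return list per condition, each with \code{time_s}, \code{closure}
#'   (NA where masked), \code{n_trials}
#' @export
affectiveSeriesTrace <- function(traces, blink_mask = 0.75) {
  stopifnot(length(traces) >= 1)
  t <- traces[[1]]$time_s
  onsets <- traces[[1]]$puff_onsets
  mask <- rep(FALSE, length(t))
  if (blink_mask > 0)
    for (on in onsets) mask[windowIdx(t, on, on + blink_mask)] <- TRUE
  if (all(mask)) stop("blink mask covers every sample")
  conds <- unique(vapply(traces, function(x) x$condition, character(1)))
  out <- list()
  for (cn in conds) {
    sel <- Filter(function(x) x$condition == cn, traces)
    M <- do.call(rbind, lapply(sel, function(x) x$closure[seq_along(t)]))
    m <- colMeans(M)
    m[mask] <- NA
    out[[cn]] <- list(time_s = t, closure = m, n_trials = nrow(M),
                      puff_onsets = onsets)
  }
  out
}
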