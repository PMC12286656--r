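# Single-unit analyses: modulation screening, peri-puff response
# clustering, cluster-region composition, and regional d' rise/decay
# timing.

# replicate x bin matrix of a series cut around each onset
.periMatrix <- function(x, t, onsets, window, bw) {
  nb <- max(1L, floor((window[2] - window[1]) / bw))
  i0 <- .binAt(t, onsets + window[1])
  if (any(i0 < 1) || any(i0 + nb - 1 > length(x)))
    stop("peri-event window extends beyond the recording")
  idx <- outer(i0, 0:(nb - 1L), "+")
  M <- matrix(x[idx], nrow = length(onsets))
  list(M = M, time_s = window[1] + bw * (seq_len(nb) - 1))
}

# units x events matrix of window means, shared across units
.windowMeansAll <- function(R, t, onsets, window, bw) {
  nb <- max(1L, floor((window[2] - window[1]) / bw))
  i0 <- .binAt(t, onsets + window[1])
  if (any(i0 < 1) || any(i0 + nb - 1 > ncol(R)))
    stop("peri-event window extends beyond the recording")
  out <- matrix(NA_real_, nrow(R), length(onsets))
  for (e in seq_along(onsets))
    out[, e] <- rowMeans(R[, i0[e]:(i0[e] + nb - 1L), drop = FALSE])
  out
}

.pairedP <- function(a, b) {
  d <- b - a
  if (length(d) < 2 || sd(d) == 0) return(1)
  t.test(a, b, paired = TRUE)$p.value
}

#' Screen units for significant puff modulation
#'
#' Paired t-tests per unit over five window pairs: 1 s pre-puff against
#' 200 ms, 0.3-0.8 s, and 1-2 s post-puff (paired across puffs), plus the
#' 1 s before (and the 1 s after) the first versus last puff of each
#' series (paired across series). A unit is flagged when any uncorrected p
#' is below \code{alpha}.
#'
#' @param activity a \code{\linkS4class{PopulationActivity}}
#' @param schedule an \code{\linkS4class{EventSchedule}}
#' @param alpha per-test threshold
#' @return named logical vector, one per unit
#' @export
significantModulation <- function(activity, schedule, alpha = 0.01) {
  ev <- events(schedule)
  tt <- trialTable(schedule)
  if (nrow(tt) < 2) stop("need at least 2 series")
  t <- timeAxis(activity)
  bw <- binWidth(activity)
  R <- rates(activity)
  onsets <- ev$onset_s
  pairs <- list(
    list(.windowMeansAll(R, t, onsets, c(-1, 0), bw),
         .windowMeansAll(R, t, onsets, c(0, 0.2), bw)),
    list(.windowMeansAll(R, t, onsets, c(-1, 0), bw),
         .windowMeansAll(R, t, onsets, c(0.3, 0.8), bw)),
    list(.windowMeansAll(R, t, onsets, c(-1, 0), bw),
         .windowMeansAll(R, t, onsets, c(1, 2), bw)),
    list(.windowMeansAll(R, t, tt$first_onset, c(-1, 0), bw),
         .windowMeansAll(R, t, tt$last_onset, c(-1, 0), bw)),
    list(.windowMeansAll(R, t, tt$first_onset, c(0, 1), bw),
         .windowMeansAll(R, t, tt$last_onset, c(0, 1), bw)))
  vapply(seq_len(nrow(R)), function(u) {
    any(vapply(pairs, function(pr) .pairedP(pr[[1]][u, ], pr[[2]][u, ]),
               numeric(1)) < alpha)
  }, logical(1)) |> setNames(rownames(R))
}

#' Cluster mean peri-puff responses
#'
#' Averages each unit's peri-puff trace (default -1 to 2 s, baseline
#' subtracted over the 1 s pre-puff) across the selected puffs, z-scores
#' each unit across the window, reduces to principal components, and
#' applies agglomerative (Ward) clustering. The cluster count is chosen by
#' the mean silhouette over \code{k_grid} unless fixed; clusters are
#' ordered by the time for their mean response to decay to 25% of peak.
#'
#' @param activity a \code{\linkS4class{PopulationActivity}} restricted to
#'   modulated units
#' @param schedule an \code{\linkS4class{EventSchedule}}
#' @param condition puffs of this condition are averaged (NULL for all)
#' @param window peri-puff window, seconds
#' @param k fixed cluster count, or NULL for silhouette selection
#' @param k_grid candidate cluster counts
#' @param n_pcs number of principal components (capped by the data)
#' @return list with \code{labels} (named, ordered by decay time),
#'   \code{means} (cluster x bins, baseline-subtracted), \code{time_s},
#'   \code{k}, \code{decay_order_s}
#' @export
clusterResponses <- function(activity, schedule, condition = "pre",
                             window = c(-1, 2), k = NULL, k_grid = 2:8,
                             n_pcs = 20) {
  ev <- events(schedule)
  if (!is.null(condition)) ev <- ev[ev$condition == condition, , drop = FALSE]
  R <- rates(activity)
  if (nrow(R) < 10) stop("refusing to cluster fewer than 10 units")
  t <- timeAxis(activity)
  bw <- binWidth(activity)
  traces <- t(vapply(seq_len(nrow(R)), function(u) {
    pm <- .periMatrix(R[u, ], t, ev$onset_s, window, bw)
    m <- colMeans(pm$M)
    m - mean(m[windowIdx(pm$time_s, -1, 0)])
  }, numeric(max(1L, floor((window[2] - window[1]) / bw)))))
  time_s <- window[1] + bw * (seq_len(ncol(traces)) - 1)
  Z <- t(apply(traces, 1, function(x) {
    s <- sd(x); if (s > 0) (x - mean(x)) / s else x * 0
  }))
  if (all(apply(Z, 2, sd) == 0)) {
    labels <- setNames(rep(1L, nrow(R)), rownames(R))
    return(list(labels = labels, means = matrix(colMeans(traces), 1),
                time_s = time_s, k = 1L, decay_order_s = NA_real_))
  }
  npc <- min(n_pcs, nrow(Z) - 1, ncol(Z))
  pcs <- prcomp(Z, center = TRUE, scale. = FALSE)$x[, seq_len(npc),
                                                    drop = FALSE]
  hc <- hclust(dist(pcs), method = "ward.D2")
  if (is.null(k)) {
    k_grid <- k_grid[k_grid < nrow(Z)]
    d <- dist(pcs)
    sil <- vapply(k_grid, function(kk) {
      cl <- cutree(hc, kk)
      if (length(unique(cl)) < 2) return(-1)
      mean(silhouette(cl, d)[, "sil_width"])
    }, numeric(1))
    k <- k_grid[which.max(sil)]
  }
  lab <- cutree(hc, k)
  # order clusters by decay-to-25%-of-peak of cluster-mean activity
  decay <- vapply(seq_len(k), function(cl) {
    m <- colMeans(traces[lab == cl, , drop = FALSE])
    post <- which(time_s >= 0)
    pk <- post[which.max(abs(m[post]))]
    thr <- 0.25 * abs(m[pk])
    after <- which(abs(m) <= thr & seq_along(m) > pk)
    if (length(after)) time_s[after[1]] else max(time_s)
  }, numeric(1))
  ord <- order(decay)
  relab <- match(lab, ord)
  means <- do.call(rbind, lapply(ord, function(cl)
    colMeans(traces[lab == cl, , drop = FALSE])))
  list(labels = setNames(relab, rownames(R)), means = means,
       time_s = time_s, k = k, decay_order_s = decay[ord])
}

#' Regional cluster composition test
#'
#' Fraction of each region's units in each cluster, with a binomial test
#' against the equal-probability categorical null and BH correction.
#'
#' @param labels named integer cluster labels
#' @param regions named region labels over the same units
#' @param alpha threshold on the corrected p
#' @return data.frame: \code{region}, \code{cluster}, \code{n}, \code{n_region},
#'   \code{fraction}, \code{p}, \code{p_corrected}, \code{flagged}
#' @export
clusterRegionComposition <- function(labels, regions, alpha = 0.05) {
  stopifnot(length(labels) == length(regions))
  k <- length(unique(labels))
  tab <- table(regions, labels)
  rows <- list()
  for (r in rownames(tab)) for (cl in colnames(tab)) {
    n_r <- sum(tab[r, ])
    x <- tab[r, cl]
    p <- if (k < 2) 1 else binom.test(x, n_r, p = 1 / k)$p.value
    rows[[length(rows) + 1]] <- data.frame(
      region = r, cluster = as.integer(cl), n = as.integer(x),
      n_region = n_r, fraction = x / n_r, p = p)
  }
  out <- do.call(rbind, rows)
  out$p_corrected <- p.adjust(out$p, method = "BH")
  out$flagged <- k >= 2 & out$p_corrected < alpha
  out
}

# d' trace with combined (summed-variance) standard deviation, matching
# the coding-dimension weight convention
.dprimeSumVar <- function(M, time_s, baseline = c(-1, 0)) {
  b <- rowMeans(M[, windowIdx(time_s, baseline[1], baseline[2]),
                  drop = FALSE])
  mb <- mean(b); vb <- var(b)
  m <- colMeans(M); v <- apply(M, 2, var)
  pooled <- v + vb
  ifelse(pooled > 0, (m - mb) / sqrt(pooled), NA_real_)
}

#' Rise and decay times of a d' trace
#'
#' The rise time is the first post-onset time the trace reaches
#' \code{threshold_frac} of its post-onset peak; the decay time is the
#' first time after the peak it falls back to that fraction. Traces whose
#' peak d' is below \code{min_peak_dprime}, or whose peak occurs later
#' than \code{max_peak_latency}, are excluded (noise-peak and
#' spurious-peak guards).
#'
#' @param d d' values per time bin
#' @param time_s bin times relative to onset (seconds)
#' @param threshold_frac fraction of peak defining rise/decay
#' @param min_peak_dprime exclusion floor on the peak
#' @param max_peak_latency exclusion ceiling on peak time (seconds)
#' @return list with \code{rise}, \code{decay} (NA when the trace never
#'   recrosses the threshold), \code{peak}, \code{peak_t},
#'   \code{excluded}
#' @export
riseDecayFromDprime <- function(d, time_s, threshold_frac = 0.25,
                                min_peak_dprime = 1.3,
                                max_peak_latency = 0.75) {
  post <- which(time_s > 0)
  pk <- post[which.max(d[post])]
  peak <- d[pk]
  if (!is.finite(peak) || peak < min_peak_dprime ||
      time_s[pk] > max_peak_latency)
    return(list(rise = NA_real_, decay = NA_real_, peak = peak,
                peak_t = time_s[pk], excluded = TRUE))
  thr <- threshold_frac * peak
  ri <- post[which(d[post] >= thr)[1]]
  after <- which(d <= thr & seq_along(d) > pk)
  list(rise = time_s[ri],
       decay = if (length(after)) time_s[after[1]] else NA_real_,
       peak = peak, peak_t = time_s[pk], excluded = FALSE)
}

#' Regional rise and decay times
#'
#' For each cluster within each region, averages rates across member
#' units, forms per-puff replicate traces from the first two puffs of each
#' series, converts to a d' time series against the 1 s pre-puff baseline
#' (combined standard deviation = sqrt of summed variances), and measures
#' the time to rise to \code{threshold_frac} of the post-onset peak and to
#' decay back to that fraction after the peak. Clusters with peak d' below
#' \code{min_peak_dprime} or peak latency above \code{max_peak_latency}
#' are excluded. Regional values are cluster-fraction-weighted averages;
#' confidence intervals are bootstrapped over puff replicates.
#'
#' @param activity a \code{\linkS4class{PopulationActivity}}
#' @param schedule an \code{\linkS4class{EventSchedule}}
#' @param labels named cluster labels for the activity's units
#' @param condition series of this condition are used (NULL for all)
#' @param threshold_frac rise/decay threshold as a fraction of peak
#' @param min_peak_dprime exclusion floor on peak d'
#' @param max_peak_latency exclusion ceiling on peak time, seconds
#' @param n_boot bootstrap resamples (0 to skip)
#' @param window peri-puff window, seconds
#' @param seed seed for the bootstrap resamples
#' @return data.frame per region: \code{region}, \code{rise_s},
#'   \code{decay_s}, bootstrap CI bounds, \code{n_units},
#'   \code{n_clusters_used}
#' @export
riseDecayTimes <- function(activity, schedule, labels, condition = NULL,
                           threshold_frac = 0.25, min_peak_dprime = 1.3,
                           max_peak_latency = 0.75, n_boot = 200,
                           window = c(-1, 2), seed = 1L) {
  set.seed(substreamSeed(seed, "boot"))
  ev <- events(schedule)
  if (!is.null(condition)) ev <- ev[ev$condition == condition, , drop = FALSE]
  onsets <- ev$onset_s[ev$puff_index < 2]   # first two puffs per series
  t <- timeAxis(activity)
  bw <- binWidth(activity)
  R <- rates(activity)
  regions <- rowData(activity)$region
  stopifnot(!is.null(regions), all(rownames(R) %in% names(labels)))
  labels <- labels[rownames(R)]

  riseDecay <- function(d, time_s) {
    out <- riseDecayFromDprime(d, time_s, threshold_frac, min_peak_dprime,
                               max_peak_latency)
    if (out$excluded) NULL else out
  }

  out <- list()
  for (r in unique(regions)) {
    ur <- which(regions == r)
    cls <- sort(unique(labels[ur]))
    per <- list(); wts <- c()
    reps <- list()
    for (cl in cls) {
      uu <- ur[labels[ur] == cl]
      x <- colMeans(R[uu, , drop = FALSE])
      pm <- .periMatrix(x, t, onsets, window, bw)
      d <- .dprimeSumVar(pm$M, pm$time_s)
      rd <- riseDecay(d, pm$time_s)
      if (is.null(rd)) next
      per[[length(per) + 1]] <- rd
      wts <- c(wts, length(uu))
      reps[[length(reps) + 1]] <- pm
    }
    if (length(per) == 0) next
    wts <- wts / sum(wts)
    rise <- sum(wts * vapply(per, `[[`, numeric(1), "rise"))
    decs <- vapply(per, `[[`, numeric(1), "decay")
    decay <- if (any(is.na(decs))) NA_real_ else sum(wts * decs)
    ci <- matrix(NA_real_, 2, 2)
    if (n_boot > 0) {
      br <- matrix(NA_real_, n_boot, 2)
      for (b in seq_len(n_boot)) {
        rr <- c(); dd <- c(); ok <- TRUE
        for (ci_ in seq_along(reps)) {
          pm <- reps[[ci_]]
          idx <- sample(nrow(pm$M), replace = TRUE)
          d <- .dprimeSumVar(pm$M[idx, , drop = FALSE], pm$time_s)
          rd <- riseDecay(d, pm$time_s)
          if (is.null(rd) || is.na(rd$decay)) { ok <- FALSE; break }
          rr <- c(rr, rd$rise); dd <- c(dd, rd$decay)
        }
        if (ok) br[b, ] <- c(sum(wts * rr), sum(wts * dd))
      }
      br <- br[stats::complete.cases(br), , drop = FALSE]
      if (nrow(br) >= 10)
        ci <- apply(br, 2, quantile, c(0.025, 0.975))
    }
    out[[length(out) + 1]] <- data.frame(
      region = r, rise_s = rise, decay_s = decay,
      rise_lo = ci[1, 1], rise_hi = ci[2, 1],
      decay_lo = ci[1, 2], decay_hi = ci[2, 2],
      n_units = length(ur), n_clusters_used = length(per))
  }
  if (length(out) == 0)
    return(data.frame(region = character(0), rise_s = numeric(0),
                      decay_s = numeric(0)))
  do.call(rbind, out)
}
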