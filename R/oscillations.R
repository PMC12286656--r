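# Detection of band-limited oscillations over a 1/f background: aperiodic
# removal, peak extraction, clustering of peaks across time segments,
# drug-unique flagging, and the dissociation-score fraction permutation
# test.

# iterative masked aperiodic (power-law) fit in log-log space:
# line fit -> mask points > mask_sd SD above the fit -> refit, n_iter times
.aperiodicFit <- function(log_f, log_p, n_iter = 3, mask_sd = 2.5) {
  keep <- rep(TRUE, length(log_f))
  fit <- NULL
  for (i in seq_len(n_iter)) {
    fit <- lm(log_p[keep] ~ log_f[keep])
    pred <- fit$coefficients[1] + fit$coefficients[2] * log_f
    r <- log_p - pred
    s <- sd(r[keep])
    if (!is.finite(s) || s == 0) break
    keep <- r <= mask_sd * s
    if (sum(keep) < 4) stop("aperiodic fit diverged: too few points left")
  }
  pred
}

#' Aperiodic-removed log power spectra per segment
#'
#' Splits the signal into segments, estimates each segment's PSD by
#' averaging multitaper windows (defaults: time-half-bandwidth 30, 59
#' tapers, 30 s windows, 15 s stride), and subtracts an iteratively
#' refitted power-law aperiodic component in log-log space (line fit,
#' masking points more than 2.5 SD above the fit, three iterations).
#'
#' @param x numeric signal
#' @param fs sampling rate, Hz
#' @param segment_s segment length, seconds
#' @param tbw time-half-bandwidth of the multitaper estimate
#' @param window,stride multitaper window and stride, seconds
#' @param freq_range frequency range analysed, Hz
#' @return list of class \code{FlattenedPsd}: \code{flat} (segments x
#'   freq, log10 power above the aperiodic fit), \code{freq_hz},
#'   \code{n_segments}
#' @export
aperiodicRemovedPsd <- function(x, fs, segment_s = 180, tbw = 30,
                                window = 30, stride = 15,
                                freq_range = c(2, 80)) {
  nseg <- floor(length(x) / (segment_s * fs))
  if (nseg < 1) stop("signal shorter than one segment")
  flat <- NULL
  for (s in seq_len(nseg)) {
    seg <- x[((s - 1) * segment_s * fs + 1):(s * segment_s * fs)]
    sp <- multitaperSpectrogram(seg, fs, time_bandwidth = tbw,
                                window = window, stride = stride,
                                freq_range = freq_range)
    psd <- colMeans(sp$power)
    lf <- log10(sp$freq_hz); lp <- log10(pmax(psd, .Machine$double.xmin))
    pred <- .aperiodicFit(lf, lp)
    flat <- rbind(flat, lp - pred)
  }
  structure(list(flat = flat, freq_hz = sp$freq_hz, n_segments = nseg),
            class = "FlattenedPsd")
}

# local maxima with topographic prominence and width at half prominence
.findSpectralPeaks <- function(freq, y, min_prominence = 0.15) {
  n <- length(y)
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  out <- list()
  for (p in peaks) {
    # prominence: drop to the lowest point before re-reaching the peak
    # height on each side (standard topographic definition)
    i <- p; lbase <- y[p]
    while (i > 1 && y[i - 1] <= y[p]) { i <- i - 1; lbase <- min(lbase, y[i]) }
    i <- p; rbase <- y[p]
    while (i < n && y[i + 1] <= y[p]) { i <- i + 1; rbase <- min(rbase, y[i]) }
    prom <- y[p] - max(lbase, rbase)
    if (prom < min_prominence) next
    half <- y[p] - prom / 2
    li <- p; while (li > 1 && y[li - 1] > half) li <- li - 1
    ri <- p; while (ri < n && y[ri + 1] > half) ri <- ri + 1
    bw <- freq[ri] - freq[li]
    # center = midpoint of the half-prominence interval (robust to the
    # flat-topped footprint of the multitaper estimate)
    out[[length(out) + 1]] <- data.frame(
      center_hz = (freq[li] + freq[ri]) / 2,
      bw_hz = max(bw, freq[2] - freq[1]),
      height = y[p], prominence = prom)
  }
  if (length(out) == 0)
    return(data.frame(center_hz = numeric(0), bw_hz = numeric(0),
                      height = numeric(0), prominence = numeric(0)))
  do.call(rbind, out)
}

#' Detect and cluster spectral peaks across segments
#'
#' Finds local maxima with a prominence floor in each segment's flattened
#' spectrum, then greedily clusters peaks across segments when their
#' frequency-width intervals (center +/- half bandwidth) overlap by at
#' least \code{overlap_frac} of the smaller interval. Clusters present in
#' fewer than \code{presence_frac} of segments are discarded.
#'
#' @param fpsd a \code{FlattenedPsd}
#' @param overlap_frac minimum interval-overlap fraction for joining
#' @param presence_frac minimum fraction of segments a cluster must
#'   appear in
#' @param min_prominence peak prominence floor (log10-power units)
#' @return data.frame, one row per surviving cluster: \code{center_hz},
#'   \code{bw_hz}, \code{mean_height}, \code{presence}, plus the
#'   per-segment heights in \code{attr(, "heights")}
#' @export
detectAndClusterPeaks <- function(fpsd, overlap_frac = 0.8,
                                  presence_frac = 0.4,
                                  min_prominence = 0.15) {
  nseg <- fpsd$n_segments
  clusters <- list()
  ovl <- function(a1, a2, b1, b2) {
    inter <- max(0, min(a2, b2) - max(a1, b1))
    inter / min(a2 - a1, b2 - b1)
  }
  for (s in seq_len(nseg)) {
    pk <- .findSpectralPeaks(fpsd$freq_hz, fpsd$flat[s, ], min_prominence)
    for (i in seq_len(nrow(pk))) {
      a1 <- pk$center_hz[i] - pk$bw_hz[i] / 2
      a2 <- pk$center_hz[i] + pk$bw_hz[i] / 2
      best <- 0; bi <- 0
      for (j in seq_along(clusters)) {
        cl <- clusters[[j]]
        o <- ovl(a1, a2, cl$center - cl$bw / 2, cl$center + cl$bw / 2)
        if (o > best) { best <- o; bi <- j }
      }
      if (best >= overlap_frac) {
        cl <- clusters[[bi]]
        cl$heights <- c(cl$heights, pk$height[i])
        cl$segments <- union(cl$segments, s)
        cl$center <- mean(c(cl$center, pk$center_hz[i]))
        cl$bw <- mean(c(cl$bw, pk$bw_hz[i]))
        clusters[[bi]] <- cl
      } else {
        clusters[[length(clusters) + 1]] <-
          list(center = pk$center_hz[i], bw = pk$bw_hz[i],
               heights = pk$height[i], segments = s)
      }
    }
  }
  keep <- vapply(clusters, function(cl)
    length(cl$segments) / nseg >= presence_frac, logical(1))
  clusters <- clusters[keep]
  out <- data.frame(
    center_hz = vapply(clusters, `[[`, numeric(1), "center"),
    bw_hz = vapply(clusters, `[[`, numeric(1), "bw"),
    mean_height = vapply(clusters, function(cl) mean(cl$heights),
                         numeric(1)),
    presence = vapply(clusters, function(cl)
      length(cl$segments) / nseg, numeric(1)))
  attr(out, "heights") <- lapply(clusters, `[[`, "heights")
  out
}

#' Flag oscillations unique to the drug window
#'
#' A drug-window peak cluster overlapping a baseline cluster in frequency
#' (within \code{freq_tol}) is flagged \code{"amplified"} only when a
#' one-sided rank-sum test on the height distributions across segments is
#' significant at \code{alpha}; a drug cluster with no baseline match is
#' flagged \code{"new_frequency"}.
#'
#' @param baseline,drug cluster tables from
#'   \code{\link{detectAndClusterPeaks}} (baseline = pre- and
#'   post-infusion pooled)
#' @param freq_tol matching tolerance, Hz
#' @param alpha one-sided rank-sum alpha
#' @return the drug table with added \code{flag}
#'   (\code{"amplified"}, \code{"new_frequency"}, or \code{"none"}) and
#'   \code{p}
#' @export
drugUniquePeaks <- function(baseline, drug, freq_tol = 2, alpha = 0.001) {
  hb <- attr(baseline, "heights"); hd <- attr(drug, "heights")
  flag <- character(nrow(drug)); p <- rep(NA_real_, nrow(drug))
  for (i in seq_len(nrow(drug))) {
    if (nrow(baseline)) {
      dmin <- abs(baseline$center_hz - drug$center_hz[i])
      j <- which.min(dmin)
    } else dmin <- Inf
    if (length(dmin) && min(dmin) <= freq_tol) {
      p[i] <- suppressWarnings(
        wilcox.test(hd[[i]], hb[[j]], alternative = "greater")$p.value)
      flag[i] <- if (is.finite(p[i]) && p[i] < alpha) "amplified" else "none"
    } else flag[i] <- "new_frequency"
  }
  drug$flag <- flag
  drug$p <- p
  drug
}

#' Oscillating-channel fraction permutation test across participants
#'
#' Compares the pooled fraction of oscillating channels between
#' participant groups (e.g. high versus low dissociation score) against a
#' null built by shuffling the group labels across participants without
#' replacement; one-sided p for the high group exceeding the low group.
#'
#' @param counts per-participant number of oscillating channels
#' @param totals per-participant total channels
#' @param group per-participant labels, \code{"high"} or \code{"low"}
#' @param n_perm number of label shuffles
#' @param seed integer seed
#' @return list with \code{delta} (observed fraction difference),
#'   \code{p}, \code{fraction_high}, \code{fraction_low}
#' @export
cadssFractionPermutation <- function(counts, totals, group, n_perm = 2000,
                                     seed = 1L) {
  stopifnot(length(counts) == length(totals),
            length(group) == length(counts))
  if (length(unique(group)) < 2 || min(table(group)) < 2)
    stop("need at least 2 participants per group")
  frac <- function(g) {
    c(high = sum(counts[g == "high"]) / sum(totals[g == "high"]),
      low = sum(counts[g == "low"]) / sum(totals[g == "low"]))
  }
  f <- frac(group)
  delta <- f["high"] - f["low"]
  set.seed(substreamSeed(seed, "perm"))
  null <- replicate(n_perm, {
    g <- sample(group)
    fr <- frac(g)
    fr["high"] - fr["low"]
  })
  p <- (1 + sum(null >= delta)) / (1 + n_perm)
  list(delta = unname(delta), p = p, fraction_high = unname(f["high"]),
       fraction_low = unname(f["low"]))
}
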