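# Two-phase first-order model of affective state: a saturating "broadcast"
# rise during stimulus input, and slow exponential "persistence" decay
# between inputs. Both phases have exact closed forms, so simulation is
# evaluated analytically per phase with no integration error.

#' Standard puff-series input schedule
#'
#' Eight 250 ms step inputs separated by 3 s (onset to onset), followed by a
#' long input-free tail.
#'
#' @param n_puffs number of step inputs
#' @param on input (puff) duration, seconds
#' @param period onset-to-onset interval, seconds
#' @param tail_s input-free tail after the last input offset, seconds
#' @return list with \code{onsets}, \code{durations}, \code{t_end}
#' @export
puffSeriesSchedule <- function(n_puffs = 8, on = 0.25, period = 3.0,
                               tail_s = 50) {
  onsets <- (seq_len(n_puffs) - 1) * period
  list(onsets = onsets, durations = rep(on, n_puffs),
       t_end = onsets[n_puffs] + on + tail_s)
}

#' Simulate the two-phase model
#'
#' During input the state relaxes toward the saturation value:
#' \code{x(t) = (S - x0)^+ (1 - exp(-t/tau_broadcast)) + x0}; with no input
#' it decays: \code{x(t) = x0 exp(-t/tau_persist)}; \code{x0} is the state
#' at the start of each phase and \code{t} runs from the phase start. The
#' closed forms are evaluated exactly on the requested grid.
#'
#' @param params a \code{\linkS4class{BiphasicParams}}
#' @param condition which entry of \code{tau_persist} to use
#' @param onsets input onset times (seconds); must not overlap
#' @param durations input durations (seconds, recycled)
#' @param t time grid (seconds) at which to evaluate; defaults to
#'   \code{seq(0, t_end, by = dt)}
#' @param dt grid step when \code{t} is not given
#' @param t_end grid end when \code{t} is not given
#' @param x0 initial state
#' @return list of class \code{ModelTrace}: \code{time_s}, \code{x},
#'   \code{onsets}, \code{durations}, \code{condition}
#' @examples
#' p <- biphasicParams(S = 1, tau_broadcast = 0.1, tau_persist = c(pre = 10))
#' tr <- simulateBiphasic(p, "pre", onsets = 0, durations = 0.25, dt = 0.005,
#'                        t_end = 15)
#' tr$x[which.min(abs(tr$time_s - 0.25))]  # 1 - exp(-2.5)
#' @export
simulateBiphasic <- function(params, condition, onsets, durations = 0.25,
                             t = NULL, dt = 0.01, t_end = NULL, x0 = 0) {
  stopifnot(is(params, "BiphasicParams"))
  if (!condition %in% names(params@tau_persist))
    stop("no tau_persist entry for condition '", condition, "'")
  durations <- rep_len(durations, length(onsets))
  if (length(onsets) > 1) {
    o <- order(onsets)
    onsets <- onsets[o]; durations <- durations[o]
    if (any(onsets[-1] < onsets[-length(onsets)] + durations[-length(onsets)]))
      stop("input intervals overlap")
  }
  if (is.null(t)) {
    if (is.null(t_end)) t_end <- max(onsets + durations) + 5
    t <- seq(0, t_end, by = dt)
  }
  S <- params@S
  tb <- params@tau_broadcast
  tp <- params@tau_persist[[condition]]

  # phase boundaries: alternate off/on segments covering [t[1], Inf)
  starts <- c(); kinds <- c()
  cur <- min(t[1], onsets[1])
  for (i in seq_along(onsets)) {
    if (onsets[i] > cur) { starts <- c(starts, cur); kinds <- c(kinds, "off") }
    starts <- c(starts, onsets[i]); kinds <- c(kinds, "on")
    cur <- onsets[i] + durations[i]
  }
  starts <- c(starts, cur); kinds <- c(kinds, "off")
  ends <- c(starts[-1], Inf)

  x <- numeric(length(t))
  xph <- x0
  for (ph in seq_along(starts)) {
    idx <- which(t >= starts[ph] & t < ends[ph])
    tt <- t[idx] - starts[ph]
    if (kinds[ph] == "on") {
      if (length(idx)) x[idx] <- max(0, S - xph) * (1 - exp(-tt / tb)) + xph
      span <- ends[ph] - starts[ph]
      xph <- max(0, S - xph) * (1 - exp(-span / tb)) + xph
    } else {
      if (length(idx)) x[idx] <- xph * exp(-tt / tp)
      span <- ends[ph] - starts[ph]
      xph <- if (is.finite(span)) xph * exp(-span / tp) else 0
    }
  }
  structure(list(time_s = t, x = x, onsets = onsets, durations = durations,
                 condition = condition),
            class = "ModelTrace")
}

#' @export
print.ModelTrace <- function(x, ...) {
  cat(sprintf("ModelTrace (%s): %d samples, %d inputs, max x = %.4g\n",
              x$condition, length(x$x), length(x$onsets), max(x$x)))
  invisible(x)
}

# internal: residuals of a candidate parameter vector against all condition
# traces; masked (NA) samples dropped.
.biphasicResiduals <- function(theta, free, conds, traces, time_s, onsets,
                               durations) {
  k <- length(conds)
  par <- .unpackTheta(theta, free, conds)
  res <- c()
  for (i in seq_len(k)) {
    cn <- conds[i]
    p <- biphasicParams(S = par$S[i], tau_broadcast = par$tau_b[i],
                        tau_persist = setNames(par$tau_p[i], cn))
    tr <- simulateBiphasic(p, cn, onsets, durations, t = time_s)
    d <- traces[[cn]] - tr$x
    res <- c(res, d[!is.na(d)])
  }
  res
}

.unpackTheta <- function(theta, free, conds) {
  k <- length(conds)
  switch(free,
    tau_persist = list(S = rep(theta[1], k), tau_b = rep(theta[2], k),
                       tau_p = theta[2 + seq_len(k)]),
    S = list(S = theta[seq_len(k)], tau_b = rep(theta[k + 1], k),
             tau_p = rep(theta[k + 2], k)),
    tau_broadcast = list(S = rep(theta[1], k),
                         tau_b = theta[1 + seq_len(k)],
                         tau_p = rep(theta[k + 2], k)),
    none = list(S = rep(theta[1], k), tau_b = rep(theta[2], k),
                tau_p = rep(theta[3], k)),
    single_phase = list(S = rep(theta[1], k),
                        tau_b = theta[1 + seq_len(k)],
                        tau_p = theta[1 + seq_len(k)]))
}

.thetaLength <- function(free, k) {
  switch(free, tau_persist = 2 + k, S = k + 2, tau_broadcast = k + 2,
         none = 3, single_phase = 1 + k)
}

#' Fit the two-phase model to per-condition traces
#'
#' Bounded least squares over the concatenation of all condition traces
#' against the concatenated model output. One parameter set may vary freely
#' per condition while the rest are shared; the default frees
#' \code{tau_persist} with \code{S} and \code{tau_broadcast} shared.
#' Masked samples (NA) are excluded from the residual. The nonconvex
#' surface is guarded by multi-start from a log-spaced grid; the best
#' residual wins.
#'
#' @param traces named list (by condition) of numeric target traces on a
#'   common grid; NA marks masked samples
#' @param time_s common time grid (seconds)
#' @param onsets,durations shared input schedule
#' @param free one of \code{"tau_persist"}, \code{"S"},
#'   \code{"tau_broadcast"}, \code{"none"} (nothing varies),
#'   \code{"single_phase"} (rise and decay constants tied, per condition)
#' @param bounds two-element numeric, per-parameter box constraints
#' @param n_starts number of multi-start initializations
#' @param seed seed for start-point jitter
#' @return list of class \code{biphasicFit}: per-condition \code{S},
#'   \code{tau_broadcast}, \code{tau_persist}, \code{ssr}, \code{fitted}
#'   (list per condition), \code{at_bound}, \code{converged}, \code{free}
#' @export
fitBiphasic <- function(traces, time_s, onsets, durations = 0.25,
                        free = "tau_persist", bounds = c(0, 100),
                        n_starts = 10, seed = 1) {
  free <- match.arg(free, c("tau_persist", "S", "tau_broadcast", "none",
                            "single_phase"))
  conds <- names(traces)
  stopifnot(length(conds) >= 1, !is.null(conds))
  k <- length(conds)
  np <- .thetaLength(free, k)
  ndat <- sum(vapply(traces, function(x) sum(!is.na(x)), integer(1)))
  if (ndat <= np) stop("fewer data points than parameters")
  durations <- rep_len(durations, length(onsets))

  lo <- rep(max(bounds[1], 1e-4), np)
  hi <- rep(bounds[2], np)
  if (free %in% c("tau_persist", "none", "tau_broadcast")) lo[1] <- bounds[1]
  if (free %in% c("S", "single_phase")) {
    sidx <- if (free == "S") seq_len(k) else 1
    lo[sidx] <- bounds[1]
  }

  amp <- max(abs(unlist(traces)), na.rm = TRUE)
  s_grid <- pmin(pmax(amp * c(0.5, 1, 2), 1e-3), bounds[2])
  tb_grid <- c(0.03, 0.1, 0.3, 1)
  tp_grid <- c(0.3, 1, 3, 10, 30)
  set.seed(substreamSeed(seed, "misc"))
  starts <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    S0 <- s_grid[1 + (s - 1) %% length(s_grid)]
    tb0 <- tb_grid[1 + (s - 1) %% length(tb_grid)]
    tp0 <- tp_grid[1 + ((s - 1) %/% 2) %% length(tp_grid)]
    jit <- if (s > 1) exp(rnorm(np, 0, 0.25)) else rep(1, np)
    th0 <- switch(free,
      tau_persist = c(S0, tb0, rep(tp0, k)),
      S = c(rep(S0, k), tb0, tp0),
      tau_broadcast = c(S0, rep(tb0, k), tp0),
      none = c(S0, tb0, tp0),
      single_phase = c(S0, rep(sqrt(tb0 * tp0), k)))
    starts[[s]] <- pmin(pmax(th0 * jit, lo + 1e-9), hi - 1e-9)
  }

  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      nls.lm(par = th0, lower = lo, upper = hi,
             fn = .biphasicResiduals, free = free, conds = conds,
             traces = traces, time_s = time_s, onsets = onsets,
             durations = durations,
             control = nls.lm.control(maxiter = 200, ftol = 1e-12,
                                      ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) stop("all optimizer starts failed")

  th <- best$fit$par
  par <- .unpackTheta(th, free, conds)
  fitted <- list()
  for (i in seq_len(k)) {
    cn <- conds[i]
    p <- biphasicParams(S = par$S[i], tau_broadcast = par$tau_b[i],
                        tau_persist = setNames(par$tau_p[i], cn))
    fitted[[cn]] <- simulateBiphasic(p, cn, onsets, durations, t = time_s)$x
  }
  at_bound <- any(th - lo < 1e-6 * pmax(1, hi - lo)) ||
    any(hi - th < 1e-6 * pmax(1, hi - lo))
  structure(list(
    S = setNames(par$S, conds),
    tau_broadcast = setNames(par$tau_b, conds),
    tau_persist = setNames(par$tau_p, conds),
    free = free, ssr = best$ssr, fitted = fitted,
    at_bound = at_bound, converged = best$fit$info %in% 1:4,
    n_obs = ndat), class = "biphasicFit")
}

#' @export
print.biphasicFit <- function(x, ...) {
  cat(sprintf("biphasicFit (free: %s), SSR = %.4g on %d points%s\n",
              x$free, x$ssr, x$n_obs,
              if (x$at_bound) " [parameter at bound]" else ""))
  for (cn in names(x$S))
    cat(sprintf("  %s: S = %.4g, tau_b = %.4g s, tau_p = %.4g s\n",
                cn, x$S[cn], x$tau_broadcast[cn], x$tau_persist[cn]))
  invisible(x)
}

#' Variance explained by the condition-varying parameter
#'
#' \code{1 - MSE_model / MSE_null}, where the null fit shares every
#' parameter across conditions. Both fits must have been obtained on the
#' same traces with the same masked support. Can be negative when the free
#' parameter does not help.
#'
#' @param traces the per-condition target traces the fits were trained on
#' @param full_fit a \code{biphasicFit} with a free parameter
#' @param null_fit a \code{biphasicFit} with \code{free = "none"}
#' @return scalar fraction
#' @export
varianceExplained <- function(traces, full_fit, null_fit) {
  mse <- function(fit) {
    num <- 0; nn <- 0
    for (cn in names(traces)) {
      d <- traces[[cn]] - fit$fitted[[cn]]
      d <- d[!is.na(d)]
      num <- num + sum(d^2); nn <- nn + length(d)
    }
    num / nn
  }
  m0 <- mse(null_fit)
  if (m0 == 0) stop("null model fits the data exactly; EV undefined")
  1 - mse(full_fit) / m0
}
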