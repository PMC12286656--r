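#' @include affectdyn-package.R
NULL

# ---------------------------------------------------------------------------
# EventSchedule
# ---------------------------------------------------------------------------

#' Stimulus event schedule
#'
#' Holds the onsets and durations of air-puff events, grouped into series
#' (trials) and labelled with an experimental condition (e.g. "pre", "drug",
#' "post"). Onsets are in seconds on the session clock and must be strictly
#' increasing.
#'
#' @slot events data.frame with columns \code{onset_s}, \code{duration_s},
#'   \code{trial} (0-based series index), \code{puff_index} (0-based index
#'   within the series) and \code{condition}.
#' @exportClass EventSchedule
setClass("EventSchedule", representation(events = "data.frame"))

setValidity("EventSchedule", function(object) {
  ev <- object@events
  need <- c("onset_s", "duration_s", "trial", "puff_index", "condition")
  if (!all(need %in% names(ev)))
    return(paste("events must have columns:", paste(need, collapse = ", ")))
  if (nrow(ev) == 0) return("schedule has no events")
  if (any(!is.finite(ev$onset_s))) return("non-finite onsets")
  if (any(diff(ev$onset_s) <= 0)) return("onsets must be strictly increasing")
  if (any(ev$duration_s <= 0)) return("durations must be positive")
  TRUE
})

#' @describeIn EventSchedule-class event table accessor
#' @param x an \code{EventSchedule}
#' @export
events <- function(x) {
  stopifnot(is(x, "EventSchedule"))
  x@events
}

#' Number of series (trials) in a schedule
#' @param x an \code{EventSchedule}
#' @export
nTrials <- function(x) length(unique(events(x)$trial))

#' Per-trial summary of a schedule
#'
#' One row per series: trial index, condition, first and last puff onset.
#' @param x an \code{EventSchedule}
#' @return data.frame with columns \code{trial}, \code{condition},
#'   \code{first_onset}, \code{last_onset}, \code{n_puffs}
#' @export
trialTable <- function(x) {
  ev <- events(x)
  sp <- split(ev, ev$trial)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    trial = d$trial[1], condition = d$condition[1],
    first_onset = min(d$onset_s), last_onset = max(d$onset_s),
    n_puffs = nrow(d))))
  out <- out[order(out$trial), , drop = FALSE]
  rownames(out) <- NULL
  out
}

setMethod("show", "EventSchedule", function(object) {
  ev <- object@events
  cat("EventSchedule:", nrow(ev), "events in", length(unique(ev$trial)),
      "series\n  conditions:",
      paste(sprintf("%s (%d)", names(table(ev$condition)),
                    as.integer(table(ev$condition))), collapse = ", "),
      "\n  span:", sprintf("%.1f-%.1f s", min(ev$onset_s), max(ev$onset_s)),
      "\n")
})

# ---------------------------------------------------------------------------
# PopulationActivity
# ---------------------------------------------------------------------------

#' Population activity container
#'
#' Sites (units or channels) by time-bin matrix of firing rates or band
#' power, stored as a \code{SummarizedExperiment}: rows are sites with their
#' metadata (region, archetype when known), columns are time bins with the
#' time axis in \code{colData()$time_s}; the bin width is kept in
#' \code{metadata()$bin_width}.
#'
#' @exportClass PopulationActivity
setClass("PopulationActivity", contains = "SummarizedExperiment")

setValidity("PopulationActivity", function(object) {
  if (!"rates" %in% SummarizedExperiment::assayNames(object))
    return("assay 'rates' is required")
  if (is.null(colData(object)$time_s)) return("colData()$time_s is required")
  t <- colData(object)$time_s
  if (any(diff(t) <= 0)) return("time axis must be strictly increasing")
  bw <- metadata(object)$bin_width
  if (is.null(bw) || bw <= 0) return("metadata()$bin_width must be > 0")
  TRUE
})

#' Construct a PopulationActivity object
#'
#' @param rates sites x time matrix (non-negative for raw rates)
#' @param time_s time axis, one value per column (bin centers, seconds)
#' @param bin_width bin width in seconds
#' @param siteData data.frame of per-site metadata (e.g. \code{region});
#'   one row per row of \code{rates}
#' @return a \code{\linkS4class{PopulationActivity}}
#' @export
populationActivity <- function(rates, time_s, bin_width, siteData = NULL) {
  rates <- as.matrix(rates)
  if (is.null(siteData)) siteData <- data.frame(row.names = seq_len(nrow(rates)))
  if (is.null(rownames(rates)))
    rownames(rates) <- sprintf("site%03d", seq_len(nrow(rates)))
  se <- SummarizedExperiment(
    assays = list(rates = rates),
    rowData = DataFrame(siteData),
    colData = DataFrame(time_s = time_s))
  metadata(se)$bin_width <- bin_width
  new("PopulationActivity", se)
}

#' Rate matrix of a PopulationActivity
#' @param x a \code{PopulationActivity}
#' @export
rates <- function(x) assay(x, "rates")

#' Time axis (seconds) of a PopulationActivity
#' @param x a \code{PopulationActivity}
#' @export
timeAxis <- function(x) colData(x)$time_s

#' Bin width (seconds) of a PopulationActivity
#' @param x a \code{PopulationActivity}
#' @export
binWidth <- function(x) metadata(x)$bin_width

# ---------------------------------------------------------------------------
# PeriEventTensor
# ---------------------------------------------------------------------------

#' Peri-event spectrotemporal tensor
#'
#' Event-aligned windows cut from a (time x frequency) spectrogram, indexed
#' (event, time, frequency), in z-units after double z-scoring.
#'
#' @slot values 3-d array (event, time, frequency)
#' @slot time_s time axis relative to event onset (seconds)
#' @slot freq_hz frequency axis (Hz)
#' @slot channel channel identifier
#' @slot condition per-event condition labels
#' @exportClass PeriEventTensor
setClass("PeriEventTensor", representation(
  values = "array", time_s = "numeric", freq_hz = "numeric",
  channel = "character", condition = "character"))

setValidity("PeriEventTensor", function(object) {
  d <- dim(object@values)
  if (length(d) != 3) return("values must be a 3-d array")
  if (d[2] != length(object@time_s)) return("time axis length mismatch")
  if (d[3] != length(object@freq_hz)) return("frequency axis length mismatch")
  if (any(diff(object@time_s) <= 0)) return("time axis must increase")
  if (any(diff(object@freq_hz) <= 0)) return("frequency axis must increase")
  if (length(object@condition) != d[1])
    return("one condition label per event required")
  TRUE
})

periEventTensor <- function(values, time_s, freq_hz, channel = "ch",
                            condition = rep("pre", dim(values)[1])) {
  new("PeriEventTensor", values = values, time_s = time_s, freq_hz = freq_hz,
      channel = channel, condition = condition)
}

setMethod("show", "PeriEventTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf("PeriEventTensor [%s]: %d events x %d time x %d freq\n",
              object@channel, d[1], d[2], d[3]))
  cat(sprintf("  t: %.2f..%.2f s   f: %.1f..%.1f Hz\n",
              min(object@time_s), max(object@time_s),
              min(object@freq_hz), max(object@freq_hz)))
})

#' Tensor values accessor
#' @param x a \code{PeriEventTensor}
#' @export
tensorValues <- function(x) x@values

# ---------------------------------------------------------------------------
# CodingDimension
# ---------------------------------------------------------------------------

#' Population coding dimension
#'
#' Per-site weight vector separating activity between a target and a
#' reference window, with its normalization mode and training provenance.
#'
#' @slot weights named numeric, one weight per site
#' @slot normalization \code{"unit_norm"} (L2 norm 1) or \code{"sum_abs"}
#'   (sum of absolute weights 1)
#' @slot target_window,reference_window seconds relative to event onset
#' @slot condition training condition label
#' @exportClass CodingDimension
setClass("CodingDimension", representation(
  weights = "numeric", normalization = "character",
  target_window = "numeric", reference_window = "numeric",
  condition = "character"))

setValidity("CodingDimension", function(object) {
  w <- object@weights
  if (any(!is.finite(w))) return("weights must be finite")
  if (!object@normalization %in% c("unit_norm", "sum_abs", "none"))
    return("unknown normalization mode")
  nrm <- switch(object@normalization,
                unit_norm = sqrt(sum(w^2)), sum_abs = sum(abs(w)), none = 1)
  if (object@normalization != "none" && abs(nrm - 1) > 1e-6)
    return("weights do not satisfy the declared normalization")
  TRUE
})

#' Weights of a coding dimension
#' @param x a \code{CodingDimension}
#' @export
dimWeights <- function(x) x@weights

setMethod("show", "CodingDimension", function(object) {
  cat(sprintf(
    "CodingDimension: %d sites, %s, target [%.2f,%.2f)s vs ref [%.2f,%.2f)s (%s)\n",
    length(object@weights), object@normalization,
    object@target_window[1], object@target_window[2],
    object@reference_window[1], object@reference_window[2],
    object@condition))
})

# ---------------------------------------------------------------------------
# BiphasicParams
# ---------------------------------------------------------------------------

#' Two-phase first-order model parameters
#'
#' Parameters of the biphasic state model: during input the state relaxes
#' toward the saturation value \code{S} with time constant
#' \code{tau_broadcast}; with no input it decays exponentially with the
#' condition-specific \code{tau_persist}. All parameters are bounded to
#' [0, 100].
#'
#' @slot S saturation input magnitude (state units)
#' @slot tau_broadcast broadcast (rise) time constant, seconds
#' @slot tau_persist named numeric, persistence time constant per condition
#' @exportClass BiphasicParams
setClass("BiphasicParams", representation(
  S = "numeric", tau_broadcast = "numeric", tau_persist = "numeric"))

setValidity("BiphasicParams", function(object) {
  v <- c(object@S, object@tau_broadcast, object@tau_persist)
  if (any(!is.finite(v))) return("parameters must be finite")
  if (any(v < 0 | v > 100)) return("parameters must lie in [0, 100]")
  if (any(c(object@tau_broadcast, object@tau_persist) <= 0))
    return("time constants must be > 0 for simulation")
  if (is.null(names(object@tau_persist)))
    return("tau_persist must be named by condition")
  TRUE
})

#' Construct BiphasicParams
#' @param S saturation magnitude
#' @param tau_broadcast rise time constant (s)
#' @param tau_persist named numeric of persistence time constants (s),
#'   one per condition
#' @export
biphasicParams <- function(S = 1, tau_broadcast = 0.1,
                           tau_persist = c(pre = 10, drug = 1)) {
  new("BiphasicParams", S = S, tau_broadcast = tau_broadcast,
      tau_persist = tau_persist)
}

setMethod("show", "BiphasicParams", function(object) {
  cat(sprintf("BiphasicParams: S = %.4g, tau_broadcast = %.4g s\n",
              object@S, object@tau_broadcast))
  cat("  tau_persist:",
      paste(sprintf("%s = %.4g s", names(object@tau_persist),
                    object@tau_persist), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# FactorSet
# ---------------------------------------------------------------------------

#' Sign-split NMF factor set
#'
#' Result of factoring a channels x (time*frequency) response matrix after
#' splitting it into positive and rectified-negative parts. Reconstruction
#' is \code{Wpos Hpos - Wneg Hneg}.
#'
#' @slot Wpos,Wneg channel x factor non-negative loadings
#' @slot Hpos,Hneg factor x (time*frequency) non-negative templates
#' @slot time_s,freq_hz axes of the unflattened template
#' @slot channels channel identifiers
#' @slot split list with \code{train} and \code{test} trial indices
#' @exportClass FactorSet
setClass("FactorSet", representation(
  Wpos = "matrix", Wneg = "matrix", Hpos = "matrix", Hneg = "matrix",
  time_s = "numeric", freq_hz = "numeric", channels = "character",
  split = "list"))

setValidity("FactorSet", function(object) {
  if (min(object@Wpos, object@Wneg, object@Hpos, object@Hneg, 0) < -1e-12)
    return("W and H must be non-negative")
  TRUE
})

setMethod("show", "FactorSet", function(object) {
  cat(sprintf("FactorSet: %d channels, %d positive + %d negative factors\n",
              length(object@channels), nrow(object@Hpos), nrow(object@Hneg)))
})

#' Signed reconstruction of a FactorSet
#' @param x a \code{FactorSet}
#' @return channels x (time*frequency) matrix
#' @export
reconstruction <- function(x) x@Wpos %*% x@Hpos - x@Wneg %*% x@Hneg

# ---------------------------------------------------------------------------
# TimescaleFit
# ---------------------------------------------------------------------------

#' Intrinsic-timescale fit
#'
#' Parameters of an \code{a * exp(-lag/b) + c} fit to the autocorrelation of
#' a baseline activity trace; \code{b} (seconds) is the intrinsic timescale.
#'
#' @slot a,b,c fit parameters
#' @slot converged logical convergence flag
#' @exportClass TimescaleFit
setClass("TimescaleFit", representation(
  a = "numeric", b = "numeric", c = "numeric", converged = "logical"))

#' Timescale (seconds) of a TimescaleFit
#' @param x a \code{TimescaleFit}
#' @export
timescale <- function(x) x@b

setMethod("show", "TimescaleFit", function(object) {
  cat(sprintf("TimescaleFit: b = %.4g s (a = %.3g, c = %.3g, %s)\n",
              object@b, object@a, object@c,
              if (object@converged) "converged" else "NOT converged"))
})

# ---------------------------------------------------------------------------
# GroundTruth
# ---------------------------------------------------------------------------

#' Ground truth of a synthetic session
#'
#' Records every planted structure of a synthetic session so each
#' downstream analysis can be checked against what was generated: the
#' two-phase model parameters, per-unit response archetypes, planted evoked
#' spectrotemporal factors, planted band-limited oscillations, coupled
#' channel pairs, the shared latent driving persistent-unit coupling, and
#' the seed.
#'
#' @slot params a \code{\linkS4class{BiphasicParams}}
#' @slot units data.frame: unit, region, archetype, amplitude, baseline
#' @slot factors list of planted evoked factors (center_hz, t_start, t_dur,
#'   loadings)
#' @slot oscillations data.frame: center_hz, bw_hz, amplitude, condition
#' @slot coupled_pairs data.frame: i, j, lag_rad
#' @slot latent list: timescale and sd per condition for the shared latent
#'   that couples persistent units
#' @slot chi aperiodic 1/f^chi exponent of the LFP background
#' @slot seed integer master seed
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
  params = "BiphasicParams", units = "data.frame", factors = "list",
  oscillations = "data.frame", coupled_pairs = "data.frame",
  latent = "list", chi = "numeric", seed = "integer"))

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth (seed", object@seed, "):\n")
  cat("  units:", nrow(object@units), "(",
      paste(sprintf("%s:%d", names(table(object@units$archetype)),
                    as.integer(table(object@units$archetype))),
            collapse = ", "), ")\n")
  cat("  planted factors:", length(object@factors),
      " oscillations:", nrow(object@oscillations),
      " coupled pairs:", nrow(object@coupled_pairs), "\n")
  show(object@params)
})

#' Unit archetype table of a GroundTruth
#' @param x a \code{GroundTruth}
#' @export
unitTable <- function(x) x@units

#' Model parameters of a GroundTruth
#' @param x a \code{GroundTruth}
#' @export
modelParams <- function(x) x@params
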