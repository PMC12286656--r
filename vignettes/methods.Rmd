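---
title: "Methods: biphasic affective dynamics from stimulus-aligned recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biphasic affective dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model it
fits, what the synthetic-data generator does and does not emulate, and the
numerical choices made where the underlying procedures leave freedom.

# The paradigm and the two-phase model

A corneal air puff produces two behaviourally and neurally separable
responses: a stereotyped reflexive blink within ~100 ms, and a slower
"affective" eye closure that outlasts the stimulus, accumulates over a
series of puffs, and decays over tens of seconds. Dissociative drugs
(e.g. ketamine) shorten the persistence of the affective component while
leaving the reflex intact.

The package models the affective state $x(t)$ as a piecewise first-order
system. While input is on (a puff),

$$x(t) = (S - x_0)^+ \left(1 - e^{-t/\tau_{\mathrm{BROADCAST}}}\right) + x_0,$$

and while input is off,

$$x(t) = x_0\, e^{-t/\tau_{\mathrm{PERSIST}}},$$

with $x_0$ the state at the phase transition and $t$ running from the
phase start. Both phases have closed forms, so `simulateBiphasic()`
evaluates the trajectory exactly on any requested grid — there is no ODE
integration error, and phase continuity holds to machine precision.

**Parameters.** $S$ (state units) is the saturation magnitude of the
input drive; $\tau_{\mathrm{BROADCAST}}$ (seconds, default 0.1) sets the
fast rise; $\tau_{\mathrm{PERSIST}}$ (seconds, one value per condition,
defaults 10 pre / 1 drug) sets the slow decay. All parameters are
box-bounded to $[0, 100]$ during fitting, matching the convention of
bounded least squares on this model class. The standard input schedule is
8 steps of 250 ms separated by 3 s onset-to-onset, followed by a 50 s
input-free tail (`puffSeriesSchedule()`).

**Fitting.** `fitBiphasic()` minimizes the squared residual of the
concatenated per-condition traces against concatenated model output with
a bounded Levenberg–Marquardt solver (`minpack.lm::nls.lm`). One
parameter set may vary per condition (`free = "tau_persist"` by default;
`"S"`, `"tau_broadcast"`, and a `"single_phase"` alternative with rise
and decay constants tied are the comparison models). The residual surface
is nonconvex, so the solver is multi-started (default 10 starts) from a
small log-spaced grid of plausible magnitudes with seeded jitter; the
best residual wins. No optimizer tolerance is prescribed by the method
itself; we run `nls.lm` at `ftol = ptol = 1e-12` with 200 iterations,
which on noiseless data recovers parameters to better than $10^{-4}$
relative. Fits ending within $10^{-6}$ of a bound are flagged. Masked
samples (NA) are excluded from the residual; behavioural fits mask the
750 ms after every puff onset to remove the reflexive blink.

**Variance explained** by the condition-varying parameter is
$1 - \mathrm{MSE}_{\mathrm{model}}/\mathrm{MSE}_{\mathrm{null}}$, where
the null fit shares every parameter across conditions and both fits use
the same masked support. It can legitimately be negative.

# What the generator emulates

`groundTruth()` + `simulateSession()` produce seeded sessions with stored
ground truth. Design goals: every planted structure must be recoverable
by the corresponding analysis stage, and identical (config, seed) pairs
must be bit-identical. A single master seed is split into fixed, named
substreams (events, rates, LFP, eye, latent, permutations, bootstrap) by
a deterministic affine map, so adding one component never perturbs
another's draws.

- **Event schedules**: series of 8 puffs × 250 ms at 3 s intervals; 20
  trials before and 20 after the infusion transition by default, with
  uniform 45–90 s inter-trial gaps. The first series starts 150 s into
  the session so a 2-minute pre-assay baseline epoch exists for spectral
  normalization.
- **Unit archetypes**: each unit is baseline + a difference-of-
  exponentials kernel convolved with the event train + noise, rectified
  at zero. Rise/decay constants: fast-transient 0.02/0.08 s;
  fast-persistent 0.02 s rise with decay $\tau_{\mathrm{PERSIST}}$ of the
  trial's condition; delayed-persistent 0.3 s rise, same decay;
  suppressed a fast negative transient; unmodulated flat. The
  difference-of-exponentials form was chosen because its peak and its
  decay-to-fraction times are closed-form checkable. Effect sizes (peak
  excess 4 spikes/s over a 5 spikes/s baseline, suppression at half
  that) are generator choices on the scale of cortical/subcortical
  responses, not claims about any particular dataset.
- **Shared latent**: persistent-archetype units additionally receive a
  common Ornstein–Uhlenbeck latent whose timescale and standard
  deviation are condition-dependent (defaults 1 s / 1.5 pre, 0.3 s / 0.5
  drug). This one mechanism yields both baseline co-fluctuation of
  persistent units (so pairwise correlations and subnetwork coupling are
  meaningful) and a drug-shortened intrinsic timescale of the persistent
  population dimension.
- **LFP-like signals**: $1/f^{\chi}$ background (default $\chi = 2$)
  synthesized by FFT spectral shaping of white noise; planted narrowband
  oscillations gated by condition epochs; evoked spectrotemporal bursts
  after each puff scaled by per-channel factor loadings (positive
  factors; negative factors are standing oscillations whose envelope
  dips after puffs); phase-coupled channel pairs built from one shared
  narrowband source injected into both channels with a fixed analytic
  phase lag.
- **Eye traces**: the model state driven by the trial's puff train (so a
  blinkless, noiseless trace *is* the model trajectory when $S \le 1$),
  plus a raised-cosine reflexive blink (amplitude 0.6, 0.4 s) after each
  puff, plus Gaussian noise, clipped to $[0, 1]$.

**What it does not emulate**: Poisson spike statistics (noise is
Gaussian i.i.d. per bin — sufficient for the window-mean statistics every
stage consumes), biophysical oscillation generation, eyelid mechanics,
artifacts, non-stationary baselines, or pharmacokinetics (conditions are
labels). Passing tests therefore demonstrate that the *analyses* recover
planted structure under clean, stationary conditions with realistic
effect sizes — not that real recordings are this well behaved.

# Numerical choices by stage

**Multitaper spectrograms.** DPSS tapers are eigenvectors of the
standard symmetric tridiagonal matrix; taper count is
$\lfloor 2\,\mathrm{TBW}\rfloor - 1$ (3 tapers at the default
time-bandwidth 2 with 0.4 s windows and 0.05 s stride; 59 tapers at
time-half-bandwidth 30 for the 30 s oscillation-detection windows). For
windows longer than 1024 samples the tapers are computed at 1024 and
spline-resampled — a standard approximation whose spectral concentration
error is negligible for power estimation. Windows are detrended by mean
removal only; window timestamps are centers; the frequency axis is
truncated to 1–100 Hz by default.

**Double z-scoring.** Per frequency, first against a long session
baseline epoch (conventionally the 2 minutes preceding the first series),
then per event against its 1.5 s pre-onset segment. Frequencies with zero
baseline variance are flagged and excluded rather than propagated. The
output is invariant to positive rescaling of the raw signal.

**Sign-split NMF.** The z-scored response matrix is split into its
positive part and rectified negative part; each is factored with NNDSVD
initialization (deterministic; the seed only perturbs exact zeros) and
HALS updates, run to `maxit = 4000` / relative-change `1e-16` so that an
exactly factorable matrix reconstructs to $10^{-6}$ of its norm.
Held-out loadings are refit by non-negative least squares against fixed
templates (`pracma::lsqnonneg`) — we interpret "reconstruction error on
test trials" as refitting loadings, not projecting, and flag this as an
interpretation. The factor count is chosen by the maximum discrete second
difference (curvature) of the held-out EV curve over an even grid
including 0, ties to the smaller count — a deterministic surrogate for a
visual elbow. Condition contrasts (infusion minus the mean of the
non-infusion conditions) are tested per factor by a paired t-test across
surviving channels (floor 0.1 on the average baseline loading), or by a
hierarchical bootstrap (participants, then channels) when participant
labels exist; the grouped mixed-model formulation is deliberately
replaced by this resampling scheme, which preserves the grouping logic
without re-implementing REML.

**Cluster permutation test.** One-sample t per cell on paired
differences; two-sided forming threshold at $\alpha = 0.01$;
4-connectivity within sign (the most conservative standard
neighbourhood); cluster statistic = mass (sum of t); null = maximum
absolute cluster mass under random whole-event sign flips;
$p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + n_{\mathrm{perm}})$
with $n_{\mathrm{perm}} = 1000$ by default and a refusal below 100.
Signs are kept separate when forming clusters. Region-level inference
applies BH to each region's minimum p.

**Coding dimensions.** Raw weight =
$(\bar{x}_{\mathrm{target}} - \bar{x}_{\mathrm{ref}})/\sqrt{s^2_{\mathrm{target}} + s^2_{\mathrm{ref}}}$
across events; normalization is `sum_abs` (human channel convention) or
`unit_norm` (mouse unit convention). Note the deliberate inconsistency,
preserved from the field's conventions: the coding-dimension denominator
*sums* the two variances, while the d′ transform *averages* them
($\sqrt{(v_1+v_2)/2}$). The rise/decay d′ uses the summed-variance
("combined standard deviation") form to match the coding-dimension
convention; its baseline statistics pool every (event, bin) baseline
sample so numerator and denominator are on the same per-bin scale.
Windows are half-open $[a, b)$ throughout, in seconds from onset:
persistent dimension trains on 0.5–1 s and is quantified at 1–2 s
(puffs); the fast dimension uses 0–70 ms; the emotion-like dimension
contrasts a 1 s window starting 5 s after the last puff of a series with
a 750 ms window ending 250 ms before the first puff, then removes the
fast per-puff direction (built from the last 4 series, 200 ms post vs
200 ms pre) by Gram–Schmidt and re-normalizes. Projections are z-scored
per event window (mouse convention) or per session (human convention);
both modes are exposed.

**Unit screening and clustering.** Modulation is any of five paired
t-tests below $\alpha = 0.01$ uncorrected: 1 s pre vs 200 ms post, vs
0.3–0.8 s post, vs 1–2 s post (paired over puffs), and pre-first vs
pre-last, post-first vs post-last 1 s of each series (paired over
series). Response clustering replaces a neighbour-graph/UMAP/Leiden
stack with a deterministic PCA (20 components) + Ward pipeline with
silhouette-selected cluster count: the exact embedding is seed- and
implementation-sensitive, and downstream analyses depend only on
archetype separation. Clusters are ordered by the time for their mean
response to decay to 25% of peak.

**Intrinsic timescale.** Full-signal autocorrelation of the
mean-subtracted series with biased normalization (divide by $N$ — the
smoother estimator for fitting), then an $a\,e^{-\mathrm{lag}/b} + c$ fit
from the peak to 2.5 s right of it, initialized at $(1, 0.2, 0)$. Fits
with $b$ under two samples are flagged non-converged and excluded
downstream. With only 30 s of data the estimator has a known downward
bias at long timescales; tests therefore assert median recovery within
15%.

**PLV.** Zero-phase fifth-order Butterworth band-pass applied forward
and backward, analytic phases, and per 5 s window the magnitude of the
circular mean of the phase differences. Amplitude scaling of either
signal is irrelevant by construction. The expected null PLV is
$\approx \sqrt{\pi/4N_{\mathrm{eff}}}$.

**Subnetwork coupling.** Sites ranked by absolute persistent-dimension
weight; the default subnetwork keeps the top tenth (the human variant
with top/bottom tenths per participant is exposed through the same
interface). Correlation mode divides the infusion-window mean edge
correlation by the pre-infusion mean; PLV mode z-scores each edge
against its pre-infusion windows.

**Oscillation detection.** Per 3-minute segment, the multitaper PSD
(59 tapers, 30 s windows, 15 s stride) is flattened by an iteratively
masked power-law fit in log–log space: fit a line, mask points more than
2.5 SD above it, refit, three iterations. Peaks are local maxima with a
topographic prominence floor of 0.15 log10 units — calibrated so that
pure $1/f$ channels produce at most 5% false drug-unique flags at the
segment sizes used here; peak centers are the midpoint of the
half-prominence interval, which is robust to the flat-topped footprint
of a heavily smoothed multitaper estimate. Peaks are greedily clustered
across segments when their center ± half-width intervals overlap by at
least 80% of the smaller interval; clusters present in fewer than 40% of
segments are dropped; drug clusters matching a baseline cluster within
2 Hz are flagged only if a one-sided rank-sum test on segment heights
is significant at 0.001, and unmatched drug clusters are flagged as
new frequencies.

# Problem sizes

The test suite and `scripts/acceptance.R` run on deliberately compact
problems: sessions of 3–8 series with 30–40 units at 10–20 ms bins,
12-minute oscillation channels (four 3-minute segments per window),
40–100 replicate runs for calibration rates, 20–50 seeds for fit-recovery
statistics, and 200–500 permutations per cluster test. These sizes were
chosen so the full chain demonstrates its statistical properties —
calibrated type-I rates, planted-structure recovery, correct orderings —
at desk scale; the thresholds asserted (e.g. median $\tau$ error ≤ 10%,
type-I ≤ nominal + 2 binomial SE, ≥ 95% signature reproduction) are the
scientific requirements themselves.

# Known limitations

- The generator's Gaussian, stationary noise understates the burstiness
  and non-stationarity of real recordings; calibration rates established
  here are necessary, not sufficient, for real data.
- The intrinsic-timescale estimator inherits the usual finite-length
  autocorrelation bias; comparisons should be within-estimator (pre vs
  drug), as done here.
- Rise/decay times measured on d′ traces are systematically early by a
  first-crossing bias when the per-bin variance is estimated from few
  replicates; the package reports them as measured and leaves replicate
  counts to the caller.
- The NMF objective is nonconvex; NNDSVD + HALS is deterministic but
  finds a local minimum. Recovery guarantees in the tests apply to
  factors with distinct supports.
- Artifact rejection (epileptic/sleep epochs, broken channels) is out of
  scope and assumed done upstream.
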