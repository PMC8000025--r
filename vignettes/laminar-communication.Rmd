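---
title: "Directed communication between cortical laminae: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed communication between cortical laminae: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminarGC)
```

# Overview

laminarGC analyzes trial-epoched local field potentials (LFPs) recorded with
linear multi-contact probes spanning the cortical depth of two visual areas
(V1 and V4) while attention is directed toward or away from the recorded
receptive field. The pipeline asks two questions: *where along the cortical
depth does feedforward input arrive* (laminar alignment), and *which
direction and frequency band carries communication between contacts and
areas, and how attention changes it* (conditional Granger causality and
modulation statistics).

The package ships a synthetic-data generator with known ground truth so
every stage is testable without recorded data. This vignette documents the
models, the tunable parameters, the numerical choices, and the places where
the design was genuinely open.

# The recording model

A session is a tensor `trial x channel x sample` in µV. Defaults mirror a
standard laminar preparation: two 16-contact probes at 150 µm spacing,
sampling rate 1017.375 Hz, epochs of 512 samples (503.25 ms), three trial
conditions (attend-RF, OUT1, OUT2), and a companion baseline tensor of 234
samples (−200 ms to +30 ms around stimulus onset). Note that 512 samples at
1017.375 Hz is exactly 503.25 ms; the sampling rate is carried as data
metadata everywhere, never hard-coded.

## What the generator emulates

`generate_session()` builds each trial from four ingredients:

1. **Band-limited oscillators.** Narrowband-filtered Gaussian noise
   (4th-order Butterworth band-pass), not pure sinusoids, so spectra have
   realistic peaked lobes with width. Each oscillator has a per-condition
   amplitude gain and a per-condition center-frequency offset, and mixes
   into channels through a depth profile. A single latent source shared by
   several channels induces coherence between them, as common synaptic
   drive does in tissue.
2. **Directed lagged couplings.** Finite-lag linear terms
   (`x_target[t] += gain * mean(x_source[t - lag])`), so the latent system
   is exactly a stable vector autoregression and Granger-causal ground
   truth is well defined. The generator rejects coupling sets whose
   companion operator has spectral radius ≥ 1, naming the largest-gain
   coupling.
3. **1/f background.** White noise shaped in the frequency domain with a
   configurable exponent (default 1), plus a small white floor.
4. **An evoked granular sink.** For stimulus-onset-aligned epochs, a
   balanced sink/source CSD depth profile with a Gaussian time course is
   pushed through the same disc-source forward model the analysis inverts,
   and a multiunit-envelope tensor with a known shortest-latency channel is
   emitted alongside.

One RNG stream is derived per trial from the master seed by counter, so a
trial's content does not depend on how many trials precede it; identical
config and seed give bit-identical sessions.

## What it does not emulate

Eye movements and microsaccades, spiking point processes, nonstationary
drifts across a session, moving-versus-stationary grating differences, and
electrode impedance artifacts. Passing tests therefore demonstrate that the
estimators recover the configured spectral and causal structure under
realistic 1/f noise and trial counts - not that recorded cortical data meet
the estimators' assumptions.

# Preprocessing

Epoching is pure slicing (no filtering or detrending); per-trial mean
removal happens inside the spectral and GC estimators. Bipolar
re-referencing takes the first difference of adjacent contacts within a
probe, superficial minus deep, assigned to the parents' midpoint depth.
This is the simplest local derivation that removes common-mode signal
exactly; the removal is tested as an exact identity.

# Laminar alignment by inverse CSD

The forward model treats each depth slab as a uniform current disc of
radius R = 500 µm in a medium of conductivity 0.4 S/m; the potential of a
disc at axial distance d is proportional to `sqrt(d^2 + R^2) - |d|`. The
CSD depth profile is parameterized by its values at the electrode depths
under natural cubic-spline interpolation, giving a conduction matrix F with
`potentials = F %*% csd`. `compute_icsd()` inverts exactly this F, so the
forward/inverse pair is a round trip on the spline span (tested to relative
error below 1e-6); conductivity scales magnitudes but never the spatial
profile. The estimate is then smoothed along depth with a Gaussian of SD
200 µm using reflection padding at the grid edges.

Layer IV is identified as the depth with the *earliest current sink*: the
first time, inside a 20-100 ms post-stimulus search window, at which the
smoothed CSD falls below 25% of the global peak sink. Both the window and
the onset fraction are exposed as arguments because no principled universal
value exists; detection is invariant to global amplitude scaling, and ties
resolve toward the larger sink. When a multiunit envelope is available its
shortest baseline-relative latency (mean + 3 SD criterion) is compared to
the sink channel; on disagreement the CSD sink wins and a warning is
logged, since the sink is the more direct signature of granular input.

Compartments follow area-specific distance rules relative to the reference
contact (positive = superficial): V1 supragranular 0.25-1 mm above,
granular within 0.25 mm, infragranular 0.25-0.75 mm below; V4 uses a 0.1 mm
granular half-width. Outer bounds are closed and the granular bound open;
contacts outside all ranges are `unassigned` and excluded from pooling.

# Spectral estimation

Power and coherence use K = 3 Slepian tapers with time-bandwidth product
TW = 2 on N = 512 samples, giving half-bandwidth W = TW·fs/N ≈ 4 Hz and
grid resolution fs/N ≈ 2 Hz. Tapers are computed from the standard
symmetric tridiagonal eigenproblem and cached. Power is returned as a
one-sided density whose integral matches the signal variance (checked
against a plain periodogram oracle on white noise).

Baseline z-normalization is `(S - mean_trials S_base) / SD_trials S_base`
per channel and frequency. The baseline window (234 samples) is shorter
than the analysis window, so baseline mean and SD are estimated with the
same taper parameters on the short window and linearly interpolated onto
the analysis frequency grid; a zero baseline SD anywhere is an error naming
the frequency rather than a silent division.

Coherence pools all taper-trial cross- and auto-spectral products jointly
before forming `|S_xy|^2 / (S_x S_y)`. This joint-pooling convention is the
standard multitaper estimator; its small-sample bias for independent
signals is approximately `1/(K * n_trials)`, and the estimator is tested
against that analytic value. A single taper of a single trial is
identically 1 and is rejected as degenerate.

Sliding time-frequency maps step a 512-sample window every 20 ms,
right-aligned so the last window ends at the alignment event (a 1,006.5-ms
span yields 26 windows). Band summaries average the grid frequencies inside
theta [4,8), alpha [8,13), beta [13,25), low gamma [25,50) and high gamma
[50,80] Hz, with lower edges inclusive, upper edges exclusive except the
last band, and DC/Nyquist always excluded. Peak localization smooths with a
3-bin moving average by default (configurable) and breaks ties toward the
lower frequency; flat spectra return a flag instead of an arbitrary peak.

# Conditional Granger causality

The estimator is a parametric multi-trial VAR with the Geweke conditional
spectral decomposition (two-model method): a full VAR on (target,
conditioning set, source), and a reduced model on (target, conditioning
set) whose innovations are passed through the full model's transfer
function after block-normalizing the innovation covariances. The spectral
values are nonnegative by construction; small negative numerical artifacts
are clipped at 0 and counted, with a warning when more than 1% of bins
clip.

Design choices that were genuinely open:

* **Model order.** BIC over 1-20 for the full model by default, with a
  fixed-order override.
* **The reduced model is derived, not refit.** The marginal of a VAR over a
  subset of its variables is VARMA - an AR(∞) process - so refitting it as
  a low-order VAR by least squares is inconsistent with the full fit and
  biases the GC level upward (the classic single-regression problem).
  Instead, the reduced model is computed from the fitted full model itself:
  the full model's autocovariance sequence (companion-form Lyapunov
  equation) is factorized by Whittle's multivariate Levinson-Durbin
  recursion into a deep AR approximation of the marginal, with lag depth
  chosen from the fitted spectral radius and capped at 64. This makes the
  decomposition exactly self-consistent - the frequency average of the
  spectral GC matches the model-implied time-domain GC to machine
  precision - and restores the calibration of the shuffle null for sources
  that are correlated with the conditioning set: in a relay-chain
  simulation the conditional false-exceedance of the 95th-percentile
  threshold is at the nominal rate, where the refit-by-OLS variant was
  several times too liberal.
* **Conditioning set.** For a within-probe pair, the remaining derivations
  of the same probe; between probes, the remaining derivations of both.
  Both are capped (default 8) keeping the nearest by depth, to protect the
  guard ratio of samples to parameters (enforced at ≥ 10 pooled samples
  per coefficient).
* **Degenerate inputs.** Duplicated or collinear channels raise explicit
  singular-covariance errors; an unstable fitted companion matrix is an
  error, not a warning; a near-singular innovation covariance receives a
  ridge of `1e-8 * trace/dim`, flagged in the model object.

Two identities anchor correctness. First, the frequency average of the
spectral decomposition equals the fitted time-domain GC
`ln(det Sigma_reduced / det Sigma_full)` (tested to 0.1%). Second, on data
simulated from a bivariate VAR(1) with known coefficients, that time-domain
GC has a closed form via Kolmogorov's spectral factorization of the exact
model spectrum, and the estimate agrees within 2% at 200 trials x 512
samples.

Significance uses a trial-shuffle null: the source channel's trial order is
permuted relative to the target (conditioning set stays with the target),
the cGC is recomputed per shuffle, and the 95th percentile is taken per
frequency, per band, and for the grid-mean statistic (default 200 shuffles,
seeded; at least 20, warning below 100). On a relay chain X→Z→Y the
unconditioned X→Y estimate exceeds the pair's significance threshold while
conditioning on the relay pulls the estimate back below that same bar -
verified across 50 seeded replicates. (Note that comparing a conditional
estimate to its own calibrated 95th-percentile null exceeds the null in
about 5% of replicates by construction; that per-statistic calibration is
tested separately on exchangeable data.)

# Attention statistics

The two attend-away conditions are pooled by drawing an equal number of
trials from each (the smaller condition's count), seeded. For estimators
whose bias depends on trial count (coherence, GC), attend-RF trials are
subsampled to the pooled size. The modulation index is
`MI = (F_RF - F_OUT) / (F_RF + F_OUT)`, in [-1, 1] for nonnegative
measures, exactly antisymmetric, and undefined (NA, counted) when both
inputs are zero. The spectrogram MI is computed on raw power by default:
baseline z-scored maps can be negative, which makes the ratio ill-behaved,
so they are refused unless explicitly allowed.

Sessions are the statistical unit. Differences are tested with two-sided
Wilcoxon signed-rank tests; Benjamini-Hochberg step-up controls the FDR at
q = 0.05 *within frequency-band families*; tests with fewer than 5 non-tied
pairs are skipped and flagged. Dominance matrices test, per contact pair,
which direction carries stronger cGC across sessions, and keep the
session-mean strength of the dominant direction with a sign encoding the
direction - entries come in antisymmetric-signed pairs by construction.
Band-averaged cGCs are normalized to the maximum across the five bands per
normalization group (e.g. per animal, separately for within- and
between-area pools), and contact-level results are pooled into the three
laminar compartments by arithmetic mean, excluding `unassigned` contacts. A
single-factor repeated-measures ANOVA across the three conditions is
available as a secondary check before OUT pooling.

Type-I behavior of the whole chain is tested: on 20 generated sessions with
no condition effect, the post-FDR fraction of significant MI cells per band
family stays within 1.5x the nominal q.

# Problem sizes and numerical choices

The test-suite and acceptance problem sizes were chosen as the smallest at
which the statistical claims are comfortably testable: coefficient recovery
and the analytic GC oracle at 200 trials x 512 samples; conditioning
soundness at 40 trials with 100 shuffles over 50 replicates; type-I control
at 20 sessions x 30 trials per condition with 8 channels; peak-shift
recovery at 100 trials per condition. The conduction matrix uses 20
quadrature subintervals per electrode gap, which puts the forward-inverse
round trip at machine precision relative to the 1e-6 contract. Session
containers are versioned RDS files with a format tag (`write_session()` /
`read_session()`), one file per session.

# Known limitations

* The parametric GC estimator assumes an adequate VAR description; strongly
  nonlinear or heavily nonstationary couplings are outside its scope (a
  nonparametric spectral-factorization estimator is deliberately not
  included).
* The generator's couplings are linear and time-invariant within an epoch;
  attention effects enter as gains, peak offsets, and coupling-gain
  changes, not as changes in noise correlation structure.
* Compartment boundary inclusivity (closed outer bounds, open granular
  bound) is one reasonable reading of distance-range rules; contacts
  exactly on a granular boundary land in the adjacent compartment.
* The shuffle null destroys *all* source-target trial pairing, so it tests
  exchangeability rather than the sharper null of zero conditional GC with
  preserved cross-trial structure.
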