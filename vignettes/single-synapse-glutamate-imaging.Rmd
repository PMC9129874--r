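---
title: "Single-synapse glutamate imaging: models, estimators and design choices"
author: "gluSynapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-synapse glutamate imaging: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gluSynapse)
```

# Scope

gluSynapse analyzes fluorescence recordings of the membrane-tethered
glutamate sensor iGluSnFR at individual synapses. Four questions drive the
design:

1. **Event detection and failure analysis.** Which frames of a 50 Hz ROI
   trace contain quantal glutamate-release events, which stimuli produced a
   release ("success"), and what are the per-synapse release probability,
   spontaneous frequency and amplitudes?
2. **Probe mobility (FRAP).** How fast do unbleached probes repopulate a
   bleached membrane region, and what fraction never recovers?
3. **Use-dependent photobleaching.** If only glutamate-bound (fluorescent)
   probes can be bleached, and probes at evoked release sites exchange with
   the membrane reservoir much more slowly than probes elsewhere in the
   synapse, how do evoked and spontaneous signals decay and recover around a
   bleaching episode?
4. **Probe nano-organization.** Are localizations of the probe clustered,
   and how does density fall off around cluster centers?

Because no raw recordings ship with the package, every estimator is paired
with a synthetic-data generator that produces inputs with exact ground
truth; correctness is established by parameter recovery rather than by
reference outputs.

# The synthetic recording model

A synapse is parameterized by `SynapseConfig`: a per-stimulus release
probability `pr` (Bernoulli per action potential — single-vesicle "success
or failure" statistics), a spontaneous fusion rate (homogeneous Poisson;
default 0.015 events/s, the middle of the 0.01–0.02 Hz range typical of
cultured hippocampal synapses), a mean quantal amplitude in arbitrary
fluorescence units, and an amplitude coefficient of variation (lognormal,
default CV 0.25, truncated at zero by construction). Each event adds the
kernel

$$A\,(1 - e^{-s/\tau_{rise}})\,e^{-s/\tau_{decay}},\qquad s \ge 0,$$

with an instantaneous rise by default and `decayTau` = 0.1 s — a plausible
decay for iGluSnFR sampled at 50 Hz; the published traces constrain the
shape only qualitatively, so these constants are explicit package choices.
Event times are snapped to the frame grid so that the sampled peak equals
the drawn amplitude; evoked events peak one frame (20 ms) after their
stimulus, a stand-in for synaptic plus sensor latency that also keeps the
peak inside the post-stimulus response window. Gaussian white frame noise
and an affine baseline are added last; shot noise and camera gain are
deliberately not modeled. Movies render each synapse as an isotropic
Gaussian (default PSF sigma 0.5 µm on a 0.2 µm pixel grid).

A single master seed drives everything. Substream seeds for each synapse
are drawn sequentially from the master stream, so enlarging a scene leaves
the traces of existing synapses bit-identical.

**What passing tests show — and what they do not.** The generator emulates
quantal statistics, kernel shape, white noise and bleaching-scaled
amplitudes. It does not emulate correlated noise, focus drift, overlapping
synapses in one ROI, or multivesicular release. Recovery results therefore
validate the estimators' correctness under the stated model, not their
robustness to every experimental artifact.

# Detection pipeline

ROIs are circular (default 2 µm diameter) and centered on local maxima of a
summed projection over a high-activity interval; maxima closer than a
minimum separation are pruned greedily, keeping the brighter peak. Traces
are the per-frame mean over pixels whose centers fall inside the ROI.

Preprocessing subtracts a single OLS line fit to the whole trace
("background subtracted linearly"), which makes detection exactly invariant
to affine drift; rolling detrending was rejected for determinism and
testability. Smoothing is a centered 3-point (optionally 5-point) moving
mean with shrinking edge windows.

Detection thresholds at `k` = 3 noise SDs above a **trailing** 4 s
moving-average baseline. Two choices here are deliberate:

* **Causal (trailing) windows.** An event should not inflate the baseline
  or noise estimate used to judge it; a trailing window ending at the
  previous frame (or at the stimulus, for evoked detection) keeps the
  threshold uncontaminated by the response itself.
* **Noise scale from raw residuals.** The noise SD is estimated robustly —
  1.4826 × the trailing median of absolute deviations from a trailing
  running median — on the *unsmoothed* trace. Thresholding a 3-point
  smoothed trace against 3 SDs of *smoothed* noise would pass ~0.1% of
  noise frames and, at 50 Hz, produce tens of spurious "events" per
  10-minute recording — an order of magnitude above real spontaneous rates.
  Calibrating the threshold on raw noise while detecting on the smoothed
  trace gives a negligible false-positive rate with >99% sensitivity at
  SNR 8 (both properties are asserted against an independently coded oracle
  in the test suite). A robust (median-based) scale is used so that the
  events themselves, which occupy a few frames of each 4 s window, do not
  inflate the estimate.

Supra-threshold runs each yield one event at their maximum; events closer
than a 0.1 s refractory interval merge (larger peak kept). Evoked detection
restricts to `(stim, stim + 0.3 s]` windows, requires inter-stimulus
intervals longer than the window, and scores at most one success per
stimulus; release probability is the exact integer ratio
successes/stimulations. Detection begins after two full baseline windows
(8 s) so both the baseline and its noise scale are fully defined; stimuli
must respect the same lead-in. Downstream statistics average synapses
within coverslips, so each culture contributes one value.

# FRAP

`doubleNormalize()` implements double normalization: after background
subtraction, the ROI is normalized to its pre-bleach mean and divided by
the correspondingly normalized unbleached reference region, canceling
acquisition photobleaching. The post-bleach recovery is fit with

$$F(t) = F_\infty - (F_\infty - F_0)\,e^{-(t - t_b)/\tau},$$

by Levenberg–Marquardt least squares (initialization: $F_0$ = first
post-bleach sample, $F_\infty$ = mean of the last 10% of samples, $\tau$ =
time-to-half-recovery / ln 2; bounds $\tau \in (0, 10\times\mathrm{span}]$,
$F_\infty \in [F_0, 1.5]$). The immobile fraction is defined on the
double-normalized scale as the gap between the pre-bleach level and the
asymptote, $1 - (F_\infty - F_0)/(1 - F_0)$; mobile + immobile = 1 exactly.
A full-scale rescaling (first post-bleach sample pinned to 0) is available
for display, but fractions are always computed on the double-normalized
scale. A recovery that is flat to within 1e-10 is returned as a fully
immobile fit with an unidentified (NA) time constant rather than forcing
the optimizer through a degenerate problem. Double-exponential and
reaction–diffusion models are out of scope.

# The use-dependent photobleaching model

Three well-mixed compartments carry unbleached-probe fractions $u_c$:
`evoked_site` (diffusion-restricted probes apposed to evoked release
sites), `synaptic_general` (freely exchanging synaptic probes) and
`reservoir` (the extrasynaptic membrane pool, effectively infinite). Only
activated probes bleach:

$$\frac{du_c}{dt} = -k_{bleach}\, I(t)\, a_c(t)\, u_c +
\frac{u_{res} - u_c}{\tau_c},$$

with relative illumination $I$ (0 dark, ~0.02 imaging, 1 full power) and
activation $a_c$. Defaults: exchange time constants 10 s
(`synaptic_general`, matching the seconds-scale FRAP recovery) and 6 h
(`evoked_site`, chosen so that recovery is essentially complete within
24 h in the dark); $k_{bleach}$ = 0.14 s⁻¹ (activated-probe half-life ≈ 5 s
at full intensity, so a 30 s bleach substantially depletes active pools);
tonic activation 0.05; per-event activation 0.3 for 0.5 s. Event-driven
activation enters as its duty-cycle average (rate × 0.3 × 0.5 s), clamped
to 1; glutamate perfusion saturates $a_c = 1$ everywhere.

One parameter departs from treating all compartments symmetrically: the
reservoir's tonic activation defaults to 0 rather than 0.05. With a
tonically activated reservoir, full-field illumination would bleach the
reservoir as fast as the evoked site, spontaneous signals would track it
down, and nothing could recover — contradicting both the seconds-scale FRAP
recovery and the minutes-scale return of spontaneous events. Physically,
ambient glutamate is a synaptic quantity and most of the reservoir surface
lies outside the illuminated field, so a near-zero reservoir tonic
activation is the defensible default; it remains a parameter
(`aTonicReservoir`) and perfusion still activates the reservoir fully,
which is what makes perfusion-bleaching ablate spontaneous signals
persistently.

Integration is a per-step exponential update with activation and the
reservoir level frozen within each step (default dt 0.1 s; the step must be
≤ min(τ)/10 and ≤ half the event duration, and halving it changes
endpoints by < 1e-4). The model yields the central ordering: after a
10-minute full-power bleach, $u_{evoked} \approx 0.02$ while
$u_{spont} \approx 0.93$; in the dark, the spontaneous pool re-equilibrates
within tens of seconds while the evoked site needs over ten hours to reach
90%. `runProtocol()` converts $u$ into relative detection metrics via the
Gaussian threshold-crossing probability, normalized to the unbleached
state. The model is compartmental by design — no spatial reaction–diffusion
PDE — and its parameters are not fit to any published recovery curves;
figure-derived values are used only as qualitative orderings.

# Spatial statistics

DBSCAN is implemented classically (core points have ≥ `minPts` neighbors
within `eps`, self included); the known border-point ambiguity is fixed by
deterministic input-order claiming, and the implementation is tested for
exact equality against a brute-force transitive-closure oracle. The
pair-correlation estimator is center-referenced: around each reference
center (typically a DBSCAN cluster centroid),

$$g_k = \frac{\sum_c N_{k,c} \,/\, \sum_c A_{k,c}}{\lambda},$$

where $N_{k,c}$ counts localizations in annulus $k$ around center $c$,
$A_{k,c}$ is the annulus area clipped to the field (computed exactly for
interior circles and by piecewise adaptive quadrature of the chord length
at the boundary), and $\lambda$ is the global density. Under complete
spatial randomness every bin has expectation 1. Default bins are 10 nm wide
out to 500 nm. The clustered generator is a Thomas process (uniform
parents, Gaussian offspring), whose analysis end-to-end shows the expected
near-center enrichment decaying to the background level.

# Numerical and interface choices

* Frames are addressed 1-based in R; frame *i* is stamped at
  $t_0 + (i-1)\,dt$. All times are seconds, amplitudes arbitrary units
  (not ΔF/F — consistent with reporting in arbitrary units).
* Window lengths given in seconds are rounded to an odd number of frames so
  trailing medians are well defined.
* TIFF stacks are stored frames-first as 32-bit pages affinely mapped to
  [0, 1]; the mapping and `dt`/`pixel_size` metadata live in a JSON sidecar
  (storage resolution ~2e-10 of the range).
* `runExperiment()` orchestrates simulate → bleach-model → detect →
  summarize from a YAML config, validates the config reporting *all*
  violations, and writes a manifest (config snapshot, seed, package
  version, output hashes); CSV outputs are byte-identical across re-runs
  with the same seed.

# Problem sizes used in validation

The shipped validation suite runs at deliberately moderate sizes chosen to
exercise the estimators' statistical claims: release-probability recovery
uses 636 synapses × 40 stimuli at SNR 8 (the tolerance, three binomial
standard errors, is ~0.009); spontaneous-rate recovery uses 100 synapses ×
600 s; FRAP recovery uses noiseless 1 Hz curves with 60 s of post-bleach
data; Monte-Carlo checks use 30–200 seeds with analytic standard-error
tolerances. These sizes make every statistical tolerance meaningful without
requiring long runtimes.

# Known limitations

* The noise model is white and Gaussian; EMCCD gain noise and photon shot
  noise are absent, so SNR-dependent results should be read as referring to
  effective SNR.
* Compartments in the bleaching model are fully disjoint; whether evoked
  and spontaneous release draw on partially overlapping probe populations
  is an open biological question, and the model's answer (disjoint) is an
  assumption.
* The pair-correlation normalization uses the global density of the
  analyzed field; patterns whose true observation window differs from the
  stored field rectangle will be biased accordingly.
* Amplitudes of detected events are measured on the smoothed trace;
  absolute amplitudes are attenuated by the smoothing kernel (ratios, as
  used in pre/post comparisons, are unaffected). Set `smoothPoints = 1`
  when absolute amplitude fidelity matters and SNR allows.
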