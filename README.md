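# gluSynapse

Quantal analysis of single-synapse glutamate imaging with the fluorescent
sensor iGluSnFR — and a fully ground-truthed simulator to validate every
estimator by parameter recovery.

Neurotransmitter release at an individual synapse is binary: each action
potential either releases one vesicle or fails, and vesicles also fuse
spontaneously at ~0.01–0.02 Hz per synapse. gluSynapse is for
neurophysiologists who record these events optically (50 Hz ROI traces
around synaptic fluorescence maxima) and need reproducible answers to:

* **Which frames contain release events, and which stimuli succeeded?**
  Events are samples of the (optionally smoothed) trace exceeding a
  trailing 4 s moving-average baseline by *k* = 3 robust noise SDs; evoked
  successes must fall within 0.3 s of a stimulus. Release probability is
  the exact ratio (detected responses)/(stimulations); spontaneous
  frequency is count/duration; statistics aggregate per coverslip.
* **How mobile is the probe?** FRAP triplets (ROI/reference/background)
  are double-normalized,
  `F(t) = [mean_pre(ref')/ref'(t)] * [roi'(t)/mean_pre(roi')]`, and fit
  with the single exponential `F(t) = Finf − (Finf − F0)·exp(−(t−t_b)/τ)`;
  the immobile fraction is `1 − (Finf − F0)/(1 − F0)`.
* **Why do evoked and spontaneous signals bleach and recover
  differently?** A three-compartment model of use-dependent photobleaching
  (`du_c/dt = −k_bleach·I·a_c·u_c + (u_res − u_c)/τ_c`) couples bleaching
  of activated probes to lateral exchange: freely diffusing synaptic
  probes re-equilibrate in ~10 s, while diffusion-restricted probes at
  evoked release sites take hours.
* **Is the probe clustered?** DBSCAN cluster detection plus a
  center-referenced pair-correlation function `g(r)` with exact
  field-boundary clipping; `g ≡ 1` under complete spatial randomness.

All estimators operate on plain R objects (S4 classes around numeric
vectors and data.frames) and read/write TIFF stacks, CSV traces/events,
and YAML protocols.

## Worked example

Simulate a synapse at release probability 0.49 recorded for 40 stimuli at
0.2 Hz with quantal amplitude 8× the noise SD, then run the detection
pipeline; and fit a noiseless FRAP curve generated at τ = 8.9 s with a 19%
immobile fraction:

```r
library(gluSynapse)

cfg   <- SynapseConfig(pr = 0.49, spontRate = 0.015, quantalAmp = 8, ampCv = 0)
stims <- 10 + (0:39) * 5
proto <- RecordingProtocol(duration = 212, sampleRate = 50, stimTimes = stims)

sim   <- generateTrace(cfg, proto, NoiseModel(sigma = 1), seed = 101)
trace <- subtractBackground(sim$trace)
ev    <- detectEvoked(trace, stims)
cat("ground-truth successes:", sum(events(sim$events)$kind == "evoked"), "\n")
cat("detected successes:   ", length(ev), "\n")
cat("estimated Pr:         ", releaseProbability(ev, stims), "\n")

fitFrap(generateFrapCurve(tau = 8.9, immobileFraction = 0.19,
                          bleachDepth = 0.8))
```

```
ground-truth successes: 21
detected successes:    21
estimated Pr:          0.525
FRAPFit: tau = 8.9 s, F0 = 0.2, Finf = 0.848, mobile = 0.81, immobile = 0.19 (R2 = 1)
```

Every one of the 21 simulated fusions was called correctly (0.525 = 21/40
is the realized Bernoulli fraction for this seed; averaged over many
synapses the estimate converges to 0.49 within binomial error). The FRAP
fit returns the generating time constant and immobile fraction exactly on
noiseless input.

The end-to-end bleaching paradigm — record, photobleach, record again,
normalize each synapse to itself — is driven by `runExperiment()` from a
YAML config and reproduces the model's signature: after a long bleach,
relative evoked release probability collapses while relative spontaneous
frequency recovers within minutes. See the vignette
(`vignettes/single-synapse-glutamate-imaging.Rmd`) for the models,
defaults and design decisions.

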