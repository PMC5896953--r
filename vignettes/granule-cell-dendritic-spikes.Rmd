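---
title: "Quantifying dendritic spikes, backpropagation and LTP in granule cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dendritic spikes, backpropagation and LTP in granule cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcdspike)
```

## The scientific problem

Mature dentate gyrus granule cells are electrically unfavorable for
classical associative plasticity: their resting potential is hyperpolarized
(about −81 mV), they fire sparsely, and backpropagating action potentials
(bAPs) attenuate steeply along their thin dendrites.  Yet theta-burst
stimulation (TBS) of perforant-path inputs onto their distal dendrites
reliably induces NMDA-receptor-dependent long-term potentiation (LTP).  The
resolution is a local one: high-frequency synaptic drive can trigger
dendritic Na⁺ spikes, visible at the soma as fast spikelets riding on the
compound EPSP, and the number of such events during induction predicts the
LTP magnitude.

`gcdspike` implements the full quantification chain of such a study as
reusable, tested code:

1. **Event detection** — dendritic spikelets are identified from the peak of
   the temporal derivative of the somatic voltage and classified by a
   half-open threshold ladder: dV/dt < 2.5 mV/ms plain EPSP;
   [2.5, 10) weak dendritic spike; [10, AP threshold) strong dendritic
   spike; at or above the site's AP threshold (40 mV/ms soma, 20 mV/ms
   dendrite) axosomatic AP.  APs are detected but never counted as
   dendritic spikes.
2. **bAP propagation** — peak amplitudes from paired soma–dendrite
   recordings are fit with a mono-exponential `A(x) = A0·exp(−x/λ)` over
   0–212 µm, optionally normalized to the somatic amplitude and relative
   dendritic length; conduction velocity is the reciprocal slope of the
   ordinary least-squares regression of half-maximal rising-phase latency
   on distance.
3. **Patch currents** — outside-out-patch voltage-clamp families are
   leak/capacitance-corrected by the P/−4 procedure
   (`corrected = test + 4·mean(subpulses)`); the A-type K⁺ current is the
   difference between −120 mV- and −40 mV-prepulse responses; the delayed
   rectifier is the −40 mV-prepulse response; Na⁺ is the corrected 0 mV
   test-pulse minimum.  Site-grouped statistics (soma, dendrite < 100 µm,
   dendrite ≥ 100 µm) use the Kruskal–Wallis test with Dunn's multiple
   comparisons.
4. **Plasticity** — LTP magnitude is the mean EPSP amplitude 25–30 min
   after induction as a percentage of the final 5 baseline minutes; the
   spike-count/LTP association is a Pearson correlation.

Because no recordings ship with the package, a synthetic-data module
generates sessions with the statistical structure these analyses assume,
with every inserted event logged as ground truth.  All tests compare
against that log, never against copied numbers.

## The synthetic generator: what it emulates

`make_tbs_session()` builds a somatic voltage session: baseline test
stimulation (0.1 Hz), four TBS episodes (10 bursts at 5 Hz of 10 stimuli at
100 Hz, episodes every 10 s — 400 pulses), and post-induction test
stimulation whose EPSPs are scaled by the configured LTP factor.

* **EPSP kernel** — peak-normalized difference of exponentials, rise 8 ms,
  decay 40 ms, first-pulse amplitude 7 mV.  These constants were chosen so
  the kernel's analytic maximum slope, `amp·(1/τr − 1/τd)/g_peak`, is
  ≈ 1.3 mV/ms — the reported derivative of EPSPs without dendritic spikes —
  which guarantees that plain synaptic responses never cross the
  2.5 mV/ms spikelet criterion.
* **Short-term depression** — within a 100 Hz burst each successive EPSP is
  scaled by 0.7 (floor 0.25).  Without depression, linear summation of ten
  7 mV EPSPs would stack slope contributions well past the spikelet
  threshold and drive the trace far above anything seen in such
  recordings; perforant-path synapses depress strongly at 100 Hz, so this
  is also the realistic choice.
* **Plateau envelope** — an alpha function (τ = 150 ms) rising from each
  burst's end, peak 36.6 mV (25.6 mV emulates NMDAR blockade).  Envelopes
  of consecutive bursts combine by pointwise maximum rather than summation:
  the plateau is a saturating regenerative event, and summation would
  otherwise accumulate to nonphysical depolarizations across ten bursts.
* **Spikelets** — Gaussian bumps of width σ = 1.5 ms whose amplitude is
  solved analytically from the intended dV/dt peak
  (`amp = target·σ·√e`).  A Gaussian was preferred over a
  difference-of-exponentials because its slope maximum is interior and
  smooth, so moderate smoothing attenuates the realized dV/dt peak by only
  `≈ W²/(12σ²)` (6% at the default detection bandwidth) instead of the
  ~25% onset-clipping a kernel with a slope discontinuity suffers; the
  logged target therefore remains meaningful ground truth.  Insertion is
  per burst (probability `spikelet_rate`, or an exact `n_spikelets`), at a
  6 ms delay after a random stimulus of the burst.
* **APs** — stereotyped Gaussian templates (93.6 mV, σ = 0.25 ms) whose
  smoothed dV/dt peak (~56 mV/ms at default settings) always classifies as
  axosomatic.
* **Noise** — additive white Gaussian passed through a one-pole low-pass at
  3 kHz (the acquisition filter corner; configurable, since published
  recordings were filtered at 3 or 10 kHz) and renormalized to the
  configured SD (default 0.3 mV).
* **Pharmacological conditions** are purely parametric: the
  Na⁺-channel-blocked (QX-314) condition is `spikelet_rate = 0`; NMDAR
  blockade reduces `plateau_amp_mV`; TTX washout of LTP sets
  `post_scale = 1`.  No channel biophysics is simulated — the generator
  reproduces the *signal phenomenology* the analyses consume, not its
  mechanism.

What the generator deliberately does **not** emulate: trial-to-trial EPSP
amplitude variability beyond additive noise, electrode artifacts, drift,
series-resistance errors, branch-specific propagation, or stochastic
channel gating.  Passing tests therefore demonstrate that the analysis
chain is correct under its stated assumptions, not that it is robust to
every pathology of real recordings.

`make_dual_ap_session()` produces soma–dendrite AP pairs with
`amp(x) = 93.6·exp(−x/147 µm)` and `latency(x) = x/226 µm·ms⁻¹`, plus
Gaussian amplitude noise (3 mV) and latency jitter (0.05 ms).  The length
constant 147 µm is the value solving `93.6·exp(−150/λ) = 33.7`, i.e. it
reproduces the reported somatic and distal-dendritic mean amplitudes; with
a 278 µm total dendritic length it also reproduces the ~36% normalized
attenuation at 150 µm.  One AP per sweep is generated: analyses use the
first AP of a train anyway, and a single Gaussian template makes the
half-max latency exactly the configured one (half-max crossings of a
scaled template are amplitude-free).

`make_patch_sweep_set()` builds the voltage-clamp families (holding
−90 mV; Na: 100 ms prepulse −120 mV, 30 ms test 0 mV; K: 150 ms prepulse
−120/−40 mV, 200 ms test +70 mV) with a linear passive patch (leak 1 nS
reversing at holding, 0.1 pF capacitive transients) and per-site channel
peaks: Na −6.81/−5.02/−7.17 pA (soma/proximal/distal), A-type
30.4/61.5/102.3 pA, delayed rectifier a uniform 19.6 pA.  Subpulse sweeps
scale the whole command by −1/4 and contain only the passive response —
channels do not gate in that hyperpolarized range — which is exactly the
assumption the P/−4 correction relies on.

`make_ltp_cohort()` generates per-cell amplitude series directly: baseline
~N(7, 1.5²) mV, induction spike count k ~ Poisson(4.14) (the reported mean
count), LTP% = 100 + 18·k + N(0, 30²).  With Var(k) = 4.14 these defaults
give a population spike-count/LTP correlation of
`r = 18·sd(k)/sqrt(18²·4.14 + 30²) ≈ 0.77`, the reported association
strength, at the reported mean LTP (100 + 18·4.14 ≈ 175%).

## Numerical and algorithmic choices

**Derivative estimation.**  `sweep_derivative()` applies a centered moving
average of width `smooth_window_ms` and then an adjacent central
difference.  That composition is an endpoint-slope estimator across the
window, so broadband voltage noise of SD σ maps to dV/dt noise of roughly
√2·σ/W.  At the default recording noise (0.3 mV) a 0.2 ms window would
give ~1.5 mV/ms of derivative noise — the 2.5 mV/ms weak-spike criterion
would then fire thousands of times per spikelet-free session.  The default
W = 1.5 ms keeps derivative noise near 0.25 mV/ms, giving a per-session
false-event expectation far below one while attenuating a σ = 1.5 ms
spikelet's slope peak by under 10%.  Both the window and the generator's
noise model are configurable, and analyses of noise-free traces in the
test-suite use smaller windows where sub-sample timing matters.

**Event segmentation.**  Candidates are defined as one per contiguous
excursion of dV/dt at or above the weak threshold (local maxima not
separated by a dip below threshold are one event), followed by a 5 ms
minimum separation.  Both rules exist because a strong spikelet's
suprathreshold excursion spans several milliseconds at this bandwidth:
noise ripples inside the excursion, and brief threshold-grazing on its
rising flank ~2.7 ms before the peak, would otherwise double-count single
events.  Five milliseconds stays below the 10 ms intra-burst stimulus
spacing, so genuinely distinct per-stimulus events are preserved; at the
default conditions the detector recovered the inserted count exactly in
100/100 simulated cells.

**Boundary convention.**  The class ladder uses half-open intervals
(exactly 2.5 → weak, exactly 10 → strong, exactly the AP threshold → AP),
following the figure-legend form of the criterion.

**Stimulus windows.**  Each stimulus owns the window from its onset
(plus a 0.5 ms artifact blank) to the next stimulus; the last stimulus of a
sweep extends 50 ms.  Events are attributed to the window containing their
dV/dt peak.

**EPSP amplitudes.**  `epsp_amplitude_series()` measures the
baseline-subtracted peak in a 0–50 ms post-stimulus window after a 2 ms
moving average, with the 5 ms baseline ending one smoothing width before
the pulse.  The raw maximum of a noisy trace is upward-biased by the
extreme-value statistics of the noise (~0.5 mV at 0.3 mV SD), which
propagates into a systematic LTP error; measuring on a lightly smoothed
trace — the digital analogue of averaging 30 consecutive traces, as is
standard — removes it.

**Plateau amplitude** is the baseline-subtracted maximum in the 200 ms
after the burst ends, where the summed fast EPSPs have largely decayed; a
small (≲1%) contamination by residual EPSP tail is inherent to measuring
an overlapping slow envelope and is covered by the test tolerances.

**Attenuation fit.**  Performed in linear amplitude space (unweighted by
default) with an analytic log-linear initialization, making the
Levenberg–Marquardt refinement deterministic and order-invariant.  A flat
or increasing profile returns a degenerate flag (λ = ∞) rather than an
error, as does a non-positive latency slope in the velocity fit.  The
normalized variant fits the one-parameter curve `y = exp(−x'/λ')`, which
enforces y(0) = 1 by construction.

**P/−4 correction** accepts 1–4 subpulse sweeps and always scales their
mean by 4, since each subpulse is −1/4 of the test command.  Peak searches
exclude 1 ms after each clamp step (capacitive residue).  Dunn's test is
computed from pooled mean ranks with the tie-corrected variance and
Bonferroni adjustment, the convention of common analysis software; adjusted
p-values can therefore never undercut unadjusted ones.

**LTP windows.**  The baseline is the final 5 pre-induction minutes (the
closest anchor to induction and standard practice); the LTP window is
25–30 min post induction.  Pairing-protocol sessions reuse the same
computation — only the stimulus protocol differs.

**Session format.**  Sessions are a directory with a JSON sidecar and one
two-column (`time_s`, `value`) tab-separated trace table per channel.
Sample values and all time-critical numerics are printed with 17
significant digits, so write → read → write is byte-identical and sample
values round-trip exactly.

## Problem sizes used by the tests

The suite exercises the study's own scales: 56 propagation pairs with
0.05 ms jitter for velocity recovery; 7 spikelet-free TBS sessions for
detector specificity; 50 seeded propagation replicates for parameter
recovery; 20 seeds for the P/−4 and A-current nulls; 1000 null simulations
for the Kruskal–Wallis type-I rate; and 200 seeded cohorts (8 cells each,
slope 15%/spike, LTP noise 10%) for the end-to-end
simulate → detect → count → correlate sign check.  Cohort-level
simulations use induction-only sessions (the four TBS episodes without
baseline/post sweeps), since only the induction epoch feeds the spike
count.

## Worked example

```{r example, eval = FALSE}
library(gcdspike)

# one TBS experiment with four inserted spikelets
ses <- make_tbs_session(tbs_gen_config(seed = 11, n_spikelets = 4))
ex  <- session_ltp_experiment(ses)
count_induction_spikes(ex)   # 4
ltp_magnitude(ex)            # ~173% (the generator's configured LTP)

# bAP propagation across 56 paired recordings
set.seed(1)
pairs  <- make_dual_ap_session(propagation_gen_config(seed = 500002),
                               runif(56, 20, 212))
points <- propagation_points(pairs)
fit_attenuation(points)      # a0 ~ 93.6 mV, lambda ~ 147 um
fit_velocity(points)         # ~226 um/ms

# A-current isolation in a distal outside-out patch
patch <- make_patch_sweep_set(patch_gen_config(seed = 3),
                              recording_site("dendrite", 150),
                              c(ka = TRUE))
measure_component(patch, "ka")   # ~102 pA
```

## Known limitations

* The detector is a single-criterion (dV/dt) classifier; the qualitative
  "spikelet waveform" pre-screen used by human analysts has no quantitative
  published criterion and is not implemented.
* The generator's kinetic constants (EPSP rise/decay, spikelet width,
  plateau τ, depression ratio, noise SD) are free parameters chosen for
  consistency with the printed derivative and amplitude statistics — no
  noise spectra or synaptic kinetics are reported to match against.
* Realized spikelet dV/dt peaks sit a few percent below their configured
  targets (smoothing attenuation plus the underlying EPSP slope);
  class-exactness tests therefore use targets away from the 2.5 and
  10 mV/ms boundaries, and counting tests at the highest noise level use
  the spikelet-free condition, where the zero count is analytic.
* Velocity and attenuation fits assume pooled, homoscedastic scatter, as
  in the source analyses; no per-cell hierarchical model is attempted.
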