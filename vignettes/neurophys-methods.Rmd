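---
title: "Methods: models, estimators and design choices in neurophys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in neurophys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurophys)
```

`neurophys` quantifies excitability phenotypes of cultured (typically
iPSC-derived) neurons. This vignette documents the science behind each
module: the models and operational definitions, the tunable parameters with
their units and defaults, the numerical choices, and what the synthetic-data
generators do and do not emulate. Every number quoted here is produced by
the package's own code paths and checked by the test suite.

## The synthetic neuron

The generator is a single-compartment conductance-based model in the
Hodgkin–Huxley tradition. With voltage $V$ in mV, time in ms, conductances
in nS and capacitance $C$ in pF (so that $g \cdot V$ is in pA and
$(g V)/C$ in mV/ms):

$$C \frac{dV}{dt} = I_{\mathrm{inj}} - g_L (V - E_L)
  - g_{Na} m_\infty^3(V)\, h\, (V - E_{Na})
  - g_{K}\, n\, (V - E_K)
  - g_M\, w\, (V - E_K)
  - g_{BK}\, b\, (V - E_K)
  - g_{SK}\, s_\infty(\mathrm{Ca})\, (V - E_K)$$

* Na⁺ activation is instantaneous ($m_\infty$, Boltzmann midpoint −28 mV,
  slope 7 mV); inactivation $h$ relaxes with $\tau_h = 3$ ms (midpoint
  −40 mV). The inactivation midpoint is deliberately close to threshold so
  that slow ramps still elicit spikes without full accommodation.
* The delayed rectifier $n$ (midpoint 0 mV, slope 8 mV, $\tau_n = 3$ ms)
  repolarises the spike; its high midpoint keeps it silent at subthreshold
  potentials so it does not mask the excitability that the ramp protocol
  probes.
* The M-type conductance $w$ is slow ($\tau_w = 150$ ms, midpoint −35 mV)
  and non-inactivating — the subthreshold brake that M-channel blockers
  remove.
* BK is fast ($\tau_b = 1$ ms) and requires both depolarisation and Ca²⁺
  ($b_\infty$ = Boltzmann(V) × Ca/(Ca + 15)).
* SK is voltage independent and instantaneous:
  $s_\infty = \mathrm{Ca}^2 / (\mathrm{Ca}^2 + K_d^2)$, $K_d = 10$ (Ca in
  arbitrary units).
* Ca²⁺ is a single pool: each spike (upward crossing of 0 mV, 2 ms
  refractory) adds 1 unit; the pool decays with $\tau_{Ca} = 500$ ms. This
  is the minimal dynamics that gives SK a medium/slow-AHP role; it does not
  model buffering, stores, or channel-level Ca microdomains.

Defaults ($C = 30$ pF, $g_L = 1$ nS so $R_N = 1$ GΩ, $E_L = -55$ mV) were
chosen once to match the passive properties typical of young iPSC-derived
cortical neurons (high input resistance, resting potential in the −50s) and
to fire robustly under the three stimulus protocols; they are illustrative,
not fitted — no quantitative channel densities are available for these
cells, so simulator output is used only for oracle-style testing (phenotype
*directions* and closed-form limits), never as a stand-in for recorded
group-level values.

Integration is fixed-step explicit: forward Euler for $V$ and Ca,
exponential Euler for the gating variables, at `dt_ms` ≤ 0.05 ms (default
0.02 ms), with the solution sampled onto the protocol's output grid.
Reproducibility is prioritised over speed: a fixed seed yields bit-identical
traces. Divergence (non-finite voltage) raises an error naming the
offending parameters. A constant bias current holds the model at the
protocol holding potential (−65 mV), as in the recording configuration;
`clamp_holding = FALSE` disables it for zero-current (resting-potential)
sweeps.

The three protocols mirror the standard phenotyping set: a 0→80 pA / 500 ms
ramp for single-AP features, 500 ms steps (−50…+30 pA in 10 pA increments)
for input resistance, and a 50 Hz train of 25 × 2 ms suprathreshold pulses
(default 1.2 nA; some protocols use 1.4 nA, so the amplitude is a
parameter) followed by ≥ 1.2 s of silence for the post-train AHPs.

## Current-clamp feature definitions

The extractors implement operational definitions, not curve fits:

* **RMP** — mean of the first 100 ms of a stimulus-free sweep. The window
  is a package choice; "immediately after break-in" is not otherwise
  quantified.
* **Input resistance** — OLS slope of steady-state ΔV (mean over the last
  100 ms of each 500 ms step) against injected current, in MΩ. Sweeps
  containing APs are excluded with a warning; at least two (ideally three)
  distinct amplitudes are required — two points determine the same line
  exactly on an ohmic cell, and the package permits that with a warning.
* **AP detection** — local maxima above 0 mV preceded (within 2 ms) by
  dV/dt ≥ 10 mV/ms, with 2 ms minimum separation. The detection rule is a
  package choice; published pipelines rarely state theirs.
* **Threshold** — voltage at the last upward crossing of dV/dt through
  5 mV/ms before the peak, linearly interpolated between the bracketing
  samples. dV/dt uses central differences (forward/backward at the edges).
* **Amplitude / half-width** — amplitude is peak minus V_h; the half-width
  is the time between the interpolated crossings of V_h + amplitude/2.
* **fAHP** — after the peak, the 1 ms sliding mean of dV/dt is followed;
  the fAHP is the voltage where that mean first re-enters 0 ± 0.5 (taken as
  mV/ms — the criterion is dimensionless in common usage) after having been
  below −0.5, within 10 ms of the peak. If the derivative never settles the
  value is reported missing rather than guessed.
* **mAHP / sAHP** — from the train sweep, using the stimulus channel to
  locate the last pulse offset: mAHP is the most negative voltage within
  1 s of the offset minus V_h; sAHP is the voltage exactly 1 s after the
  offset (nearest sample) minus V_h. Negative values mean
  hyperpolarisation. Recordings shorter than offset + 1.2 s are rejected.
* **QC** — strict inequalities on all four gates (R_S < 30 MΩ,
  R_N > 200 MΩ, V_rest < −45 mV, amplitude > 80 mV); a cell at a boundary
  fails. Missing fields give an indeterminate result rather than a pass.

All extractors are validated against closed forms (triangle and Gaussian
spikes, exponential relaxations) and against brute-force scans of
10×-oversampled simulated traces; voltage outputs are stable to < 0.5 mV and
half-widths to < 0.1 ms under resampling between 10 and 50 kHz.

## Liquid junction potential

`compute_ljp()` evaluates the stationary Henderson equation with
diffusion-coefficient-weighted relative mobilities
$u_i = \lambda_i / (z_i^2 \lambda_K)$:

$$V_{LJ} = \frac{RT}{F}\,
  \frac{\sum_i z_i u_i (c_i^{bath} - c_i^{pip})}
       {\sum_i z_i^2 u_i (c_i^{bath} - c_i^{pip})}\,
  \ln \frac{\sum_i z_i^2 u_i c_i^{pip}}{\sum_i z_i^2 u_i c_i^{bath}}$$

and reports the **pipette-minus-bath** potential: the additive correction
for pipette-referenced recordings (for a K⁺-rich pipette facing a Na⁺-rich
bath the value is negative, and corrected potentials become more negative).
The closed form is verified in the tests against independent numerical
integration of the Nernst–Planck potential gradient along the linear mixing
path, and antisymmetry under swapping the solutions is a tested property.

The packaged mobility table (relative to $\lambda_K = 73.5$ S·cm²/mol) uses
standard limiting conductivities for the inorganic ions, 48.8 S·cm²/mol for
methylsulfate, ~22 for the HEPES anion, and documented *estimates* (0.25)
for the poorly tabulated organic polyanions (phosphocreatine²⁻, ATP²⁻,
GTP³⁻). Ionisation conventions for the shipped solutions: HEPES is 43%
anionic at pH 7.35 with the matching K⁺ from the KOH titration;
Na₂-phosphocreatine, Mg-ATP (as the Mg-buffered divalent anion) and
Na₃-GTP are fully dissociated; glucose is neutral; phosphate is entered as
H₂PO₄⁻. The default temperature is 306.65 K (33.5 °C, midpoint of a
32–35 °C bath); a room-temperature value can be passed instead.

For a ~130 mM K-methylsulfate internal against standard aCSF the computed
potential is −9.9 mV. Junction potentials quoted for such internals in the
literature span roughly −8 to −10 mV; the spread is dominated by the
assumed methylsulfate mobility (120 mM of the pipette anion — moving its
relative mobility across the physically plausible 0.6–0.8 range moves the
result by about 2 mV) and by which minor organic species are entered. The
package therefore documents its table per species rather than matching any
particular published correction value.

## MEA metrics and Poisson-surprise burst detection

Well metrics follow the standard operational definitions: active
electrodes fire ≥ 1 spike/min (an inclusive count threshold — 5 spikes in
300 s); mean firing frequency divides all spikes on active electrodes by
(active electrodes × duration); the ISI CoV is computed per active
electrode with ≥ 3 spikes and averaged unweighted across electrodes
(averaging, rather than pooling, matches the per-electrode adaptivity of
the burst detector; a pooled variant is available by flag).

Burst detection is surprise maximisation in the Legendy–Salcman style,
adaptive to each electrode's mean rate $r = n/T$:

1. seed candidate runs where consecutive ISIs fall below
   `seed_factor` (0.5) × mean ISI;
2. extend the run forward spike-by-spike while the surprise
   $S = -\ln P(N \ge n \mid \mathrm{Poisson}(r \cdot \mathrm{span}))$
   increases;
3. trim spikes from the start while $S$ increases further;
4. accept when $S \ge$ `min_surprise` (10, natural log) and the run has ≥
   `min_spikes` (3) spikes. Accepted bursts are non-overlapping, resolved
   greedily in time order.

The three knobs are configuration options because the commercial detector
this mirrors does not publish its internals; the defaults are conventional
for surprise-based detectors. Surprise values are computed on the log scale
(`ppois(..., log.p = TRUE)`), so extremely improbable runs do not
underflow; the tests require agreement with a brute-force Poisson tail sum
to 10⁻⁹ relative error. On the benchmark synthetic well (64 electrodes,
300 s, 0.5 Hz tonic firing, 6 planted bursts/min with a mean of 10 spikes
at 10 ms intervals) the detector achieves recall and precision ≥ 0.95
against the planted ground truth, with misses concentrated in 2-spike
planted bursts that the `min_spikes` rule excludes by construction.

Burst summaries: bursting electrodes have ≥ 1 burst; burst frequency =
total bursts / (bursting electrodes × duration); IBI CoV per electrode with
≥ 3 bursts, averaged; burst % = 100 × spikes inside bursts / all spikes on
active electrodes (the denominator includes non-bursting active
electrodes). Spikes in bursts plus spikes outside bursts always equals the
total — a tested conservation property.

Raw-signal spike detection band-passes at 300–5000 Hz (2nd-order
Butterworth, zero-phase), estimates noise robustly as median(|x|)/0.6745
over 10 s windows, and emits one event per ±6×RMS crossing group with 1 ms
dead time, timed at the extremum. A threshold floor at 0.1% of the filtered
signal's maximum guards the degenerate noise-free case, where the robust
RMS collapses to numerical filter residue.

The generator behind these benchmarks is a two-state renewal process —
homogeneous Poisson background plus compound bursts at Poisson onsets
(negative-binomial counts, gamma intra-burst intervals), with an enforced
refractory period — chosen for the analytic tractability of its oracles
(Poisson count statistics, exponential-ISI CoV = 1). It does not emulate
network synchrony, development over days in culture, electrode crosstalk,
or non-stationary rates; passing its benchmarks shows the detector and
metrics are correct under their own assumptions, not that biological bursts
are negative-binomial.

## Voltage-clamp analysis

The protocol is the standard one for slowly activating, non-inactivating
K⁺ currents: holding −80 mV, 1000 ms steps from −80 to +40 mV in 10 mV
increments every 20 s, then 300 ms at 0 mV for tails. Background removal is
pre-drug minus post-drug subtraction — only the blocker-sensitive current
is analysed; no leak model is fitted beyond that. Peak currents are read at
the sample nearest 999 ms into the step and tails at 5 ms into the tail
step (single nearest sample by default; an averaging window is available
since the original convention is not stated). Current density divides by
membrane capacitance; percent-of-WT divides variant and wild-type group
mean densities, with a first-order (delta-method) SEM because the
original's error propagation is unstated.

Activation kinetics are fitted as a rising saturating exponential
$I(t) = A(1 - e^{-t/\tau}) + C$ over 50–1000 ms, with data-driven initial
values ($C$ = first 5 ms of the window, $A$ = end minus start, $\tau$ =
time to 63% of the rise), $\tau$ bounded to [1, 5000] ms
(Levenberg–Marquardt via `minpack.lm`); flat traces and bound-hitting fits
are flagged unconverged rather than reported. Noiseless recovery across
τ ∈ {25, 50, 100, 200, 400} ms is exact to < 0.5%, and the median error
under 5% amplitude noise stays below 10%.

Tail-based G–V curves normalise tail magnitudes after subtracting the
smallest tail (the brief relaxation toward the tail-potential open
probability adds an identical offset to every step, isolated by the most
hyperpolarised step); the optional Boltzmann fit recovers the simulator's
midpoint within 1 mV and slope within 0.5 mV noiselessly. QC is inclusive
at its printed boundaries: seal ≥ 0.5 GΩ and series resistance ≤ 20 MΩ.

## qPCR

Relative expression uses the two-housekeeping-gene ΔCt scheme: technical
duplicates are averaged on the Ct scale, the mean of the two housekeeping
means (GPI/GAPDH) is subtracted from each target's mean Ct, and expression
is $2^{-\Delta Ct}$, optionally scaled to a reference sample per batch
(which makes the reference exactly 1 and removes between-batch scale
effects that ΔCt itself cannot — those affecting targets and housekeeping
genes differentially). No amplification-efficiency correction is applied,
matching the plain $2^{-\Delta Ct}$ convention. Shifting every assay of a
sample by a constant leaves its relative expression unchanged — a tested
invariance.

## Statistics

The tests used in this field's group comparisons are implemented
self-contained so that each can be validated against brute-force oracles:

* pooled-variance Student t test by default (the legacy-package
  convention), Welch and paired variants by flag; degenerate zero-variance
  equal-mean data give p = 1 by convention;
* one-way ANOVA (two-group F equals t² to 10⁻⁸, a tested identity);
* two-way crossed ANOVA with Type III sums of squares under sum-to-zero
  coding (matching legacy commercial defaults; Type II by flag), via QR
  model comparisons; empty cells are an error naming the cell;
* mixed-design repeated-measures ANOVA (one between-subjects factor × one
  within-subjects factor): the between effect is tested against
  subject-within-group variation, within and interaction effects against
  the subject×within residual; incomplete subjects are dropped with a
  message; no sphericity correction is applied (uncorrected degrees of
  freedom are reported, matching the conventional output), and the
  two-timepoint interaction F provably equals the squared between-group t
  on per-subject change scores;
* Fisher's protected LSD: pairwise comparisons with the omnibus error
  term, performed only when the omnibus F is significant at α; no further
  multiplicity correction, as the procedure specifies.

Null calibration is part of the acceptance suite: at α = 0.05 the empirical
type-I error over 10⁴ seeded null replicates is within 0.05 ± 0.007 for the
t test and the one- and two-way ANOVA main effects.

## Problem sizes and runtime choices

The test and acceptance suites run at deliberately modest sizes chosen to
make every oracle exact or tightly bounded: 64-electrode / 300 s synthetic
wells for detector benchmarks, 10⁴-spike trains for CoV calibration, ~100
simulated APs (at 250 kHz, decimated ×10 to the 25 kHz analysis rate) for
threshold cross-checks, 100 seeds for noisy τ recovery, and 10⁴ null
replicates for test calibration. These sizes are statements about oracle
precision, not about the package's capacity; all analysis functions are
linear (or near-linear) in the input size.

## Known limitations

* The neuron model is phenomenological: one compartment, instantaneous Na⁺
  activation, a scalar Ca pool. It reproduces phenotype directions (SK/BK
  deepen AHPs, M-current brakes excitability), not quantitative channel
  densities of any real cell line.
* The burst generator's planted "ground truth" is defined by construction;
  detector benchmarks measure agreement with that construction under the
  stated matching rule (≥ 50% overlap of the shorter interval).
* The Henderson LJP is a stationary idealised-junction result computed from
  concentrations (not activities); its absolute value inherits the
  uncertainty of the organic-anion mobilities discussed above.
* The repeated-measures ANOVA covers the single-between × single-within
  design used in this pipeline; it is not a general mixed-model engine.
* Raw MEA spike detection assumes stationary Gaussian-dominated noise
  within each 10 s window; it is not a spike sorter.
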