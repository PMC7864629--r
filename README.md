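# neurophys

Feature extraction and statistics for cellular-electrophysiology studies of
iPSC-derived neuron cultures.

Disease-modelling studies of channelopathies (for example *KCNQ2*
loss-of-function, where reduced M-current is compensated by upregulated SK/BK
K⁺ conductances) quantify neuronal phenotypes through a stereotyped pipeline:
whole-cell current-clamp measurements of action-potential (AP) and
afterhyperpolarization (AHP) properties, multi-electrode array (MEA) metrics
of spontaneous firing and bursting, drug-subtraction voltage-clamp analysis
of heterologously expressed channels, ΔΔCt quantification of gene expression,
and ANOVA-based group statistics. `neurophys` implements that pipeline as a
tested, reusable R package, together with seeded synthetic-data generators so
that every analysis stage can be exercised and validated without any
recordings.

## What the package computes

**Current clamp** (per cell, with quality-control gating):

* resting potential (mean of the first 100 ms of a zero-current sweep) and
  input resistance *R*<sub>N</sub> (OLS slope of the steady-state V–I
  relation over 500 ms steps, −50…+30 pA, in MΩ);
* AP threshold — voltage where dV/dt crosses 5 mV/ms on the rising phase;
  AP amplitude from the holding potential V<sub>h</sub> to the peak;
  half-width at V<sub>h</sub> + amplitude/2 with linear interpolation;
  fAHP — voltage where the 1 ms sliding mean of dV/dt first returns into
  0 ± 0.5 mV/ms after the spike;
* medium and slow AHP after a 50 Hz train of 25 brief suprathreshold
  pulses: mAHP = min V within 1 s of the last pulse offset − V<sub>h</sub>,
  sAHP = V(offset + 1 s) − V<sub>h</sub>;
* QC gates: R<sub>S</sub> < 30 MΩ, R<sub>N</sub> > 200 MΩ,
  V<sub>rest</sub> < −45 mV, AP amplitude > 80 mV;
* liquid junction potentials by the stationary Henderson equation,
  V<sub>LJ</sub> = (RT/F)·[Σz<sub>i</sub>u<sub>i</sub>Δc<sub>i</sub> /
  Σz<sub>i</sub>²u<sub>i</sub>Δc<sub>i</sub>]·ln(Σz<sub>i</sub>²u<sub>i</sub>c<sub>i</sub><sup>pip</sup> /
  Σz<sub>i</sub>²u<sub>i</sub>c<sub>i</sub><sup>bath</sup>), with a documented
  relative-mobility table.

**MEA metrics** (per well): active electrodes (≥ 1 spike/min), mean firing
frequency, ISI coefficient of variation, and Poisson-surprise burst
detection (Legendy–Salcman-style surprise maximisation,
S = −ln P(N ≥ n | Poisson at the electrode's mean rate), acceptance at
S ≥ 10) with burst frequency, IBI CoV, spikes/burst and burst %. Raw-signal
spike detection (300–5000 Hz Butterworth band-pass, threshold at 6× robust
noise RMS) is included for completeness.

**Voltage clamp**: pre/post drug subtraction to isolate blocker-sensitive
currents, peak currents at 999 ms and tail currents 5 ms into the 0 mV tail
step, current density (pA/pF), percent-of-WT summaries with delta-method
SEMs, single-exponential activation fits I(t) = A(1 − e^(−t/τ)) + C over
50–1000 ms, and tail-based G–V curves with Boltzmann fits.

**qPCR**: ΔCt against the averaged Ct of two housekeeping genes
(GPI/GAPDH), relative expression 2^(−ΔCt), and scaling to a reference
sample (optionally per batch).

**Statistics**: self-contained pooled-variance t tests, one-way and Type III
two-way ANOVA, mixed-design repeated-measures ANOVA, and Fisher's protected
LSD post hoc tests — each validated in the test suite against base-R
implementations and brute-force decompositions.

**Synthetic data**: a single-compartment conductance-based neuron (fast
Na⁺/delayed-rectifier spiking plus M-, BK- and SK-type K⁺ conductances and a
spike-driven Ca²⁺ pool), MEA rasters as tonic Poisson firing with planted
compound bursts (ground truth returned for benchmarking), Boltzmann-gated
voltage-clamp currents with a drug-blockable fraction, extracellular signals
with planted spike waveforms, and Ct tables with known fold changes.

## Worked example

```r
library(neurophys)

pars <- neuron_params()                      # default excitable cell
ramp <- simulate_neuron(pars, stimulus_protocol("ramp"), seed = 1)
pk <- detect_aps(ramp)
ap_threshold(ramp, pk[1])                    # -39.0 mV
ap_amplitude_halfwidth(ramp, pk[1])          # 118.9 mV, 3.84 ms
fahp(ramp, pk[1])                            # -86.6 mV

train <- simulate_neuron(pars, stimulus_protocol("pulse_train"), seed = 1)
post_burst_ahp(train)                        # mAHP -23.5 mV, sAHP -0.99 mV

sim <- simulate_mea_well(spike_train_params(seed = 42))
well_metrics(sim$raster)
#  64 active electrodes, 1.49 Hz mean firing, ISI CoV 1.99,
#  1779 bursts on 64 electrodes, 11.0 spikes/burst, burst % 68.3

compute_ljp(kmeso4_internal(), acsf_bath())  # -9.87 mV
```

The ramp sweep yields eight APs; the first fires at a −39 mV threshold with
a 119 mV amplitude from the −65 mV holding potential. The pulse train leaves
a 23.5 mV medium AHP and a ~1 mV slow AHP, and raising `g_sk_ns` deepens
both — the phenotype direction the SK conductance is expected to produce.
The synthetic MEA well (0.5 Hz tonic firing, 6 planted bursts/min) is
recovered by the surprise detector with recall and precision above 0.95
against the planted ground truth, and its ISI CoV of ~2 reflects the bursty
firing mode. The junction potential is the additive correction for
pipette-referenced potentials (a recorded −45 mV corrects to −54.9 mV).

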