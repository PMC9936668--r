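---
title: "Models and methods behind vnsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vnsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`vnsim` implements, as one tested pipeline, the computational machinery of a
mouse vagus nerve stimulation (VNS) parameter-space study: construction of
temporally patterned stimulation trains; synthesis of trial recordings (ECG
and laryngeal EMG at 5 kHz) with known ground truth; quantification of
heart-rate and evoked-EMG responses; a stochastic ganglion-gated sinoatrial
(SAN) network model of VNS-evoked bradycardia; a Ding-type force–fatigue
model of laryngeal muscle activation fitted by a neighborhood particle swarm
optimizer (PSO); a simplified myelinated-fiber recruitment model; and
sum-of-squares effect-size analysis. Everything runs on synthetic data
generated by the package itself, so every downstream stage can be verified
against a known truth without any external data.

This vignette records the models, their assumptions, the tunable parameters,
and the design decisions taken where the design was genuinely open. It
states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

# Stimulation patterns

All stimulation is delivered as symmetric, biphasic, charge-balanced pulses
of 300 µs per phase, with amplitude expressed as a multiple of the
bradycardia threshold (BCT — the amplitude producing roughly a 10 % drop in
heart rate at 20 Hz). Patterns repeat in concatenated 1 s epochs:

* **constant** — uniform pulse spacing, rate = mean pulse rate (MPR);
* **burst** — MPR pulses at the intra-burst spacing `1/frequency` at the
  start of each epoch, then silence. The burst is placed at the epoch start
  because that matches the schematic arrangement of leading pulses followed
  by silence; the epoch location of the burst was otherwise unspecified.
* **random** — MPR uniformly random onsets in one epoch, tiled across the
  window. A 1 ms minimum inter-pulse interval is enforced by rejection
  sampling; whether the in vivo random epochs enforced any floor is
  unstated, so the floor (larger than the 0.6 ms pulse) is our choice.
* **duty50** — MPR pulses compressed into the first 0.5 s of each epoch.

The factorial design crosses the rate grid {2, 5, 10, 20, 30, 40, 50, 100}
(as intra-burst frequency and MPR, keeping MPR ≤ frequency) with amplitudes
{0.8, 1.0, 1.2} × BCT: 8 constant + 28 burst = 36 temporal patterns, 108
conditions. Amplitude is carried as the dimensionless ×BCT scalar; absolute
mA is optional metadata only.

# The synthetic-trial generator

`generate_trial()` builds a two-channel recording for the 70 s protocol
(10 s baseline, 30 s stimulation, 30 s recovery; shorter protocols are
supported and all analysis windows scale with them).

**Heart rate.** The embedded trajectory is
`baseline × RSA(t) × response(t)` with baseline 450 BPM (anesthetized mice
rest at roughly 400–500 BPM), a respiratory sinus arrhythmia of fractional
depth 0.03 at 60 breaths/min, and a condition response
`HR_norm = 1 − A(amp) · S(mpr_eff)`, `S(x) = x/(x + m50)` with `m50 = 20`
pulses/s. The effective rate `mpr_eff` is the MPR multiplied by the expected
transmission fraction of the ganglion synapse evaluated on the train's
actual inter-pulse intervals (`train_transmission_fraction()`, an exact
dynamic-programming expectation), so the surface inherits the
intra-burst-frequency dependence of the synapse rather than assuming one.
Amplitude gains default to A(0.8) = 0.10, A(1.0) = 0.25, A(1.2) = 0.45 and
interpolate linearly through (0, 0). The response engages with a 1.5 s
exponential transient, comfortably inside the 5 s analysis offset. Beats
come from an integrate-to-threshold process driven by the trajectory, and
an 8 ms biphasic QRS-like wavelet is placed at each beat.

**EMG.** Each pulse deposits a stimulus artifact (0–1 ms, amplitude
proportional to ×BCT) and, unless the trial is vagotomized, an evoked
biphasic wave from 1.5 to 6 ms post-pulse. Evoked amplitude =
recruitment(amplitude) × fatigue. Recruitment is logistic in ×BCT (midpoint
0.6, scale 0.067, rebased to 0 at zero amplitude), giving onset near
0.4×BCT and near-saturation at 0.8×BCT. Fatigue uses an accumulated-drive
state `D` (unit increment per pulse, 2 s recovery time constant) with
per-pulse factor `0.6 + 0.4·exp(−D/100)`, reproducing the qualitative
decline of evoked EMG during high-rate trials; only that qualitative
decline is documented, so the parameters are generator conventions.

**Noise** is Gaussian, band-limited to 10 Hz–1 kHz with a Butterworth
filter, mirroring the acquisition band-pass; the deterministic waveforms
are generated in-band. Vagotomy is a generator switch: stimulus artifacts
remain, evoked EMG and the heart-rate response vanish.

What the generator does **not** emulate: anesthesia dynamics, BCT drift
across trials, artifact-shape variability, EMG latency jitter, reflexive
sympathetic rebound. Passing round-trip tests therefore show that the
quantification pipeline is correct and unbiased on signals with these
idealized properties — not that it is robust to every pathology of real
recordings.

# Signal quantification

Beats are the positive QRS peaks found with an adaptive threshold (half the
rolling 2 s maximum, 50 ms refractory); the published description fixes only
"positive peak of the QRS complex", so the threshold rule is ours.
Instantaneous heart rate assigns `60/RR` to each inter-beat interval's
midpoint and averages midpoints inside a centered 0.5 s window; the nominal
0.1 ms step is stored decimated to 1 ms, which leaves window means over the
analysis intervals unchanged. `HR_baseline` averages the series over the
baseline window, `HR_stim` over stimulation excluding the first 5 s, and
`HR_norm = HR_stim / HR_baseline`. Whether the published analysis averaged
the instantaneous series or per-beat rates is ambiguous; we average the
series.

Stimulus artifacts are removed by template subtraction (pulse-averaged
−1 ms…+1 ms segment, subtracted at every trigger; overlapping windows are
truncated at trigger midpoints with a warning). Evoked EMG is the average
rectified value (ARV) over 1–6 ms post-pulse (configurable up to 8 ms),
summed over all pulses and normalized per animal to the 1.0×BCT, 20 Hz
constant trial. The effect score is
`(1 − HR_norm)/(1 − HR_norm_ref) − EMG_norm`: positive favors the cardiac
(therapy proxy) response, negative the muscle (side-effect proxy) response,
and the reference condition scores exactly 0.

# The heart-rate model

Three chained stages, seeded independently so repeated runs differ only
through their seeds.

**Ganglion synapse.** One hundred phenomenological postganglionic cells
each receive the shared preganglionic train. A pulse is transmitted when a
uniform draw falls below
`p(dt) = 1.028 − 2.183·dt^(−0.7146)` (dt in ms, clamped to [0, 1]) — the
frequency-dependent failure of the vagal-to-ganglion synapse — where `dt`
is the time since the cell's previous event of any origin; intrinsic events
reset the same clock (the alternative, resetting only on stimulus-evoked
events, is not what a shared refractory mechanism would do). Fifty randomly
chosen cells also fire intrinsically: Bernoulli per 50 ms bin at a phasic
rate following a half-sine over each 1 s respiratory cycle, peak 0.6
events/bin (the published description gives only the range and the
respiratory linkage).

**ACh release.** Each postganglionic event releases 5 % of the 0.075 mM
available presynaptic store into the neuroeffector junction; junction and
extra-junctional pools exchange at 10 s⁻¹ and both are hydrolysed at
14 s⁻¹ (5 and 30 s⁻¹ selectable). The pool pair is linear, so the
standalone `simulate_ach()` solves it exactly via its eigenmodes; inside
the network integrator the same kinetics are advanced by forward Euler at
the network step.

**Pacemaker network.** The full ionic SAN cell model is out of scope; the
cell interface is pluggable and the shipped cell is a two-variable
Morris–Lecar-type relaxation oscillator (instantaneous inward current,
delayed-rectifier K, leak; parameters `gca = 4/3`, `gk = 8/3`, `gl = 2/3`
nS, `phi = 1/45`, C = 25 pF) plus a slow receptor pool: bound ACh `B`
relaxes toward junctional ACh with a 400 ms time constant —
G-protein-coupled (GIRK) activation kinetics — and gates
`I_KACh = g_KACh · B²/(B² + K²) · (V − E_K)` with `g_KACh = 6.75 nS`
(the published 0.00864 µS scaled by 25/32 pF) and `K = 0.050 mM`.
The slow pool matters: junctional ACh is impulsive (discrete quanta), and
without receptor filtering no static gate can separate sustained VNS-evoked
release from phasic intrinsic release of similar per-event size. Cells sit
on a 10×10 grid with 6 nS gap junctions between edge-sharing neighbors;
the mean firing rate of the 36 peripheral cells is read out as heart rate.

The applied current (27.445 pA) and the Hill midpoint are the two
calibration constants of the reduced cell, set so that (i) the resting
network **with** intrinsic ganglionic drive fires at 389 BPM, and (ii) the
respiration-linked intrinsic ACh release produces ≈ 0.2 % peak-to-trough
fluctuation of the network rate — the two published calibration targets of
the full model. The cell operates near the top of its oscillation window so
that added K conductance produces a graded, monotone slowing down to
quiescence (asystole under saturating ACh), which underwrites the bisection
search on ACh density.

**Amplitude as ACh density.** Stimulation amplitude enters only as the
number of the 100 cells (a seeded random subset) whose afferent carries the
VNS-evoked events; the 50 intrinsic targets receive intrinsic-evoked ACh
regardless. `calibrate_density()` matches modeled `HR_norm` across a
constant-frequency grid to a target curve by bisection on the signed mean
error (integer densities, ties to the lower density, grid-search fallback
with a warning if the response is not monotone at the endpoints). All three
stochastic elements — synapse draws, intrinsic firing, density mask — are
re-randomized across repeated runs.

**Filtering knockout.** `filtering = FALSE` makes every pulse release ACh
in every driven cell, removing the ganglion's frequency-dependent cap; the
model then overshoots bradycardia with a gap that grows with stimulation
frequency, the mechanism probed by the perturbation analysis.

**Integrator.** Fixed-step forward Euler at 0.05 ms for the network (cell
time constants are ≥ 3 ms, and halving the step does not change the
baseline rate beyond the acceptance tolerance); spike times by linear
interpolation of the −10 mV upward crossing.

# The muscle model

The Ding force–fatigue system: a normalized Ca²⁺–troponin driver `CN`
excited by each pulse with doublet enhancement
`R_i = 1 + (R0 − 1)·exp(−IPI/tau_c)`; force
`dF/dt = A·CN/(Km + CN) − F/(tau1 + tau2·CN/(Km + CN))`; and first-order
fatigue of `A`, `Km`, `tau1` driven by force with recovery constant
`tau_fat`. The driver is advanced with its exact exponential update (the
pulse-train convolution has the same time constant as the state, giving the
resonant closed form), so no step size aliases the pulses; force and
fatigue use fourth-order Runge–Kutta, default 0.1 ms (0.5 ms is the
coarsest accepted step). The model is deterministic. Force-time integrals
are normalized to the 20 Hz constant train of the same duration
(`Force_norm`), and `EMG_norm ≡ Force_norm` under the study's assumption of
a linear EMG–force relationship.

Two kinetics constants, `tau_c = 20 ms` and `R0 = 2`, are not given by the
study and are configurable defaults taken from the force-model literature.
One consequence is documented honestly: with these constants the printed
laryngeal ("PSO-identified") parameter set — whose `tau1` sits at its 2 ms
bound — produces markedly more force per pulse inside high-frequency bursts
than for isolated pulses, so its burst/constant force ratio at equal MPR is
far from 1, whereas the published quadriceps set shows the near-invariance
(≤ 3 %) that matches the in vivo EMG insensitivity to intra-burst
frequency. The unit test asserts the invariance on the set where it holds.

# The swarm fitter

100 particles in 20 fixed neighborhoods of 5; 50 iterations per run;
uniform-in-bounds initialization; patterns split 50/50 into training and
testing per run; final model = lowest total (all-pattern) RMSE across runs.
The guide rule is the three-case neighborhood scheme: the neighborhood best
is steered by the global best and the neighborhood second-best, the second
best by the best and third-best, everyone else by the best and second-best;
ranking ties break by particle index; the global best's position is frozen,
which makes the swarm minimum monotone non-increasing.

The velocity is implemented exactly as printed:
`V = rand()·(P_best1 − P) − rand()·(P_best2 − P)` with `rand()` uniform on
(0, 1.496), drawn per dimension (per-particle vs per-dimension was
unspecified). The minus sign departs from conventional PSO and there is no
inertia or personal-best term; the rule explores without tight contraction,
and on a smooth 8-dimensional convex bowl it stalls short of the minimum.
A documented `velocity_sign = "conventional"` toggle restores the
double-attraction form, which localizes the bowl minimum to well under 1 %
of each parameter range; the convexity sanity test runs under the toggle
while the default remains faithful to the printed rule — which, on the
actual fitting problem, recovers known generating parameters essentially
exactly (the parameter-recovery acceptance test). Parameters are scaled to
the unit box internally so the shared random coefficients act uniformly
across the eight heterogeneous scales, and positions are clipped to the
bounds (several published fitted values sit exactly at bounds, consistent
with clipping).

# The recruitment model

A deliberately simplified stand-in for the finite-element study; its claims
are structural, never absolute thresholds.

* **Field**: homogeneous isotropic medium (0.3 S/m) with the two cuff
  contacts modeled as annular bands on the cuff inner surface (radius
  100 µm = 90 µm nerve + 10 µm standoff; 895 µm center spacing; 200 µm
  axial width; discretized 12 × 3 equal-current point sources). The band
  representation matters: a bare point source 10 µm from the nerve creates
  a field so sharply peaked that node alignment dominates the thresholds of
  every fiber class, erasing the diameter dependence of the small fibers.
* **Fibers**: 21 Hodgkin–Huxley-style nodes (channel densities ten times
  the classic squid values, reflecting dense mammalian nodes and giving a
  robust conduction safety factor; gating accelerated ×3) joined by passive
  internodal resistances, INL = 100 × diameter, axon 0.6 × and node 0.7 ×
  the fiber diameter. A fibers 7–11 µm, B fibers 2–5 µm (truncated normals,
  two SD), uniform positions in the 90 µm cross-section, uniform
  longitudinal jitter of ±0.5 INL.
* **Thresholds**: symmetric biphasic 300 µs/phase pulse, cathode leading;
  action potentials detected as −30 mV rising crossings at 90 % of fiber
  length; bisection to 1 % with a 10 mA bound. Because intense fields near
  the contacts can annihilate the spike during the anodic phase, activation
  is not monotone in amplitude; the search therefore scans a geometric
  amplitude grid for the lowest activating point before bisecting its lower
  edge, and the returned value is the smallest activating amplitude
  (windows narrower than the grid factor 0.6 can be missed).

At the population level the model reproduces the study's central
recruitment-order structure: A-fiber threshold variance is dominated by
longitudinal node alignment (jitter), B-fiber variance by diameter, and the
two populations' threshold ranges overlap. One mechanistic caveat is
recorded: in this reduced field the B-fiber diameter effect does not have a
uniform sign per position (node alignment confounds it), so the
diameter-dominance claim is asserted on variance shares, not pointwise
ordering.

# Effect-size analysis

`variance_partition()` uses sequential (Type I) sums of squares on the
balanced synthetic design, where Type I, II and III coincide; shares are
each term's SS divided by the corrected total SS (deviations from the grand
mean) so that term shares plus the residual ("unaccounted") sum to 100 %.
Reading the normalization as raw, uncorrected SS would make shares depend
on the response's offset, so the corrected reading is fixed and documented.
Post-hoc multiple-comparison machinery is deliberately not implemented;
`ols_fit()` provides the response-versus-pattern-statistic regressions
(slope, intercept, R², F-test p-value).

# Problem sizes and reproducibility

Unit and acceptance tests run the models at reduced scale chosen as the
package's own verification sizes: shortened trial protocols (6 s baseline,
12 s stimulation) for simulation-heavy checks with the full 70 s protocol
exercised where windows matter; 10 × 30–50 s seeded runs for the resting
network statistics; 200 fibers per type for recruitment; swarm recovery
with 2 runs × 35 iterations on 2 s trains at 0.5 ms steps. Every stochastic
stage takes an explicit integer seed, and derived stage seeds keep the
ganglion draws, intrinsic firing and density masks independently
reproducible; identical configurations reproduce outputs bit for bit.

# Known limitations

* The reduced pacemaker cell preserves network-level mechanisms (graded
  cholinergic slowing, gap-junction synchronization, density-mediated
  amplitude, asystole) but none of the ionic detail of the full SAN model;
  absolute frequency–response magnitudes are calibration outcomes, not
  predictions.
* The muscle model's two unpublished kinetics constants leave the printed
  laryngeal parameter set frequency-sensitive in this implementation (see
  above).
* The recruitment field omits the cuff insulation, perineurium and
  anisotropic endoneurium; thresholds are orders of magnitude from in vivo
  BCTs by construction, and only structural claims are made.
* No sympathetic reflexes: post-stimulation tachycardia and saw-tooth
  high-MPR dynamics are outside the model, as in the study it follows.
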