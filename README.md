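# vnsim

Vagus nerve stimulation (VNS) slows the heart — the physiological proxy for
its cardiac therapeutic effect — but also activates laryngeal muscles, the
dominant side effect that limits tolerable stimulation in patients. How the
balance between the two shifts with stimulation amplitude, mean pulse rate
(MPR) and intra-burst frequency is a quantitative question about the whole
pathway: vagal efferents, frequency-dependent synaptic failure in the
intrinsic cardiac ganglia, acetylcholine handling at the sinoatrial node,
pacemaker network dynamics, and muscle force–fatigue behavior.

`vnsim` implements that pathway as a tested R package for computational
neurophysiologists and bioelectronic-medicine researchers. It provides:

* **Pulse-train construction** — constant, burst, random and duty-cycle
  patterns in 1 s epochs; the factorial design of 36 temporal patterns ×
  3 amplitudes (108 conditions); inter-pulse-frequency statistics.
* **A synthetic-trial generator** — two-channel 5 kHz recordings (ECG +
  laryngeal EMG) for the 70 s trial protocol with known ground truth:
  respiration-modulated heart rate near 450 BPM, condition-dependent
  bradycardia, per-pulse stimulus artifacts and evoked EMG with high-rate
  fatigue, optional vagotomy.
* **Signal quantification** — QRS detection, sliding-window instantaneous
  heart rate, `HR_norm = HR_stim / HR_baseline`, artifact template
  subtraction, per-pulse average rectified EMG, per-animal normalization,
  and the effect score
  `(1 − HR_norm)/(1 − HR_norm_ref) − EMG_norm`.
* **A stochastic bradycardia model** — 100 postganglionic cells gated by
  the transmission probability `p(dt) = 1.028 − 2.183·dt^−0.7146`
  (clamped to [0, 1]), three-pool ACh kinetics, and a 10×10
  gap-junction-coupled network of reduced pacemaker cells whose peripheral
  firing rate is read out as heart rate (389 BPM at rest, ~0.2 %
  respiratory fluctuation). Stimulation amplitude enters as the number of
  cells receiving VNS-evoked ACh ("ACh density"), calibrated by bisection;
  the ganglion filter can be knocked out.
* **A Ding-type force–fatigue muscle model** with normalized force-time
  integrals (`Force_norm`, the model-side `EMG_norm`), fitted by the
  study's neighborhood particle swarm optimizer (100 particles, 20
  neighborhoods, frozen global best, printed velocity rule with a
  documented conventional-sign toggle).
* **A simplified fiber-recruitment model** — A/B fiber populations with
  diameter and node-alignment jitter, band-contact extracellular fields in
  a homogeneous medium, and activation thresholds by bisection on a reduced
  myelinated cable.
* **Effect-size analysis** — sequential sum-of-squares variance partitions
  and pattern-statistic regressions.

The methods vignette (`vignettes/vnsim-methods.Rmd`) documents every model,
its assumptions, and the design decisions in detail.

## Worked example

Generate one synthetic trial (1.0×BCT, 50 Hz constant frequency), quantify
it, and compare with its embedded ground truth and with the mechanistic
model:

```r
library(vnsim)

cond  <- vns_condition(amplitude = 1.0, frequency = 50)
trial <- generate_trial(cond, response_surface(), noise_sd = 0.02, seed = 42)
q     <- quantify_trial(trial$recording)
q[, c("hr_baseline", "hr_stim", "hr_norm", "emg_sum")]
#>   hr_baseline  hr_stim   hr_norm  emg_sum
#> 1    450.1504 375.5003 0.8341665 229.8624
trial$ground_truth$target_hr_norm
#> [1] 0.834

ref <- quantify_trial(generate_trial(vns_condition(1, 20), response_surface(),
                                     noise_sd = 0.02, seed = 42)$recording)
emg_norm <- normalize_emg(q$emg_sum, ref$emg_sum)
effect_score(q$hr_norm, ref$hr_norm, emg_norm)
#> [1] -0.77

run_hr_trial(cond, density = 50, seed = 1)$hr_norm
#> [1] 0.881
```

Reading the numbers: the pipeline recovers the trial's embedded normalized
heart rate (0.834, a 17 % bradycardia) to three decimals despite noise; the
50 Hz trial evokes 2.17× the reference EMG, so its effect score is negative
(−0.77) — at this amplitude, raising the rate buys extra bradycardia at a
larger relative cost in muscle activation. The stochastic ganglion–pacemaker
model, run at ACh density 50 (the density representing 1.0×BCT), produces
an HR_norm of 0.881 for the same condition.

For the full chain — cohort synthesis, quantification, effect-size
partition, density calibration, filtering knockout and the swarm fit — see
`reproduce_trends()` with a `vnsim_config()`.

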