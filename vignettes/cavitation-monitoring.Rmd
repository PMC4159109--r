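---
title: "Monitoring cavitation emissions to predict and suppress vessel rupture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring cavitation emissions to predict and suppress vessel rupture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcdrupture)
```

## The problem

High-intensity focused ultrasound (HIFU) can occlude a blood vessel, but
the same exposure can rupture its wall. During pulsed exposure (0.5-s
insonations alternating with 0.5-s pauses, up to 300 cycles), an unfocused
passive cavitation detector (PCD) records acoustic emissions whose
spectral content reflects the bubble activity at the focus: low-frequency
(10–30 kHz) emission accompanies boiling, broadband emission
(0.3–1.1 MHz) accompanies inertial cavitation, and the subharmonic of the
3.3-MHz drive (1.65 MHz) accompanies stable cavitation. This package
implements the analysis chain that (i) quantifies those emissions per
cycle, (ii) tests how well each band predicts imminent rupture, and (iii)
closes the loop: a feedback controller that modulates exposure intensity
whenever the demodulated subharmonic level crosses a threshold.

Because the original raw PCD recordings are not deposited, all
signal-level computation is exercised against a synthetic generator whose
statistical structure matches what the analysis assumes. Everything that
*is* derivable from the published summary tables (exposure conditions,
rupture times, paired suppression outcomes) ships as plain-text fixtures
and is reproduced exactly (`reproduce_report()`).

## Spectral quantification

Each on-cycle record is reduced by segmented periodogram averaging:
non-overlapping rectangular-window segments of 5,000 samples, DFT per
segment, squared magnitudes averaged. The declared normalization is
$P[k] = \overline{|X[k]|^2}/N$: a unit sinusoid centered on bin $k_0$
contributes $N/4$ in the one-sided spectrum, and the two-sided sum equals
the mean per-segment energy (Parseval; checked to $10^{-12}$ on
deterministic input). Band levels are closed-interval sums over bin
centers, the DC bin always excluded (the preamplifier high-passes at
10 kHz); the subharmonic "band" is the single bin nearest 1.65 MHz, ties
to the lower bin. Each band level is divided by the same band's level in a
pre-insonation noise reference processed identically, giving a
time-dependent SNR in dB at 1-s resolution.

One numerical point deserves note: 5,000-sample segments at 10 MHz give
2-kHz bins, although a 10-kHz resolution is sometimes quoted for this
protocol; bin width here is always `sampling_rate / segment_length`, and
`segment_length` is configurable so either reading can be reproduced.
Windowing is rectangular with no overlap and no detrending — plain segment
DFT averaging, nothing more.

## Rupture detection and labeling

An intact vessel's flow-meter current fluctuates about ±1%; rupture is a
3% drop below the pre-sonication baseline (mean of pre-sonication samples;
first sample as fallback). The meter responds with a measured 8-s delay,
so the rupture instant is defined as 8 s before detection. Emissions
within $W = 10$ s before the rupture instant are *pre-rupture*, earlier
ones *intact-vessel*; cycles at or after the rupture instant are excluded
(the analysis stops at rupture). Synchronization is at 1-s precision —
timestamps are integer seconds. A *post hoc* sweep recomputes the ROC at
$W = 1, \dots, 20$ s.

## ROC analysis

Scores are the dB-scaled band SNR values (AUROC is invariant under the
monotone dB transform, but thresholds are then reported in dB). Every
unique score is a threshold under the rule "score ≥ θ ⇒ positive". The
AUROC is computed by the rank (Mann–Whitney) identity — the probability
that a random pre-rupture cycle outscores a random intact-vessel cycle,
ties counted half — which equals the trapezoidal area; its standard error
uses the Hanley–McNeil formula with a normal test against 0.5. The
reported operating point is the *corner threshold*, the point closest to
(FPR, TPR) = (0, 1), ties broken toward the lower threshold; PPV and NPV
come from the confusion matrix at that threshold.

## The analog monitoring chain and the controller

The suppression hardware is modeled functionally: a 1.65-MHz bandpass, the
preamplifier (gain 20,000, 10-kHz high-pass at 12 dB/octave), half-wave
rectification, a 1,063-Hz AM demodulator, and digitization at 68.6 kHz;
the controller consumes the RMS of the demodulated envelope per 0.5-s
insonation. Unpublished hardware details were fixed as conventional
choices: the bandpass is a 2nd-order Butterworth with 10% fractional
bandwidth, the demodulator a classic envelope detector (one-pole low-pass
at the stated cutoff), and the linear stages are applied zero-phase as
analytic magnitude responses on the record's spectrum (a
frequency-sampled realization of forward–backward filtering). For an
in-band tone of amplitude $A$ the envelope mean is $A\,G/\pi$ (half-wave
rectified sine), the closed form used in tests.

The controller follows the published state machine: if the cycle's RMS
exceeds the threshold (deployed value 0.06 V_RMS, derived as the corner
threshold of chain-processed labeled data minus 1.5 × the measured RMS
noise), the function-generator voltage drops 10 mVpp; after 10
consecutive below-threshold cycles it rises one step (default symmetric,
10 mVpp — the published description does not state the increase step),
clamped so the mapped intensity never exceeds the ceiling. The protocol
text gives a 21,980 W/cm² maximum while the flow-chart caption allows
24,430 W/cm²; the protocol value is the default and both are
configurable. Controller-inactive trials run the same cadence with an
infinite threshold, yielding the specified monotone ramp. Voltage maps to
acoustic power and SPTP focal intensity through the shipped six-point
calibration table: linear interpolation inside 250–325 mVpp; below
250 mVpp power extrapolates as voltage squared and intensity follows the
first tabulated intensity-per-power slope, which puts the 9,117 W/cm²
starting level at ≈192 mVpp. Energy accounting uses the 50% duty cycle:
$E = \sum_\text{cycles} P \times 0.5\,\mathrm{s}$.

## The synthetic generator

`synth_config()` holds every constant. Each record is synthesized in the
frequency domain — a complex-normal half-spectrum scaled so the white
noise floor has the configured RMS and each band-limited component carries
its variance uniformly over its (brick-wall) band, plus a deterministic
tone on the bin nearest 1.65 MHz — and inverted with a single FFT. This
gives exactly band-limited Gaussian components (convenient for closed-form
tests) and one record per FFT. Class amplitudes follow

$$A_b(t) = (\text{base}_b + \text{growth}_b\, t)
  \left(\frac{I}{I_\text{ref}}\right)^{c} J_b
  + w_b B e^{-t/\tau_B},$$

with $I_\text{ref} = 20{,}570$ W/cm², coupling $c = 2$, log-normal
cycle-to-cycle jitter $J_b$, and an initial burst $B$ decaying with
$\tau_B = 5$ s that mimics residual gas bubbles eliminated early in the
exposure — largest at low frequency and smallest in the broadband band, as
observed. The jitter is smaller for the subharmonic (sdlog 0.15) than for
the broadband class (0.3): sustained stable-cavitation emission is
steadier cycle-to-cycle than spiky collapse noise.

Rupture is a latent cumulative-dose process: each 1-s cycle adds
$\big((A_\text{sub} + 0.3\,A_\text{broad})/A_\text{ref}\big)^{3}$, and the
vessel ruptures when the dose crosses a per-trial log-normal threshold
(meanlog 13.19, sdlog 1.1) drawn once at trial start. Three modeling
choices matter here, all made once during design and documented as such:

* *Subharmonic-weighted dose.* Stable cavitation is the dominant driver of
  wall damage, with inertial cavitation secondary — the synthetic analogue
  of subharmonic emissions being the best rupture predictor.
* *Cubic dose–amplitude law.* Damage grows superlinearly with emission
  amplitude, so sustained high-amplitude cavitation is disproportionately
  harmful. This is what makes feedback control effective in the
  simulation: capping the amplitude near the threshold nearly stalls the
  dose, and controller-active trials frequently reach the 300-s limit
  unruptured, while a linear law would merely slow rupture while also
  cutting delivered energy.
* *Hazard calibration.* The threshold distribution is calibrated so that
  constant-intensity exposures at the published conditions rupture with a
  median near 45–50 s and a range of roughly 15–120 s, matching the
  published qualitative behavior (mean 51 s, range 14–133 s). No
  quantitative emission trajectories are published, so the generator's
  amplitude scales are anchored only to (i) these rupture-time statistics,
  (ii) the deployed 0.06-V_RMS chain threshold being reachable mid-ramp,
  and (iii) the qualitative band-SNR ordering.

Every trial consumes one seeded RNG stream with a documented draw order
(threshold, noise reference, then per cycle: jitters, tone phase, spectral
noise; finally flow fluctuations), so a seed reproduces a trial bit for
bit within this implementation; across implementations the seed is
portable only statistically.

What the generator does **not** emulate: nonlinear acoustic propagation,
bubble dynamics, harmonics/ultraharmonics, nonstationarity within a 0.5-s
record (amplitudes are quasi-static per cycle), vessel-type differences,
and any coupling between heating and cavitation. Passing tests therefore
demonstrate that the *pipeline* recovers the structure the generator puts
in — band ordering, pre-rupture elevation, suppression direction — not
that real tissue behaves this way.

## Problem sizes and numerical choices

The full experimental scale (0.5-s records of 5 × 10⁶ samples, 1,000
averaged segments) is supported; simulation studies use the desk scale
(`desk_config()`): 0.05-s records at 3.75 MHz (187,500 samples, 37
segments). That rate keeps the subharmonic exactly on the 750-Hz bin grid
of 5,000-sample segments — as it is on the 2-kHz grid at full scale — so
the single-bin measurement suffers no scalloping loss. The replicated
studies run 50 replicates of 6 prediction trials at the modal published
condition (21,980 W/cm²), with 0.04-s records, and 50 paired
active/inactive suppression trials with 0.05-s records (paired arms share
a seed and hence the same latent vessel). Degenerate
inputs are errors, not guesses: single-class ROC input, zero noise band
energy, sub-segment records, voltages above the calibrated range, zero
flow baselines.

## Known limitations

* The emission model is phenomenological; amplitudes, growth rates and
  the dose law are calibrated to published summary behavior, not fitted
  to raw data.
* AUROC/threshold tables from the original recordings cannot be
  reproduced numerically without those recordings; the package
  substitutes property-based recovery on synthetic data.
* The exact p-value of the signed-rank test uses the classical null
  (sign assignments on integer ranks 1..N, zeros counted in N, Pratt
  ranking for the statistic), which reproduces the published
  $T_- = 8$, $p = 0.0244$ with a zero pair present; enumeration
  conditional on the observed tied ranks would give 0.0254.
* The analog chain is zero-phase and memoryless across cycles; real
  hardware has phase response and settling behavior.
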