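---
title: "Models and methods behind cyclepop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cyclepop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cyclepop` re-implements, as a tested pipeline, the population analyses
used to ask how the two motor cortices divide labor when one arm performs
a rhythmic cycling task: single-unit lateralization statistics,
cross-hemisphere signal comparison, subspace orthogonality, trajectory
tangling, and muscle-activity decoding. This vignette documents the
models, the parameters that matter, the numerical choices, and the known
limitations. Everything stated here is computed by the package's test
suite or by `scripts/acceptance.R`; nothing is quoted from external data.

## The task and its canonical time base

Eight unimanual conditions are analyzed: performing arm (left/right) ×
cycling direction (forward/backward) × starting pedal position
(top/bottom). Trials last seven cycles at roughly 2 cycles/s. Pedal angle
is expressed in cycles with 0 at the top of the cycle, vertical hand
position `cos(2π·angle)`, and forward cycling increasing the angle; one
fixed convention is needed for alignment and for the top- versus
bottom-start control, and this is it.

**Two-step alignment.** Averaging across trials of slightly different
speed smears rhythmic responses, so trials are (1) anchored at the
completion of the first half-cycle — operationally, the first crossing of
0.5 cycles of *unsigned cumulative* pedal angle, a definition that treats
top- and bottom-start trials identically — and (2) resampled as functions
of unsigned cumulative angle over the middle six cycles onto a canonical
grid of 500 ms per cycle (0–3000 ms). Rate *values* are never altered,
only the times at which they occur. Unsigned accumulation makes backward
cycling warp identically and is immune to tiny non-monotonic jitter.
Interpolation is piecewise linear in both the angle→time and time→rate
maps, matching the linear position-to-time mapping of the canonical
grid. After alignment the warped vertical hand position is a perfect
sinusoid by construction (verified to sup-norm < 1e-3 in the tests).

**Grids and kernels.** Spike trains are convolved with a Gaussian kernel
of SD 25 ms (truncated at ±4 SD) on a 1 ms grid; "25 ms" is read as the
standard deviation, the common convention in this literature, and the
choice is isolated in a single parameter (`kernel_sd`) for sensitivity
checks. Aligned traces are downsampled to a 10 ms analysis grid: the
25 ms kernel leaves essentially no power above 50 Hz, so 10 ms sampling
is information-preserving while keeping the O(T²) tangling computation
fast. EMG is high-pass filtered at 40 Hz (zero-phase 4th-order
Butterworth — the corner frequency is prescribed, the filter family is
our choice; zero-phase avoids latency artifacts in trial averages),
rectified, and smoothed with the same Gaussian.

**Windows.** Most statistics use the middle four cycles (2–5), i.e. the
2000 ms slice starting 500 ms into the canonical window, where behavior
is steady-state and non-performing-arm muscle activity is minimal. The
top- versus bottom-start control compares cycles 2–5 of top-start
conditions with cycles 1.5–4.5 of bottom-start conditions, so both
windows cover the same pedal positions.

## The synthetic-data generator

The generator is first-class, tested code; its defaults define the
simulated study conditions.

* **Latents.** Per arm and direction, `latent_dim_per_arm` (default 4)
  latent signals: a cycle-fundamental sinusoid plus one second harmonic
  (`harmonic_weight` 0.3), with random phases shared between starting
  positions — latents are functions of absolute pedal position, so
  bottom-start responses are half-cycle-shifted copies of top-start
  responses, which is exactly what the start-position control exploits.
* **Arm subspaces.** Two unit-space bases over the unified population
  with all principal angles equal to `(1 − subspace_overlap)·90°`
  (default overlap 0.1, near-orthogonal). The latent drive is scaled by
  `sqrt(n_units/latent_dim)` so a unit's modulation does not depend on
  how many units are simulated; `rate_gain` (default 8 spikes/s) is the
  per-unit modulation scale on a 12 spikes/s baseline, and intensities
  are rectified at zero, as Poisson intensities must be.
* **Lateralization.** A unit's drive is attenuated by
  `1 − lateralization` when its ipsilateral (non-driven) arm performs
  (default 0.15, giving a mildly contralateral bias comparable to real
  motor cortex; 1 reproduces the classical strictly-lateralized picture).
* **Kinematics.** Per-trial speed is constant, drawn from a normal
  (mean 2, SD 0.15 cycles/s) truncated at ±2.5 SD — the simplest
  structure that exercises the alignment warp and the speed-split test.
  The non-performing pedal wiggles sinusoidally about the bottom of the
  cycle within ±0.02 cycles, with per-trial amplitude and frequency
  drawn at random so that its mean speed varies across trials.
  `speed_coupling` (default 0) optionally couples the firing-rate gain to
  the standardized non-performing-arm speed, providing the alternative
  hypothesis for the speed-split test.
* **EMG.** Muscles of the performing arm are rectified linear readouts of
  that arm's latents; raw voltages are simulated as intensity-modulated
  broadband noise plus additive noise (`emg_noise_sd`), so the
  preprocessing chain (high-pass, rectify, smooth) is exercised
  realistically. The non-performing arm carries an optional weak bump of
  activity near the end of the movement (`stopping_emg_amplitude`,
  default 0.1, placed in the final half-cycle); no published curve
  quantifies this "tensing when stopping" profile, so it is a free
  amplitude parameter. `emg_rectified = FALSE` moves the readout into its
  linear range for noiseless decoder-recovery tests.
* **Spiking and determinism.** Spikes are inhomogeneous Poisson (1 ms
  bins, uniform jitter within bins). A single root seed feeds named child
  streams for every stochastic sub-step, so identical configurations are
  byte-identical and re-ordering operations cannot silently change
  results.

What the generator does *not* emulate: non-Poisson count dispersion,
slow within-trial speed drift, electrode artifacts, bimanual
coordination, or any nonlinear neuron-to-muscle map. Passing tests
therefore demonstrate correctness of the *analyses* under the stated
statistical structure, not fidelity of the generator to any particular
recording.

## Single-unit statistics

Modulation is the *population* standard deviation of the concatenated
middle-cycle response (four conditions per arm); at ~800 samples the
population/sample distinction is negligible, and one documented
convention beats an ambiguous one. Response correlations are Pearson
correlations of per-condition mean-centered concatenations, so a
nonspecific rate elevation cannot masquerade as pattern similarity.
Zero-variance responses propagate as missing values, never imputed.

The shuffle null replaces each unit's driven/non-driven pair with the
driven response of one random unit and the non-driven response of
another (with replacement), 1000 times; significance means exceeding 95%
of resampled means. The meta-correlation correlates, over unit pairs and
conditions, pairwise rate correlations under one arm against the other.

The speed-split test splits a condition's trials at the median
non-performing-arm speed (ties to the lower group, a deterministic
split), compares mean rates pointwise, and flags time points whose
absolute difference exceeds 95% of 1000 random same-size splits — a
two-sided test on |Δ|; the criterion's sidedness is not prescribed
anywhere, and two-sided on the absolute difference is the conservative
reading. Conditions with fewer than eight trials are excluded. Under the
null generator the flagged fraction is 5.06% at seed 1 (120,000 points;
the acceptance script recomputes this for any seed). No
multiple-comparison correction is applied across time points: the
analysis is deliberately pointwise at 5% and compared against the chance
rate.

The Fano factor counts spikes in two 250 ms windows around the crossing
of 3.5 cycles on *unwarped* trials (a modified time base would complicate
the interpretation of count variability) and reports the OLS slope of
count variance on count mean across units × conditions × windows, with a
free intercept; a through-origin option exists, and weighting of the
regression is left as future work. The required-magnification solver
finds, by monotone bisection (validated against grid search), the factor
by which non-driven muscle modulation must be inflated for the median
muscle arm-preference index to drop to a target.

## Population geometry

Soft normalization divides each unit by its firing-rate range plus 5
(spikes/s scale) so PCA is not dominated by a few high-rate units; the
per-channel minimum is subtracted first, which pins constant channels at
zero and is invisible downstream because every analysis recenters per
condition. EMG uses plain range normalization (constant 0).

Subspaces are fit per condition by PCA of the time × unit matrix after
per-condition temporal centering. Variance capture projects a test
condition — centered by *its own* temporal mean; centering the test data
by the training mean is exposed as an option since the convention for
projections is genuinely open — onto the leading components and reports
captured fraction of the centered sum of squares, so curves from
different spaces are comparable. The triplet sweep uses every condition
as the training condition once, with the same-arm test sharing arm and
direction (opposite start) and the opposite-arm test sharing direction
and start. The neuron-count sweep repeats this on random unit subsets:
small populations bias capture estimates *away* from orthogonality,
which is why the recovery tests run at 200 units.

Tangling uses central differences (one-sided at window edges;
second-order accurate on the uniform grid), pools states across the four
conditions of an arm, fits the PCA for dimensionality reduction once per
arm's condition set, and sets ε to 10% of the total variance across the
top 8 dimensions. The case t′ = t is included in the maximum (its ratio
is zero, never the max), avoiding a special case. The implementation is
vectorized per reference state and is tested to equal an O(T²)
double-loop oracle exactly, and to be invariant to orthonormal rotations
and uniform rescalings to 1e-10. Distributions are pooled across
hemispheres into driving-cortex, non-driving-cortex and muscle groups.

*Noise sensitivity:* tangling divides squared derivative differences by
squared state differences, and trial-average noise inflates derivatives
far more than states. At desk scale (tens of units, ~20 trials) cortical
tangling is therefore noise-dominated and can exceed muscle tangling;
the expected ordering (muscles well above cortex) emerges at ~200 units
and ≥25 trials, or immediately on the generator's noise-free tensors.
Tests of the ordering use those regimes.

## Decoding

Generalization is quantified as population variance explained,
`R² = 1 − ‖Y − Ŷ‖²_F / ‖Y‖²_F`, on per-condition-centered targets: 1 for
perfect prediction, exactly 0 for the zero prediction, negative when
worse than predicting zero.

The muscle decoder is PLS2 regression implemented as SIMPLS; any
standard deflation variant is acceptable because the rank is selected by
validation R², and the variant is recorded in the model's provenance
(the full-rank solution matches least squares, and predictions match an
independent NIPALS implementation on univariate targets). Training uses
the condition sharing arm and direction with the test condition but the
opposite starting position; validation is cycle 2 of the test condition
(the first middle cycle — the specific validation cycle is not
prescribed, only that it is one cycle of the test condition); testing
uses the remaining middle cycles. Rank candidates run 1..min(20, units,
4 × muscles). Test-time centering uses the test condition's own temporal
mean — per-condition means are not decodable by a linear map fit
elsewhere, so this is recorded in provenance rather than hidden.

The cross-hemisphere signal comparison regresses the driving cortex on
the top PCs of the non-driving cortex (ranks 1–10) and, for reference,
on leave-one-out PCs of itself; PLS would predict equally well here but
its scale robustness would obscure exactly the magnitude differences the
comparison is designed to expose, hence principal-components regression.
The label-shuffle test reassigns units to hemispheres 100 times and
deems the self-minus-cross gap significant if it exceeds 95 of 100
resampled gaps. Perturbation controls — reconstructing the source
without its first PC, or halving PCs 1–2 while doubling PCs 3–4 —
verify that the comparison does detect missing or rescaled signals.

Wrong-arm generalization trains decoders of each arm's muscles on the
whole two-hemisphere population using performing-arm conditions only
(`train_performing`) or the matching pair of performing and
non-performing conditions (`train_both`), then measures decoded
modulation when the other arm performs. With orthogonal ground-truth
subspaces, decoded wrong-arm modulation stays below 15% of performing-arm
modulation at 200 units and 30 trials, and `train_both` reduces it
further; the residual comes from the soft-normalization diagonal (which
slightly tilts the two subspaces toward each other) and from Poisson
noise passing through the decoder weights. Decoded arm-preference
distributions are right-shifted relative to the units' own — the
decoder, not the neurons, is lateralized.

## Estimator biases worth knowing

* Trial-average noise puts a floor under modulation estimates, biasing
  arm-preference indices toward zero; with full lateralization the
  noise-free index is exactly 1 while a 10-trial Poisson session yields
  a median near 0.4. Comparisons between units and muscles are
  unaffected in direction but absolute indices depend on trial counts.
* Variance-capture estimates are biased upward (toward overlap) at small
  unit counts; use `neuron_count_sweep()` before interpreting absolute
  capture numbers.
* Tangling magnitudes are comparable only within a fixed preprocessing
  and population-size regime (see above).

## Problem sizes

The shipped tests simulate sessions of 4–200 units and 8–30 trials per
condition; the calibration benchmark uses 50 units × 8 conditions × 30
trials with 1000 permutations, and the subspace/decoder recovery tests
use 200 units. These sizes were chosen so that every statistical claim
is tested in a regime where its expected behavior is unambiguous.

## Interfaces

Sessions serialize to a plain-text directory (`session.json`,
`spikes.csv`, `traces.csv`, `ground_truth.json`) and read back with
`read_session()`. `run_all()` orchestrates simulate → preprocess → unit
statistics → population geometry → decoding from one `run_config()` in
which every default (25 ms kernel, soft-norm constant 5, 8 tangling
dimensions, ε = 10%, 1000 permutations, 100 shuffles, cycles 2–5)
appears explicitly; outputs are CSV/JSON with an MD5 manifest, and
`summarize_run()` produces a single summary document. Rate tensors are
exported as long-format CSV. The exported functions plus
`scripts/acceptance.R` are the package's command-line surface.
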