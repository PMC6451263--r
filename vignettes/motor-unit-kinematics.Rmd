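---
title: "Decoding wrist kinematics from motor unit discharge timings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding wrist kinematics from motor unit discharge timings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Proportional myoelectric control maps muscle activity to continuous joint
commands. The classical route extracts time-domain (TD) features — root mean
square, slope sign changes, zero crossings, waveform length — from the
interference surface EMG and regresses them onto kinematics. High-density
surface EMG can instead be decomposed into the discharge timings of
individual motor units, giving direct access to the neural drive. This
package implements and compares both routes for the three degrees of freedom
(DoFs) of the wrist — flexion/extension, pronation/supination, ulnar/radial
deviation — together with a physiologically motivated dimensionality
reduction of the motor unit population activity, on a built-in motor neuron
pool / surface EMG simulator.

## The model

Motor neurons of one pool share a large fraction of their synaptic input
(common drive). Each unit's windowed spike count `x_ij` (unit `j`, DoF pool
`i`) is therefore a noisy, nonlinearly thresholded view of one underlying
activation. The package models the inverse view linearly,

    alpha_ij^r = slope_ij * x_ij^r + intercept_ij ,

fitted per unit by iteratively reweighted least squares with the Tukey
bisquare weight (tuning constant 4.685, robust scale = median(|r|)/0.6745,
at most 50 iterations, relative tolerance 1e-8) against the joint angle of
the DoF the unit is assigned to. Units are assigned to the DoF whose
window-averaged angle has the highest absolute Pearson correlation with
their count series (sign retained); units with assignment correlation below
0.2 in magnitude are treated as unassignable noise and excluded.

The per-DoF activation is then the recursive median

    a_i^r = median(alpha_i1^r, ..., alpha_in^r, a_i^{r-1}) ,    a_i^0 = 0,

with the even-cardinality median defined as the mean of the central order
pair (this keeps the operator continuous in its inputs). The median makes
the pooled activation insensitive to gross errors in up to `floor((n-1)/2)`
units at a time — precisely the kind of damage EMG decomposition errors
cause — and the previous-activation term promotes smoothness. The three
activations, concatenated with PCA-reduced TD features of the *residual*
EMG (recorded EMG minus the spike-triggered-average reconstruction of the
decomposed units), form the proposed feature set. Ordinary least squares
maps features to the three joint angles; the final estimate per DoF is the
median of three consecutive regression outputs.

Four feature sets are compared under identical conditions:

* `TD` — interference-EMG time-domain features, PCA at 98% variance;
* `AM2` — windowed decomposed spike counts (DSC), PCA at 98%;
* `AM1` — DSC plus residual-EMG TD features, one joint PCA;
* `PROPOSED` — the model-based reduction above plus residual features.

## Windowing, filtering, thresholds

All features share one windowing: 100 ms windows advanced every 90 ms
(205 and 184 samples at 2048 Hz; sample counts are `round(seconds * fs)`).
EMG is band-passed 20–500 Hz with a 5th-order Butterworth high-/low-pass
cascade applied forward-backward (zero phase). Channels whose RMS deviates
from the median channel RMS by more than 5x in either direction are masked.
ZC/SSC amplitude thresholds are estimated per channel from rest-period
signal as 3 times the robust SD (1.4826·MAD), clipped at 10% of the
channel's full scale; the SSC threshold is the square of the ZC threshold
because the SSC comparison `(x_k - x_{k-1})(x_k - x_{k+1}) >= thr` lives in
squared signal units (the comparison additionally requires a strictly
positive product, so a zero threshold still demands a true slope reversal).
PCA bases are fitted on z-scored training features (training-set statistics;
features have heterogeneous units, so standardization is required) and keep
the smallest component count whose cumulative explained variance reaches
98%.

## The simulator

The generator emulates the study protocol: per DoF, triangular single-DoF
cues (neutral → +60° → neutral, rest, neutral → −60° → neutral), three
trials per DoF, ramp legs of 5, 2.5 or 1 s, 2 s rests, 2048 Hz, one 8x8
electrode grid. Six direction-specific agonist pools (30 units each by
default) receive a common drive equal to the rectified normalized cue
angle; 5% of units also receive the drive of a pool of another DoF,
emulating the few multi-DoF units seen in real decompositions. Recruitment
thresholds follow a geometric ladder spanning a 30-fold range; firing rates
rise linearly from 8 discharges/s at recruitment with 30 (discharges/s) per
unit drive, saturating at 35/s; inter-spike intervals are Gaussian with CoV
0.15 and a 1 ms refractory floor. Each unit contributes a randomized
biphasic/triphasic MUAP whose channel amplitudes decay as a Gaussian of
grid distance from the unit territory (decay SD 1.5 electrodes) and whose
peak amplitude grows with recruitment threshold. Channel-mean SNR during
activity defaults to 15 dB (typical of good surface recordings); the
recorded kinematics carry 1° RMS of slowly varying sensor noise (2 Hz
knots, linearly interpolated), emulating the nonzero resting output of
inertial motion capture. Decomposition errors are modelled as independent
spike deletions, homogeneous false-positive insertion per unit, and
detection of only a threshold-biased subset of units.

What the simulator does *not* model — and what passing tests therefore do
not show about real data: electrode shift, fatigue, EMG nonstationarity,
volume-conductor anatomy, correlated or bursty decomposition failures
(merged/split sources), and co-contraction. Interference-EMG features are
substantially *easier* in this synthetic world than in real dynamic
recordings; see "Known limitations" below.

## Cross-validation and scoring

Evaluation follows repeated three-fold leave-one-ramp-out cross-validation:
per fold, one trial of every DoF is held out and every stage parameter
(channel mask, thresholds, STA templates, PCA bases, unit assignments,
g-functions, regression weights) is refitted on the remaining two trials
only; three folds test every trial once and repeats rerandomize the
assignment. Trial spans are separated at the midpoints of inter-trial
rests, so rest periods belong to both training and testing traces. The
regression target for a window is the mean recorded angle over that
window. Accuracy is the per-DoF coefficient of determination
`R^2 = 1 - SS_res/SS_tot` about the test-trace mean (which normalizes the
different ranges of motion), averaged over DoFs; zero-variance DoFs are
excluded as undefined. Paired comparisons between feature sets are
reported as mean deltas with an exact sign test — a descriptive summary,
deliberately short of a full ANOVA.

## Numerical and design choices

* **Robust-fit windows.** Each unit's g is fitted on the training windows
  of its assigned DoF's *ramp episodes*. Including all training windows
  (or even whole own-DoF trials at the fastest speed) puts more than half
  of the fitting data at an exact (count 0, angle ≈ 0) point; the robust
  MAD scale then collapses onto that cluster and the bisquare weights
  reject every informative ramp window, driving fitted slopes to zero.
  On episode windows the count-zero samples of the antagonist direction
  carry high angle variance, so the bisquare rejects *them* — the intended
  behaviour. The same degeneracy motivates the simulated kinematic sensor
  noise: ideal, exactly-zero rest angles are an artifact no inertial
  motion-capture system produces.
* **Template alignment.** A discharge index marks the template's
  peak-energy sample; simulator waveforms are cropped so this sample sits
  at the template centre, and spike-triggered averaging uses the same
  offset, making STA recovery exact on noiseless non-overlapping data.
  Template support defaults to 25 ms (51 samples at 2048 Hz).
* **Unit matching.** Cross-correlation is evaluated on the concatenated
  admissible channels (peak amplitude above 1.25x the rest-estimated noise
  SD on either template) over lags up to half the template length; the
  signed value at the lag of maximal magnitude is reported, so a
  shape-inverted template reports its negative correlation rather than an
  incidental positive side lobe. Matching is transitive-closure over pairs
  above 0.8, merged in order of decreasing correlation. On simulated
  sessions unit identities are global, so matching is exercised by its own
  tests rather than by the main pipeline.
* **Degenerate inputs.** Constant features get unit scale in
  standardization (and contribute nothing); constant count series make a
  unit unassignable; rank-deficient regression designs fall back to the
  minimum-norm solution with a warning; empty activation pools emit the
  initialization constant and are flagged.
* **Problem sizes.** The built-in studies use the full protocol scale
  (3 DoFs x 3 trials x 3 speeds, 30 units per pool, 64 channels) for the
  clean parameter-recovery study, and ten seeded 1 s-ramp sessions with
  two CV repeats for the corrupted-decomposition study — the fastest speed
  is where decomposition errors matter most and where the decomposed
  population is largest.

## Known limitations

* In this simulator the interference EMG is stationary, the MUAP shapes are
  stable, and noise is white: TD features therefore decode close to their
  theoretical best and can match or exceed the neural sets — unlike real
  dynamic recordings, where nonstationarity degrades TD features and
  favours the decomposition-based sets.
* The corruption model uses *independent* spike deletions and insertions.
  Linear decoders average such noise out efficiently, so the median
  pooling's robustness advantage (designed for structured, unit-level
  decomposition failures) appears only weakly under this error model.
* The linear g underestimates activation at the extremes of the count
  range (rate saturation) and cannot represent the antagonist direction of
  a unit's DoF; the median across a mixed flexor/extensor pool compresses
  the activation scale, which the final regression rescales.
* Single-DoF cues only; simultaneous multi-DoF movements are out of scope.
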