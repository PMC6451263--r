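# mukin — wrist kinematics decoding from motor unit discharge timings

`mukin` is an R package for neural-interfacing myocontrol research. It
predicts the joint angles of the three wrist degrees of freedom (DoFs —
flexion/extension, pronation/supination, ulnar/radial deviation) from the
discharge timings of motor units identified by high-density surface EMG
decomposition, and compares this *neural* route against classical
interference-EMG time-domain (TD) features under a repeated three-fold
leave-one-ramp-out cross-validation. Everything runs end to end on a
built-in motor neuron pool / surface EMG simulator, so no external
recordings are required.

## The method

Motor neurons of a pool share a large part of their synaptic input (common
drive), so each unit's discharge pattern is a noisy view of one underlying
activation. For each unit *j* assigned to DoF *i*, a linear map from its
windowed spike count `x_ij` to the joint angle is fitted by robust
regression (iteratively reweighted least squares with the Tukey bisquare
weight, tuning constant 4.685):

    alpha_ij = g_ij(x_ij) = slope_ij * x_ij + intercept_ij

Units are assigned to the DoF whose angle their counts correlate with most
(in absolute value). The per-DoF activation is then pooled with a recursive
median over the unit proxies and the previous activation,

    a_i^r = median(alpha_i1, ..., alpha_in, a_i^{r-1}),

which is robust to gross errors in up to `floor((n-1)/2)` units — the
damage pattern EMG decomposition errors produce — and promotes smoothness.
The three activations plus PCA-reduced TD features of the residual EMG
(recording minus the spike-triggered-average reconstruction of the
decomposed units) feed an ordinary least-squares regression onto the three
angles; each output is smoothed by the median of three consecutive
estimates and scored per DoF with `R^2 = 1 - SS_res/SS_tot`.

Four feature sets are compared: `TD` (interference-EMG features + PCA),
`AM2` (decomposed spike counts + PCA), `AM1` (spike counts + residual
features, joint PCA) and `PROPOSED` (the model-based reduction above).

## Worked example

Simulate a small session (1 s triangular ramps, 3 trials per DoF, 10 units
per direction pool on a 4x4 grid), train the proposed decoder on two trials
per DoF and score the held-out trials:

```r
library(mukin)

s <- sim_session(ramp_duration = 1, n_trials = 3, units_per_pool = 10,
                 grid_shape = c(4, 4), sample_rate = 1024, seed = 7)
s
#> <mu_session> 1 s ramps, 3 trials/DoF, 60 units, 4 x 4 grid, 79872 samples @ 1024 Hz
#>   decomposed trains: 60 units (ground_truth)

dec <- fit_decoder(s, kind = "PROPOSED",
                   train_trials = c("d1t1","d1t2","d2t1","d2t2","d3t1","d3t2"))
dec
#> <mu_decoder> kind=PROPOSED, 42 features -> 3 DoF, trained on 6 trials
#>   activation model: 60 units across pools (20/21/19)

pred <- predict(dec, trials = c("d1t3", "d2t3", "d3t3"))
r2 <- r_squared(pred, dec$targets[attr(pred, "rows"), ])
r2$per_dof
#> 0.887, 0.870, 0.924   (mean 0.894)
```

The decoder tracks the held-out triangular ramps with R² around 0.89 —
i.e. ~89% of the held-out angle variance is explained. The full
cross-validated comparison:

```r
rep <- run_comparison(s, kinds = c("TD", "AM2", "PROPOSED"),
                      repeats = 2, seed = 1)
summary(rep)
#>       kind ramp_duration_s   mean_r2       sd_r2 n_cells
#> 1      AM2               1 0.9603742 0.005661866      18
#> 2 PROPOSED               1 0.8982381 0.023991078      18
#> 3       TD               1 0.4512555 0.121238448      18
```

(On this deliberately tiny 16-channel session the TD set is starved for
spatial information; at the full 64-channel scale it is far stronger — see
the studies below.) `compare_kinds(rep, "PROPOSED", "TD")` gives paired
deltas with a sign test, and `plot(rep)` draws the R² distributions.

Sessions can be written to and read from an open on-disk layout
(`write_session()` / `read_session()`: float32 EMG with a text sidecar,
CSV spikes/kinematics/segmentation, JSON manifest), and `exec/mukin`
provides `simulate` and `evaluate` subcommands over the same functions.

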