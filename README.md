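# gaitfbf

Heading-invariant gait phase recognition from wearable inertial sensors.

Gait analysis with body-worn IMUs runs into two reproducibility problems:
the sensors report everything relative to a fixed global frame, so the data
change whenever the subject walks in a different direction, and they change
again whenever a sensor is strapped on at a slightly different angle. This
package implements a recognition pipeline that removes both dependencies
geometrically before any learning happens, then classifies the four
sub-phases of the gait cycle — swing (SW, 5), heel strike (HS, 4), full
contact (FC, 3) and heel off (HO, 2) — with a bidirectional LSTM. It is
aimed at researchers in movement science and wearable sensing who need
direction-robust phase labels from waist/shank/foot IMUs plus a 3-channel
FSR insole for ground truth.

## Method in brief

1. **Stand–stoop calibration.** Averaged waist orientations of a standing
   and a stooping pose give the gesture rotation
   `Q = R_stoop %*% t(R_stand)`; its horizontal rotation axis is the
   mediolateral axis `k`, the forward axis is `x = k × z`, and
   `R_Bf = [x k z]` is the body-fixed frame. Each sensor `j` gets the
   alignment `R_C,j = t(R_j,stand) %*% R_Bf`.
2. **Floating body-fixed frame.** The waist sensor carries the frame along
   as the subject turns: `R_FBf(t) = R_waist(t) %*% t(R_waist,stand) %*% R_Bf`.
   Distal streams re-expressed as `t(R_FBf) %*% R %*% {R_C | a | ω}` are
   identical under any heading offset and any sensor mounting — the package
   asserts both at 1e-9 on noiseless synthetic sessions.
3. **Preprocessing.** Gaussian noise-injection augmentation
   (`σ_j = 0.10 · (max|x_j| − |mean_j|)`, factor 15), per-feature
   standardization (population σ, fitted on training data only), and a
   sliding-window label-overlapping encoder (14-sample windows labeled only
   when their last N = 4/7/10 sample labels agree, for overlap ratios
   0.3/0.5/0.7).
4. **Classifier.** Stacked bidirectional LSTM → dropout → dense
   (tanh/LeakyReLU) → 4-way softmax, trained by BPTT with Adam/Nadam/AdamW
   (implemented natively in R, gradient-checked against finite differences).
5. **Hyperparameter selection.** An L18(2¹×3⁷) orthogonal array over eight
   design parameters with level-average analysis; the bundled array ships
   with the reference per-run accuracies.

A synthetic gait simulator (IMU + insole contacts + calibration gesture,
with controllable heading, cadence, speed, mounting and noise) makes the
entire pipeline testable without recorded subjects.

## Worked example

Select the optimal hyperparameters from the bundled orthogonal-array study:

```r
library(gaitfbf)
tab <- build_l18(with_accuracy = TRUE)
level_average(tab)
#> Level-average analysis
#>   activation     74.90 / 79.49  -> level 2 (LeakyReLU)
#>   overlap_ratio  77.99 / 77.00 / 76.60  -> level 1 (0.3)
#>   layers         77.99 / 76.60 / 76.99  -> level 1 (1)
#>   optimizer      77.56 / 76.70 / 77.33  -> level 1 (Adam)
#>   hidden_units   76.97 / 77.55 / 77.07  -> level 2 (64)
#>   learning_rate  77.33 / 76.81 / 77.44  -> level 3 (0.003)
#>   dropout        76.66 / 78.42 / 76.50  -> level 2 (0.5)
#>   batch_size     76.84 / 76.66 / 78.09  -> level 3 (7000)
```

Each line shows the mean test accuracy over the runs at each level of one
factor; the argmax per factor assembles the optimal combination
(`optimal_hyper_params()`). A model at 86.43% total accuracy sits at 122%
of the worst array run (71.10%) and 105% of the best (82.66%):

```r
improvement_ratios(86.43, tab$accuracy)
#> vs_worst  vs_best
#>      122      105
```

Train and evaluate on synthetic sessions whose headings differ by 90°:

```r
pc <- pipeline_config(
  train = sim_config(duration = 40, noise_accel = 0, noise_gyro = 0, seed = 21),
  test  = sim_config(duration = 20, noise_accel = 0, noise_gyro = 0,
                     heading = pi / 2, seed = 22),
  stride = 3L, hyper = optimal_hyper_params(epochs = 25L, seed = 7L),
  batch_size = 140L)
res <- run_pipeline(pc)
res$report
#> Gait phase evaluation (rows: truth, cols: prediction)
#>     SW HS  FC HO
#> SW 248  0   0  0
#> HS   0 80   0  0
#> FC   0  0 184  0
#> HO   0  0   0 85
#> Per-phase accuracy [%]: SW=100.00  HS=100.00  FC=100.00  HO=100.00
#> Total accuracy: 100.00%
```

With `use_fbf = FALSE` (raw global-frame features) the same experiment
drops to ~50–56% — the cost of heading dependence the floating frame
removes. On noiseless synthetic gait the phases are far more separable
than in real recordings, hence the 100%.

A command-line wrapper is included
(`inst/scripts/gaitfbf <simulate|calibrate|preprocess|train|evaluate|taguchi|run>`),
with YAML configs and JSON reports; see `?gait_cli`.

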