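# gaitTFS

Gait trajectory prediction from plantar force for lower-limb exoskeleton
control: an R implementation of the TFSformer network — a
convolution/transformer hybrid with variational mode decomposition (VMD) —
plus the full pipeline around it.

## The problem

Exoskeleton controllers need the wearer's joint angles slightly ahead of
what sensors deliver. Plantar force is phase-locked to the gait cycle and
easy to measure at the feet, so the task is: from the previous `n = 32`
samples of bilateral three-axis plantar force

    F_t = (f1x, f1y, f1z, f2x, f2y, f2z)'   [N]

predict the next `k` in {1, 3, 6} samples of the four sagittal joint
angles

    Q_t = (q1, q2, q3, q4)'                 [rad]

(left hip, left knee, right hip, right knee; flexion positive). Angles
come from sagittal markers by two-link inverse kinematics,

    q1 = atan((xk - xh) / (zh - zk)),
    q2 = q1 - atan((xa - xk) / (zk - za)).

## What is inside

* **TFSformer** (`build_tfsformer`): a 1-D-convolutional dual-dimension
  encoder — convolutions along the force-space axis with temporal channels
  32→64→128→256, then along the temporal axis with force-space channels
  6→36→108→256, with kernel-1 residual projections, ReLU and batch norm —
  feeding a decoder that consumes the VMD modes of the window (K = 3 per
  channel), expands them to a 256×256 stream, applies multi-head
  self-attention and four multi-channel attention blocks (channels
  8→16→32→64, (3,3) conv-produced Q/K/V, one attention head per channel,
  (2,2)/stride-2 max pooling between blocks), then a feed-forward stack
  (inner widths 1024, 256) and a linear head to `k × 4`.
* **VMD** (`vmd_decompose`): the frequency-domain ADMM — Wiener-like mode
  updates, power-centroid centre frequencies, optional dual ascent —
  written from scratch, with mirror-extension boundary handling.
* **Preprocessing** (`fill_small_gaps`, `reject_corrupt_segments`,
  `lowpass_filter`, `make_windows`, `joint_angles_from_markers`):
  cubic-spline gap filling (runs ≤ 5 samples), robust-z segment rejection,
  4th-order zero-phase Butterworth low-pass, stride-1 moving-window
  division (`L − n − k + 1` windows).
* **Baselines** (`build_baseline`): CNN, vanilla mask-free transformer,
  CNN-transformer — all trained by the same harness (`train_model`: AdamW,
  lr 1e-4, batch 32, MAE loss, subject-held-out test split).
* **Synthetic gait generator** (`simulate_cohort`, `generate_dataset`):
  phase-locked angle waveforms, alternating-stance double-bump forces,
  per-subject variation and sensor noise, markers produced by forward
  kinematics — so the whole pipeline is testable without the private
  motion-capture dataset the method was originally built on.
* A small compiled core (RcppArmadillo) for batched attention and 2-D
  convolution; everything else is base R over BLAS.

## Worked example

Decompose a two-tone signal and check the recovered centre frequencies:

```r
library(gaitTFS)
t <- 0:1023
s <- sin(2 * pi * 0.03 * t) + sin(2 * pi * 0.15 * t)
vmd_decompose(s, vmd_config(K = 2))
#> VMD result: 2 modes over 1024 samples
#>   centre frequencies (cycles/sample): 0.02997, 0.1501
#>   iterations 16, relative residual 0.0713
```

The two tones are recovered to 0.1% and 0.07%; the residual is boundary
ringing (the central 80% of the window reconstructs to 0.02%), and drops
to ~1% with the constraint-enforcing dual-ascent variant (`tau > 0`).

Train the scaled network on a synthetic cohort and evaluate on three
held-out subjects:

```r
cohort <- simulate_cohort(6, duration = 6, sampling_rate = 100,
                          master_seed = derive_seed(7, "simulate"))
ds  <- dataset_from_cohort(cohort, n = 32, k = 1,
                           seed = derive_seed(7, "split"))
mod <- build_tfsformer(model_config(k = 1, width_multiplier = 0.25),
                       seed = derive_seed(7, "init"))
fit <- train_model(mod, ds, train_config(max_epochs = 20,
                                         seed = derive_seed(7, "train")))
evaluate_model(fit$model, ds)
#>          Hl      Hr      Kl      Kr       M
#> MAE 0.08031 0.08294 0.08652 0.07396 0.08093
#> MSE 0.01098 0.01080 0.01421 0.01160 0.01190
constant_mean_report(ds)$mae[["M"]]
#> [1] 0.2463582
```

A ~77k-parameter width-0.25 model reaches 0.081 rad mean test MAE on
subjects it never saw — a third of the constant-mean reference (0.246
rad). The run takes a few minutes on one CPU. `run_experiment()` drives
the full models × tasks grid and writes a comparison report plus a
reproducibility manifest; `inst/cli/gaittfs.R` exposes
`simulate | preprocess | vmd | train | evaluate | run` subcommands.

## Scope

Sagittal hip/knee angles only (no ankle, no 3-D kinematics, no C3D
parsing); the synthetic generator is a structural stand-in, not a
physiological model — see `vignettes/gait-prediction-methods.Rmd` for the
model details, design decisions and limitations.
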