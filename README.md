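# t1forge

Multi-contrast 3D Beltrami denoising and saturation-recovery T1 mapping for
quantitative cardiac MRI.

## What problem this solves

Saturation-recovery T1 mapping (SASHA-type acquisitions) estimates the
spin–lattice relaxation time T1 per voxel from `n` co-registered T1-weighted
volumes acquired at different delays `TS` after a saturation pulse, plus one
unprepared (fully recovered) image. The method is accurate but
noise-sensitive: the recovery curve's low dynamic range amplifies image
noise into T1 variability, so maps are precise only at the cost of
resolution or scan time.

`t1forge` is for researchers developing or evaluating such protocols. Its
core is an edge-preserving denoiser applied to the T1-weighted stack before
fitting: the denoised volumes $m_i$ minimize

```
sum_i ||m_i - d_i||^2  +  lambda * sum_v sqrt( 1 + beta^2 * sum_i |grad_w m_i(v)|^2 )
```

a data-fidelity term per contrast plus one coupled Beltrami regularizer per
voxel, whose inner sum over all contrasts enforces common edge information
across the recovery series. `grad_w m = w(m) * grad(m)` with
`w = exp(-|grad m|^2 / h^2)` shields sharp transitions from the penalty and
is refreshed during optimization. The energy is minimized with a
Chambolle–Pock primal–dual hybrid gradient (PDHG) scheme; defaults are
`lambda = 0.25`, `h = 5`, `beta = 1`. Downstream, each voxel's curve is
fitted with the standard three-parameter model
`S(TS) = A * (1 - B * exp(-TS/T1))` (the unprepared image entering as the
`TS -> infinity` asymptote), and evaluation utilities report per-ROI mean/SD
(accuracy/precision), Bland–Altman agreement, and a simplified AHA
16-segment summary. A phantom generator with known ground truth makes the
whole chain testable end to end; see the methods vignette
(`vignettes/t1forge-methods.Rmd`) for the model, assumptions and design
choices.

## Worked example

Simulate the nine-vial phantom (T1 log-spaced 250–1500 ms, eight saturation
times in 100–700 ms plus an unprepared image, 1.4 × 1.4 × 8 mm voxels,
Gaussian noise at SNR 100), then fit T1 maps from the same noisy stacks
before and after denoising, three replicates:

```r
library(t1forge)
cfg <- experiment_config(seeds = 1:3)
exp <- run_paired_experiment(cfg)
exp
#> <paired_experiment> 3 replicates, 9 ROIs
#>   precision improved in 9/9 ROIs; max |bias change| 0.34 ms
#>   Bland-Altman denoised vs raw: bias -0.10 ms, LoA [-0.50, 0.29]

exp$aggregate[, c("label", "truth_t1_ms", "mean_sd_raw_ms",
                  "mean_sd_denoised_ms", "bias_change_ms")]
#>   label truth_t1_ms mean_sd_raw_ms mean_sd_denoised_ms bias_change_ms
#> 1     1         250           9.74                7.90        0.00529
#> 2     2         313          10.91                8.88       -0.04857
#> 3     3         391          12.26                9.82       -0.04249
#> 4     4         489          14.95               12.01       -0.02655
#> 5     5         612          17.99               14.57       -0.13092
#> 6     6         766          22.79               18.32       -0.10286
#> 7     7         958          27.88               22.48       -0.03857
#> 8     8        1199          41.14               32.83       -0.33708
#> 9     9        1500          57.92               46.78       -0.20482
```

Reading the table: `mean_sd_raw_ms` vs `mean_sd_denoised_ms` is the
precision proxy (within-vial SD of fitted T1, averaged over replicates) —
denoising lowers it in every vial, by roughly 19% on average.
`bias_change_ms` is the accuracy cost: the per-vial mean T1 moves by less
than 0.4 ms, i.e. accuracy is preserved. That is the central behavior the
package exists to test.

Individual stages are available directly
(`build_phantom()`/`simulate_stack()`, `denoise_stack()`, `fit_t1_map()`,
`roi_stats()`, `bland_altman()`, `aha_segments()`, `sweep_denoise()`), with
NIfTI I/O (`read_stack()`, `write_stack()`) and a minimal DICOM series
reader/writer (`read_dicom_series()`). The same operations are scriptable
through the CLI:

```sh
inst/cli/t1forge simulate --preset vial --sigma 10 --seed 1 --out stack.nii.gz
inst/cli/t1forge denoise --in stack.nii.gz --times stack.times.txt \
    --lam 0.25 --h 5 --beta 1.0 --out denoised.nii.gz
inst/cli/t1forge fit --in denoised.nii.gz --times stack.times.txt --out t1map.nii.gz
```

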