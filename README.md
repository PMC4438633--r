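# ecmquant

Quantitative image analysis of human cardiac myofibroblast activation and
extracellular-matrix (ECM) remodeling in 3D collagen gel assays.

Activated myofibroblasts (the α-SMA–positive, contractile state induced by
TGF-β1) remodel collagen matrices in four measurable ways, and ecmquant
implements the standard read-out for each:

* **Collagen fiber alignment** from confocal reflectance images: the 2D FFT
  magnitude spectrum is profiled along rays from its center ("oval
  profile"), the angular curve is normalized to a no-cell control, and the
  **alignment index** is the area under the curve within ±10° of its peak,

  $$\mathrm{AI} = \int_{\hat\theta-10^\circ}^{\hat\theta+10^\circ}
    \tilde I(\theta)\,d\theta ,$$

  where $\tilde I$ is the unit-mean control-normalized angular intensity
  curve. A direction-free field scores exactly 20; co-aligned fibers score
  higher. The reported fiber axis is the spectral peak rotated by 90°.
* **Total protease activity** from in situ zymography z-stacks: fluorescent
  digestion objects are segmented (threshold + 26-connectivity + minimum
  size), and

  $$\text{activity} = \mathrm{MFI} \times
    \frac{\text{total object volume}}{\text{image volume}},$$

  with MFI the unweighted mean of per-object mean intensities.
* **Single-cell morphology**: roundness $4\pi A/P^2$ (1 = round,
  → 0 = stellate/activated) with a corrected chain-code perimeter, and
  skeleton-endpoint **extension lengths** from the cell-body center to each
  tip. α-SMA positive fractions are computed from per-image
  positive/total count tables.
* **Gel contraction**: percent surface-area loss
  $100\,(1 - A_{24h}/A_0)$ between serial silhouettes, with fold-of-control
  normalization.

Seeded synthetic-image generators (von Mises fiber fields, non-overlapping
fluorescent spot stacks, star-shaped cell masks, shrinking gel disks,
binomial count tables) carry exact ground truth for every read-out, and a
YAML-configurable pipeline runs simulated multi-group experiments through
the matching statistics (Student's t-test for two groups, one-way ANOVA +
Tukey HSD for more).

## Worked example

```r
library(ecmquant)

# a TGFb1-like aligned fiber field and a no-cell control, with ground truth
ff <- sim_fiber_field(kappa = 8, mean_angle_deg = 30, seed = 1)
cc <- sim_fiber_field(kappa = 0, seed = 2)
fiber_alignment(ff$image, cc$image)
#> <alignment_result> fiber axis 30.1 deg, alignment index 46.483 (window +/- 10 deg)
```

The generator placed fibers around a 30° axis with concentration κ = 8; the
pipeline recovers the axis within 0.1° and scores the field at 46.5 —
substantially above the direction-free baseline of 20.

```r
ss  <- sim_spot_stack(n_spots = 10, seed = 3)
obj <- segment_objects(ss$stack, threshold = 60)
total_protease_activity(obj, ss$stack)
#> <protease_activity> 10 objects, MFI 152.509, volume 2570.0 / 262144.0 um^3, total activity 1.4952

gs <- sim_gel_series(area_contraction_fraction = 0.4)
measure_contraction(gs$baseline, gs$followup)
#> # A tibble: 1 x 4
#>   baseline_area_px followup_area_px residual_fraction percent_contraction
#> 1           101780            61060             0.600               40.0
```

A simulated three-arm experiment (untreated-like κ = 1, TGF-β1-like κ = 8,
TGF-β1 + FGF-2-like κ = 2) reproduces the expected activation ordering:

```r
cfg <- list(seed = 7, stages = list(alignment = list(
  n_replicates = 5,
  groups = list(control    = list(kappa = 1),
                tgfb1      = list(kappa = 8),
                tgfb1_fgf2 = list(kappa = 2)))))
rep <- run_remodeling_pipeline(cfg)
tidy(rep)
#>   group_label n  mean    sd
#> 1 control     5  27.3 2.30
#> 2 tgfb1       5  48.2 1.10
#> 3 tgfb1_fgf2  5  33.5 0.499
glance(rep$stages$alignment$comparison)
#>   test_name                 statistic  p_value
#> 1 one-way ANOVA + Tukey HSD      258. 1.38e-10
```

The TGF-β1 arm has the highest mean alignment index and the FGF-2 arm falls
back toward control, with all pairwise Tukey-adjusted p-values below 1e-4.

Result objects have `tidy()`/`glance()` methods and `autoplot()`/`plot_*()`
visualisations; `inst/cli/ecmquant.R` exposes the same operations as shell
subcommands (`simulate`, `align`, `zymo`, `morph`, `smafrac`, `contract`,
`stats`, `run`).

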