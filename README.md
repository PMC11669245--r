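# microglia3d

Quantification of microglia in 3D confocal stacks of IBA-1/CD68-labelled
retina, for researchers studying microglial activation in neurodegeneration.
Microglia shift from a ramified (surveillance) towards an amoeboid
(activated, phagocytic) morphology; this package measures that shift
cell-by-cell in whole z-stacks and compares it between donor groups.

The pipeline is:

1. **Voxel classification** — a three-class random forest
   (microglia / vasculature / background) over a multi-scale filter bank:
   intensity plus Gaussian smoothing, Laplacian of Gaussian, gradient
   magnitude, difference of Gaussians, structure-tensor and Hessian
   eigenvalues at σ ∈ {0.3, 0.7, 1.0, 1.6, 3.5, 5.0, 10} voxels, trained
   from sparse expert labels. Vasculature is an explicit class because
   vessels fluoresce in the IBA-1 channel.
2. **Instance segmentation** — Gaussian smoothing (σ = 1) of the microglia
   probability, Otsu thresholding, exclusion of voxels with vasculature
   probability ≥ 0.5, then marker-based watershed on the Sobel gradient of
   the binarized map, a 100 µm³ size filter, and optional expert QC.
3. **Morphometry** — per cell: volume `V`, convex-hull volume `V_H`,
   solidity `V/V_H`, and on the z-projection: area `A`, perimeter `P`, hull
   area/perimeter, solidity `A/A_H`, convexity `P_H/P`, circularity
   `4πA/P²`, minor/major axis of the moment-equivalent ellipse and their
   ratio; plus count densities in cells/mm² and cells/mm³.
4. **CD68 colocalization** — per-cell CD68 (lysosomal) volume, the
   CD68/IBA-1 volume ratio, CD68± classification and the per-stack CD68⁺
   proportion.
5. **Statistics** — Shapiro–Wilk-gated Student's t / exact Mann–Whitney U
   for two-group comparisons, and a Type-II two-way ANOVA (group × CD68
   status) with Bonferroni pairwise contrasts.

Because donor images are not public, the package ships a **synthetic
confocal simulator** (soma + random-walk processes, vessels bleeding into
the IBA-1 channel, CD68 puncta, Gaussian PSF, Poisson + read noise) with
exact voxel-level ground truth; every stage is validated against it.

## Worked example

Simulate one control and one AD field, train the classifier on sparse
labels sampled from ground truth, and run the full pipeline:

```r
library(microglia3d)

g <- acquisition_geometry(nx = 128, ny = 128, nz = 28, dx = 0.5, dz = 1)
scene_c <- generate_scene(scene_params(geometry = g, n_cells = 8,
                                       group = "control"), seed = 1)
scene_a <- generate_scene(scene_params(geometry = g, n_cells = 8,
                                       group = "AD"), seed = 2)
stacks  <- list(render_stack(scene_c)$stack, render_stack(scene_a)$stack)
labels  <- sample_sparse_labels(scene_c, n_per_class = 200, seed = 1)

bundle <- run_pipeline(
  data.frame(stack = I(stacks), group = c("control", "AD")),
  config = pipeline_config(output_dir = tempfile()),
  train_labels = labels)

summarize_groups(bundle$cells, "volume_um3", "group")
#>   group       n  mean    sd   sem label
#> 1 AD          9 1552.  546.  182. 1552 ± 182
#> 2 control     9  995.  407.  136. 994.9 ± 135.8

bundle$stats$volume_um3
#> <mg_test> mann_whitney_u: statistic = 9, p = 0.00399 ** (n = 9, 9)
#>   normality gate: p_a = 0.425, p_b = 0.0119 (alpha = 0.05)
```

What the numbers mean: the two simulated fields have true voxelized mean
volumes of 1051 (control) and 1687 µm³ (AD); the pipeline recovers group
means of 995 and 1552 µm³ and flags the difference at `**` — the AD sample
failed the normality gate (p = 0.012), so the comparison fell through to
the Mann–Whitney branch, which the result records. The per-cell table
`bundle$cells` carries the full metric suite (`volume_um3`,
`solidity_3d`, `circularity`, `axis_ratio`, `cd68_positive`, ...),
`bundle$densities` the count densities, and `autoplot(bundle$cells)` draws
the group comparison. The acceptance script below runs the adequately
powered versions (10 fields of 30 cells; simulated cohorts of 278/268
cells).

Everything is also scriptable from a shell via the thin CLI at
`inst/cli/microglia3d.R` (`simulate`, `train`, `segment`, `measure`,
`stats`, `run-all`).

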