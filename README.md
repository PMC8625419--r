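# myotype

Cell-type-specific organization analysis of cardiac tissue micrographs.

Cardiomyocytes and cardiac fibroblasts orient differently under cyclic
uniaxial strain, and in co-culture each population perturbs the other.
Measuring that interaction requires separating the two cell types in the
same image: actin (present in both) carries the orientation signal, while
sarcomeric alpha-actinin marks myocytes — but only cells with visible
sarcomere striations count as mature striated myocytes.  `myotype`
implements the full measurement pipeline:

1. **Foreground classification** of alpha-actinin images from four texture
   features (local entropy, standard deviation, range, Gaussian-smoothed
   intensity) with a CART decision tree trained on a balanced 2.5% pixel
   subsample, hyperparameters chosen by seeded cross-validated grid search.
2. **Striation detection**: anisotropic (edge/coherence-enhancing)
   diffusion, white top-hat filtering, dual binarization (adaptive local
   mean + global Otsu), ~200 SLIC superpixels.  A superpixel is a
   *Striated Myocyte* region iff at least 10% of its foreground lies on
   striation components roughly perpendicular to the local object axis
   (|dot| < 0.8 on unit axial vectors) and at least 5% is positive in the
   global mask; otherwise *Other* (alpha-actinin without striations).
3. **Nucleus labeling**: each nucleus in an externally produced instance
   label map inherits the modal class within its boundary when the mode
   covers at least 40% of it.
4. **Organization metrics** per cell type from the structure tensor
   T̄ = mean(r rᵀ) of the per-pixel unit axial actin vectors r:
   OOP = 2·λ_max(T̄) − 1 (0 = isotropic, 1 = perfectly aligned), the
   director (eigenvector of λ_max), the angle to the stretch axis
   θ = arccos|p·q| ∈ [0°, 90°], and the per-type actin fraction.
5. **Log-normal regression** of cardiomyocyte OOP against actin fraction,
   y = y0 + a·x·exp(−0.5·(ln(x/x0)/b)²), by unconstrained nonlinear least
   squares; for a < 0 the curve's minimum sits at x0·exp(b²).
6. A **synthetic co-culture generator** producing actin / alpha-actinin /
   nuclei channels with exact ground-truth class, orientation and nucleus
   maps, so the entire pipeline is testable offline.

## Worked example

```r
library(myotype)

# train the foreground classifier on synthetic wells
ws <- generate_wellset(4, 0.5, cells_per_well = 8, base_seed = 100,
                       other_fraction = 0.3)
model <- train_texture_model(ws$scenes, fraction = 0.025, seed = 1)
model
#> <pixel_classifier> CART, depth<=4, min leaf 1, training accuracy 0.9919

# classify a co-culture scene and measure per-type organization
scene <- generate_wellset(1, 0.6, cells_per_well = 8, base_seed = 7)$scenes[[1]]
cls <- classify_actinin(scene$alpha_actinin, model)
field <- estimate_orientation_field(scene$actin)
afg <- actin_foreground_mask(scene$actin)
organization_metrics(field, cls$class_map, afg, stretch_angle_deg = 90)
#>       cell_type    oop director_deg angle_to_stretch_deg n_vectors actin_fraction
#> 1 cardiomyocyte 0.8942        26.79                63.21     11766         0.7371
#> 2    fibroblast 0.7635       116.76                26.76      3865         0.2421
```

The generator placed myocytes at a 25° mean axis and fibroblasts at 115°;
the measured directors (26.8° and 116.8°) recover them, the OOPs say both
populations are strongly aligned, and the cardiomyocyte actin fraction
(0.74) reflects the 0.6 seeding fraction plus the myocytes' larger measured
share in this draw.  With the sample mounted at 90° to the stretch axis,
the fibroblasts sit 27° from stretch and the myocytes 63°.

Fitting the organization curve to well-level data:

```r
xs <- seq(0.05, 0.95, length.out = 40)
set.seed(20)
ys <- lognormal_eval(-0.1605, 0.3504, 0.4334, 0.7437, xs) + rnorm(40, 0, 0.02)
fit_lognormal(xs, ys)
#> Four-parameter log-normal fit: y = y0 + a*x*exp(-0.5*(ln(x/x0)/b)^2)
#>   a = -0.1561, b = 0.3789, x0 = 0.4247, y0 = 0.7410
#>   R-squared: 0.5661, converged: TRUE (14 iterations), n = 40
#>   minimum of the curve at x = 0.4903
```

## Command line

A thin CLI over the same functions ships at `inst/cli/myotype.R`
(subcommands `synth`, `train`, `classify`, `organize`, `fit`, `run`), e.g.

```sh
CLI=$(Rscript -e 'cat(system.file("cli/myotype.R", package = "myotype"))')
Rscript $CLI synth --n-wells 2 --myocyte-fraction 0.6 --seed 5 --outdir wells
Rscript $CLI train --wells wells --seed 5 --model model.json
Rscript $CLI classify --actinin wells/well01/alpha_actinin.tif \
        --model model.json --out class.tif
Rscript $CLI organize --actin wells/well01/actin.tif --class class.tif \
        --stretch-angle 90 --out metrics.csv
```

All decision thresholds (0.8 / 0.10 / 0.05 / 0.4) are flags with the
documented defaults.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the pipeline's main computation from scratch: it trains the texture
classifier on a synthetic wellset, generates a myocyte-density sweep
(fractions 0–1), classifies every well, measures the per-type organization
metrics, and fits the log-normal organization curve, writing the results
JSON to `--out`.

See `vignettes/myotype-methods.Rmd` for the model details, parameter
defaults and their rationale, what the synthetic generator does and does
not emulate, and known limitations.
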