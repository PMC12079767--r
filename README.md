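# condatlas

Deep-diffeomorphic construction of **conditional anatomical templates** —
templates tailored to a covariate such as age — with a purely geometric
two-stage deformation model, plus the synthetic phantoms and evaluation
battery needed to exercise it end-to-end at desk scale.

## The problem and the model

A group template is a single reference anatomy; it cannot show how, say, an
85-year-old brain differs from a 55-year-old one. Conditional templates
T<sub>α</sub> fill that gap, but they are only useful if (i) they remain
topologically consistent with the group template and the individual scans,
and (ii) they actually sit at the *centre* of the anatomy of subjects with
conditioning value α.

`condatlas` addresses both with deformations integrated from **stationary
velocity fields** (SVFs). Writing φ for the unit-time flow of a velocity
field v (computed by scaling and squaring), the model is:

- **Stage 1 (conditional generator).** Fully connected layers map the
  normalized covariate α to a latent code z<sub>α</sub>; a
  transpose-convolution decoder turns z<sub>α</sub> into a velocity field
  v<sub>α</sub>. The conditional template is
  T<sub>α</sub>(x) = T(φ<sub>α</sub>(x)).
- **Stage 2 (registration U-Net).** A U-Net over the pair
  (T<sub>α</sub>, X<sub>p</sub>) predicts v<sub>p|α</sub>, and the predicted
  scan is X̂<sub>p</sub>(x) = T<sub>α</sub>(φ<sub>p|α</sub>(x)).
- **Local mean-deformation tracking.** Per 5-year age bin k, a running mean
  v̄<sub>k</sub> of Stage-2 velocities is kept by an exponential moving
  average, v̄<sub>k</sub> ← (1−q<sub>k</sub>) v̄<sub>k</sub> +
  q<sub>k</sub> v<sub>p|α</sub> with q<sub>k</sub> = λ ζ<sub>k</sub>(α),
  where ζ<sub>k</sub> are triangular soft-binning weights
  (ζ<sub>k</sub> + ζ<sub>k+1</sub> = 1). The *mean-adjusted* template is
  T̂<sub>α</sub> = T ∘ φ̂<sub>α</sub> with
  v̂<sub>α</sub> = v<sub>α</sub> + ζ<sub>k</sub> v̄<sub>k</sub> +
  ζ<sub>k+1</sub> v̄<sub>k+1</sub>.
- **Training loss.**
  ℒ = γ₁ℒ<sub>recon</sub> + γ₂ℒ<sub>bend1</sub> + γ₃ℒ<sub>bend2</sub> +
  γ₄ℒ<sub>disp1</sub> + γ₅ℒ<sub>disp2</sub> + γ₆ℒ<sub>mean</sub>,
  with reconstruction MSE, bending energy (mean squared Laplacian) and mean
  squared displacement of both stages' deformations, and the
  template/mean-adjusted-template MSE; γ = (1, .01, .01, .01, .01, 1),
  optimized with AdamW (lr 10⁻⁴ reference / 10⁻³ desk scale, β₁ 0.9,
  β₂ 0.999, weight decay 10⁻²). ℒ<sub>mean</sub> is what keeps conditional
  templates centred: a centred model leaves no systematic per-bin Stage-2
  deformation, so v̄<sub>k</sub> → 0 and T̂<sub>α</sub> → T<sub>α</sub>.

Because every deformation is an SVF flow, Jacobian determinants stay
positive (no folding) — the evaluation battery checks this directly.

The networks, backpropagation and AdamW are implemented in the package's own
Rcpp engine; NIfTI I/O uses RNifti.

## Worked example

```r
library(condatlas)

# 200 synthetic age-conditioned phantoms (64x64): ventricles +50% across
# ages 50-90, hippocampus -15%, cortical grey matter -10%
ds  <- study_dataset(n = 200, seed = 42)
gt  <- build_group_template(attr(ds, "spec"))
cfg <- study_config(seed = 7)

ck <- run_training(ds, cfg)                   # ~4 min on one CPU
tps <- build_templates(ck$model, ck$tracker, gt$image, seq(50, 90, 5))

# topology: Jacobian determinants of the template deformations
jacobian_report(lapply(tps, `[[`, "phi"))$pooled
#>        min      max      mean        sd n_nonpositive
#>  0.3628911 2.019385 0.9999372 0.0621455             0

# volumetric trend recovered from the templates vs the phantom truth
tv  <- normalized_volumes(template_volumes(tps, gt$labels))
ref <- study_reference_curves(ds)
trend_recovery(tv[tv$roi == "vent", ], ref[ref$roi == "vent", ])[c("spearman", "sign_agreement")]
#> $spearman
#> [1] 1
#> $sign_agreement
#> [1] TRUE
```

The Jacobian summary shows determinants centred at 1 with no non-positive
voxels: the age-specific templates are diffeomorphic reshapings of the group
template. The Spearman correlation close to 1 with matching sign says the
ventricle growth written into the phantoms is recovered by the conditional
templates (the trend's direction and ordering; its amplitude is attenuated at
this training scale — see the methods vignette).

## Command line

A thin CLI over the package functions lives at `inst/cli/condatlas.R`
(subcommands `synth`, `train`, `template`, `evaluate`, `ablate`), writing
NIfTI images, manifest CSVs, loss logs and evaluation tables.
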