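# octamls

Multilayer and multisector peripapillary OCTA analysis for glaucoma
diagnosis and staging, in R.

Optical coherence tomography angiography (OCTA) images retinal and
choroidal perfusion as en-face intensity maps. Glaucoma damages the
peripapillary microvasculature, and that damage is measurable per retinal
layer and per sector around the optic nerve head. `octamls` implements the
full measurement-and-classification pipeline for researchers who want to
quantify it:

1. **Fovea–disc axis correction** — estimate the axis angle α from the
   annotated fundus image (circle centroids) and rotate sector masks to a
   common anatomical frame, with OD/OS mirroring.
2. **Segmentation** — macrovessels on the superficial plexus (pixels above
   the 88th intensity percentile, morphological opening + closing,
   8-connected components < 250 px removed) and the optic nerve head
   optically hollow area on the choroid (largest dark component below the
   40th percentile of the equalized histogram, summarized as a circle of
   radius √(A/π)). Both are excluded from every region of interest.
3. **Features** — the microvascular intensity median (VIM) over each of
   the 7 Garway-Heath sectors (ST, SN, N, IN, IT, T, CP) in each of the 6
   device layers (superficial, deep, avascular, whole retina,
   choriocapillaris, choroid): a 42-dimensional vector per eye, plus the
   circumpapillary RNFL thickness as the structural comparator.
4. **Classification** — SVM, random forest and gradient boosting (all
   implemented in-package) under outer leave-one-out cross-validation with
   inner stratified 5-fold grid search and univariate top-k feature
   selection (Mann-Whitney / Kruskal-Wallis), for three tasks: control vs
   glaucoma, POAG vs NTG, and four-level severity (one-versus-all,
   micro-averaged metrics).
5. **Statistics** — permutation one-way ANOVA with BH-adjusted pairwise
   permutation post hocs, DeLong comparison of correlated ROC curves,
   McNemar–Bowker symmetry test, stratified bootstrap 95% CIs,
   Kolmogorov–Smirnov normality checks, and a −log10(p) heat-grid of the
   42-feature significance pattern.

Because no clinical OCTA dataset is deposited, a first-class **phantom
generator** produces seeded synthetic layer stacks, Panomap annotations and
cohort feature tables with controllable disease effects, so every stage is
testable end to end. See the methods vignette
(`vignettes/octamls-methods.Rmd`) for the model, all numerical choices, and
what phantom-based validation does and does not establish.

## Worked example

```r
library(octamls)

# a 121-eye synthetic cohort shaped like the reference study
# (39 controls, 82 glaucoma eyes two severity steps in)
tb <- generate_cohort_feature_table(cohort_effect_spec(
  n_per_group = c(control = 39, glaucoma = 82),
  severity_steps = c(glaucoma = 2), seed = 1))

cv <- run_nested_evaluation(
  tb, task = "diagnosis", model = "svm",
  grid = data.frame(kernel = "linear", C = c(0.01, 1), gamma = NA),
  feature_set = "all", seed = 1)
score_binary(cv, seed = 3)
#>        metric  estimate    ci_low ci_high
#> 1       auroc 1.0000000 1.0000000       1
#> 2    accuracy 0.9917355 0.9752066       1
#> 3 sensitivity 1.0000000 1.0000000       1
#> 4 specificity 0.9743590 0.9224359       1
```

121 outer folds, one eye per test fold; AUROC/accuracy/sensitivity/
specificity with stratified-bootstrap 95% CIs. With the default effect map
(strongest deficit at the superficial inferotemporal sector, −18 a.u. per
severity step against a between-subject SD of 17), the diagnosis task is
nearly separable — the point of the phantom is to validate the machinery,
not to reproduce clinical accuracy. The univariate view:

```r
grid <- univariate_pvalue_grid(tb, "diagnosis")
plot_pvalue_grid(grid)   # -log10(p) heat-grid; X marks p > 0.05 cells
```

The image-level pipeline (phantom rendering → axis correction →
segmentation → 42 VIM features → feature CSV + QC overlays):

```r
res <- run_pipeline(pipeline_config(
  n_per_group = c(control = 10, severe = 10), seed = 5,
  out_dir = "out"))
dim(res$features)  # 20 subjects x (5 metadata + 42 feature) columns
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch
against the installed package: it renders a phantom cohort through the full
image pipeline, runs the nested leave-one-out SVM evaluation and the
univariate statistics on a 121-eye cohort, and writes the JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
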