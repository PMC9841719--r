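# itwiner

Correlation-guided weighted elastic-net logistic regression for selecting
candidate biomarker genes in two-class transcriptomic cohorts — built for
the contrast between early-stage colorectal tumors that metastasized
within follow-up (**PM**) and those that did not (**P**), and usable for
any two-class gene-expression cohort.

## The idea

Classes can differ in *how genes co-express*, not only in mean
expression. For gene *j*, take its correlation profile in each class —
the *j*-th column σⱼ of the class-conditional gene–gene correlation
matrix — and measure how much the profile rewires between classes by the
angle

    d_j = arccos( ⟨σⱼᴾ, σⱼᴾᴹ⟩ / (‖σⱼᴾ‖‖σⱼᴾᴹ‖) )  ∈ [0, π].

Normalize wⱼ = dⱼ / max dⱼ and invert: qⱼ = 1/wⱼ ≥ 1 becomes the
per-gene **penalty factor** of an elastic-net logistic regression

    −(1/n)·ℓ(β) + λ Σⱼ q̃ⱼ ( α|βⱼ| + ((1−α)/2)βⱼ² ),

so the most rewired genes are penalized least and selected
preferentially (the **iTwiner** regularizer; the original **Twiner**
uses wⱼ directly and favors *conserved* patterns). P is coded y = 1.
λ comes from stratified 10-fold cross-validation; α defaults to 0.05
(iTwiner) and 0.2 (plain elastic net).

The package also ships the surrounding benchmark protocol: constant-gene
filtering, class-balanced undersampled datasets (all PM samples in every
dataset, the P cohort partitioned across them), clinical exploratory
statistics (Fisher exact, Welch t, Kaplan–Meier/log-rank), a rank-based
DE stand-in with BH-FDR, five reference classifiers (decision tree,
linear/radial SVM, logistic regression, random forest) over resampled
stratified 70/30 splits, selection-stability profiles, and a synthetic
cohort generator with planted differential-correlation blocks.

## Worked example

```r
library(itwiner)

# 120-sample cohort: a 20-gene block whose within-block correlation is
# 0.8 in P and 0 in PM, plus 10 genes shifted by 1.5 log-units in PM
co <- generate_cohort(n_per_class = 60, p_genes = 200, block_size = 20,
                      rho_p = 0.8, rho_pm = 0, n_shift_genes = 10,
                      shift = 1.5, seed = 7)

wts <- compute_penalty_weights(co$expression, co$annotation, type = "itwiner")
wts
#> itwiner weights over 200 genes; d in [1.198, 1.485]; 0 excluded (d = 0)

fit <- itwiner_fit(t(co$expression), encode_class(co$annotation$class),
                   alpha = 0.05, q = wts$penalty, seed = 7)
fit
#> weighted EN logistic (factor mode): alpha = 0.05, lambda = 0.000704, 166/200 nonzero, 0 excluded

head(selected_genes(fit), 10)
#>  [1] "g0026" "g0022" "g0025" "g0023" "g0021" "g0027" "g0029" "g0028" "g0024"
#> [10] "g0015"

evaluate_recovery(selected_genes(fit), co$truth, "shift")
#> $precision
#> [1] 0.06024096
#> $recall
#> [1] 1
```

Reading the output: the dissimilarities span 1.20–1.49 rad (no gene has
an identical profile in both classes — sample correlations are never
noise-free, so `d` has a finite floor). At α = 0.05 the ridge-heavy
penalty keeps many genes with small coefficients (166 nonzero, hence the
low precision against the 10-gene shift stratum), but the *ranking* by
|β| puts the truly shifted genes g0021–g0029 in nine of the top ten
positions, and every shifted gene is recovered (recall 1). Gene sets of a
fixed size come from `path_gene_ranking()` (order of entry along the
regularization path), and `run_benchmark()` evaluates classifier routes
over resampled splits.

A shell front end with `simulate`, `weights`, `fit`, `benchmark` and
`pipeline` subcommands is installed at
`system.file("cli", "itwiner", package = "itwiner")`, and
`run_pipeline()` drives the full workflow from one JSON/YAML config with
a single master seed.

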