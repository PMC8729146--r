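# toastnet

Interpretable classification of ischemic-stroke TOAST subtypes (LAA, CE,
SAO, OC, UND) from tabular clinical cohorts, for clinical ML researchers
and methodologists working with small, severely imbalanced registries.

The pipeline mirrors how a neurologist reads a chart. Features are ranked
by gradient-boosted-tree gain importance (features with importance
&le; 0.005 are dropped), and each patient becomes a sequence
*x*<sub>0</sub>, *x*<sub>1</sub>, …, *x*<sub>t</sub>, most important
feature first. A 1-D convolutional network with **causal padding** — the
output at position *t* depends only on inputs at positions &le; *t* — reads
that sequence so the subtype call *Y*<sub>t</sub> = *f*(*x*<sub>0</sub>, …,
*x*<sub>t</sub>) accumulates evidence in importance order. Four
architecture variants (V1–V4) differ after the shared first causal
convolution; V4, which concatenates the max-pool branch, the second
convolution branch and the (stride-aligned) first-layer output, is the
default.

Training minimizes the **KL-focal loss**

> KFL = −(1 − p<sub>x</sub>)<sup>γ</sup> log p<sub>x</sub> + Σ<sub>j</sub> P<sub>j</sub> log(P<sub>j</sub>/Q<sub>j</sub>),

a focal term (γ = 2 by default) that keeps minority subtypes influential,
plus a KL divergence from the label-smoothed target that regularizes
iterative fine-tuning. A single-cycle **active model adaptation** then
scores every pool sample by entropy, top-2 margin, or the mixed criterion
α·p₁log p₁ + (1−α)(p₁−p₂) with α = 0.3, appends the most uncertain
`floor(0.5·n)` samples as duplicates, and fine-tunes from the current
weights.

Because clinical registries are private, a first-class synthetic cohort
generator reproduces the statistical shape the method cares about: five
subtypes with counts 1290/107/550/81/282 (2310 patients), 122 mixed-type
features with a configurable informative subset, and 0.47 % missing cells
filled by training-set mode imputation. Evaluation uses support-weighted
multiclass metrics (under which weighted recall equals accuracy — the
identity is fuzz-tested), one-vs-rest AUC, and stratified k-fold
cross-validation with fold-internal preprocessing.

## Worked example

```r
library(toastnet)

coh <- generate_cohort(cohort_spec(seed = 1))      # 2310 x 122 cohort
coh <- impute_mode(coh)
ranking <- filter_and_rank(compute_importance(coh, seed = 1), 0.005)
xs <- to_sequence(coh, ranking$kept)

fit <- causal_cnn(xs, coh$y, variant = "V4", epochs = 20, seed = 1)
print(fit)
#> Causal CNN subtype classifier (variant V4)
#>   2310 training samples, sequence length 19, 5 classes
#>   8509 parameters; loss 'kl_focal'; 20 epochs trained
#>   final training loss: 0.3642

adapted <- run_active_cycle(fit, cycle_config(strategy = "mixed",
                                              alpha = 0.3, epochs = 20))
print(adapted$report)
#> Cycle 1: training size 2310 -> 3465 (+1155)
#>   addition counts: 531/105/343/80/96  (rates %: 41/98/62/99/34)
```

The fit reads the 19 features surviving the 0.005 importance cut (the
synthetic cohort concentrates its signal in a minority of columns), and
the cycle appends the 1155 most uncertain patients — disproportionately
minority subtypes (OC grows by 99 %, LAA by only 41 %), which is where
the fine-tuning gain comes from.
`summary(fit)`, `plot(fit)`, `residuals(fit)` and `simulate(fit)` give
the usual modelling-object views; `cross_validate()` and
`run_experiment()` reproduce the variant/loss/strategy comparison
designs, and `inst/cli/toastnet` exposes the same steps as shell
subcommands.

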