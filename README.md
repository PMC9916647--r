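# hiprs — high-order interaction-aware polygenic risk scores

Polygenic risk scores (PRS) usually sum additive per-SNP effects. When a
phenotype is epistatic — driven by *combinations* of allele levels at several
loci — additive scores hit a ceiling, while black-box learners that can fit
interactions give up the interpretability that makes a PRS useful for
discovery and validation. `hiprs` is for statistical geneticists and clinical
researchers who work with modest panels of individual-level genotypes
(tens of SNPs, hundreds to thousands of samples) and want a score that models
interactions of any order yet stays a readable list of weighted terms.

## The method

Genotypes are categorical: 0 = major-allele homozygote, 1 = heterozygote,
2 = minor-allele homozygote. An *allele pattern* is a conjunction of
(SNP, level) pairs, evaluated on a genotype as a product of indicator
functions, e.g. `{S8=2,S9=2,S10=2}`. The fitted score is

```
score = β₀ + β₁·I₁ + … + β_K·I_K,        logit P(Y=1) = score
```

where each `I_k` is a pattern indicator and the β's are ordinary logistic
coefficients (per-pattern log odds ratios). The pipeline:

1. **Mine** — frequent-itemset search over the *case class only*: keep every
   pattern with case frequency strictly above `δ` and length ≤ `l_max`.
2. **Rank** — score each candidate by empirical mutual information with the
   outcome over the full training data.
3. **Select** — greedy minimum-redundancy/maximum-relevance choice of `K`
   patterns, where redundancy is the number of shared (SNP, level) pairs
   with the already-picked set.
4. **Weight** — unpenalized logistic regression on the `K` binary features
   (with a documented tiny-ridge fallback under perfect separation).

The package also ships the machinery to study such a score honestly: an
epistatic phenotype simulator with closed-form case probability and missing
heritability, exact-quota class-imbalance undersampling, bootstrap resampling
from published genotype-by-class tables, additive penalized baselines
(lasso/ridge/elastic-net), imbalance-aware metrics (trapezoidal AUC,
rectangular-rule average precision), a repeated-simulation harness, a
cross-validated `(δ, K)` grid search, and a command-line interface
(`inst/cli/hiprs.R`).

## Worked example

```r
library(hiprs)

sim <- simulate_epistasis(n_train = 1000, n_test = 500, epsilon = 0.01, seed = 11)
fit <- hiprs(sim$train, delta = 0.05, K = 10)
tidy(fit) |> head(4)
#> # A tibble: 4 × 6
#>   term              estimate  rank support      mi redundancy
#>   <chr>                <dbl> <int>   <dbl>   <dbl>      <dbl>
#> 1 (Intercept)          -3.30    NA  NA     NA              NA
#> 2 {S8=2,S9=2,S10=2}    21.3      1   0.278  0.0922          0
#> 3 {S8=1,S9=1,S10=1}     5.62     2   0.189  0.0568          0
#> 4 {S4=1,S5=1}           3.26     3   0.344  0.0514          0

auc(predict(fit, sim$test), sim$test$Y)
#> [1] 0.9235075
average_precision(predict(fit, sim$test), sim$test$Y)
#> [1] 0.8404619

# an additive lasso PRS on the same data caps out near chance-plus
base <- fit_additive_prs(sim$train, penalty = "lasso")
auc(predict(base, sim$test), sim$test$Y)
#> [1] 0.6016347
```

The top-ranked terms are instances of the generative rules: the first two
are rule-C patterns (`S8=S9=S10` at a common level) and the third is the
core of rule B (`S4=1,S5=1`), each with a large positive log odds ratio —
the model is readable straight off `tidy()`. Under the simulator's rules the
phenotype depends on interactions up to order 7, which is why the additive
baseline stalls around 0.60 AUC while the interaction-aware score reaches
0.92 here.

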