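---
title: "Modeling high-order allele interactions in polygenic risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling high-order allele interactions in polygenic risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiprs)
```

## The problem

Classical polygenic risk scores sum per-SNP additive effects. When the
phenotype is driven by *epistasis* — combinations of allele levels at several
loci acting jointly — no additive model can represent the risk surface, and
penalized additive scores plateau well below the attainable discrimination.
The other extreme, black-box machine learning, can fit interactions but
returns no readable model and overfits small cohorts.

`hiprs` takes the middle road. It searches genotype-level data for
*allele patterns*: conjunctions of (SNP, level) conditions such as
`{S8=2,S9=2,S10=2}`, where levels follow the additive coding
0 = major-allele homozygote, 1 = heterozygote, 2 = minor-allele homozygote.
Each pattern is a binary feature — a product of per-SNP indicator functions —
and the final score is an affine linear predictor over `K` such features,

$$\mathrm{score} = \beta_0 + \sum_{k=1}^{K} \beta_k\, I_k(\text{genotype}),$$

with the $\beta_k$ fitted by ordinary logistic regression, so every term reads
as a per-pattern log odds ratio.

## The four-stage pipeline

**1. Mining (`mine_patterns()`).** Only the case class is scanned. A pattern
is kept when its empirical frequency among cases is *strictly* greater than a
threshold $\delta$ and its length (number of SNPs) is at most $l_{\max}$.
Support is anti-monotone, which makes the search a frequent-itemset problem;
the implementation is a depth-first tidset-intersection search equivalent to
Apriori but cheaper on the short, dense transactions genotype data produce.
Restricting the scan to cases is what keeps the search tractable and what
orients the candidate set toward the minority phenotype.

**2. Relevance (`rank_patterns()`).** Each candidate is encoded over the full
training data (cases *and* controls) and scored by plug-in mutual information
with the outcome, in nats, with the $0 \log 0 = 0$ convention for empty cells
of the 2×2 joint. The base of the logarithm is a free choice — selection only
uses rankings and ratios — and natural logarithms are used throughout.

**3. Selection (`select_patterns()`).** A greedy minimum-redundancy /
maximum-relevance loop. Redundancy between two patterns is the number of
(SNP, level) pairs they share — a shared SNP held at *different* levels
counts zero. The first pick is the relevance argmax; afterwards each
iteration computes every remaining candidate's relevance $V$ and average
similarity $W$ to the picked set, and takes $\arg\max V$ if any remaining
candidate has $W = 0$, otherwise $\arg\max V/W$.

One detail of that rule is genuinely ambiguous: when *some* candidate has
zero redundancy, the greedy step as usually written maximizes relevance over
**all** remaining candidates — which can pick a candidate that itself has
positive redundancy. The package implements this literal reading by default
(it is deterministic and regression-tested), and offers
`zero_redundancy = "restricted"` to confine the argmax to the zero-redundancy
candidates, which is the other defensible interpretation. On realistic data
the two rarely diverge; we default to the literal rule rather than guess
intent.

Every argmax breaks ties deterministically: higher mining support, then
shorter pattern, then canonical pattern order (SNPs in data-column order,
then level). Runs are therefore bit-reproducible for fixed inputs.

**4. Weighting.** Unpenalized maximum-likelihood logistic regression of the
outcome on the `K` selected 0/1 features. Dummies are not standardized, so
coefficients stay interpretable. With many terms and few cases the likelihood
can separate; the fit then falls back to a very lightly ridge-penalized
logistic regression (`ridge = 1e-4` on glmnet's mean-log-likelihood scale) so
fitting always terminates with finite weights. The fallback and its strength
are recorded in the model metadata and surfaced by `glance()`.

## Tunable parameters

* `delta` (default **0.05**): minority-class support threshold, a fraction in
  $[0, 1)$. Larger values shrink the candidate set exponentially; the strict
  inequality means `delta = 0` keeps every pattern observed at least once.
* `K` (default **10**): number of interaction terms — the model's entire
  dimensionality, `K + 1` parameters including the intercept. `K` of 10–40
  spans readable-to-flexible on 15-SNP problems.
* `l_max` (default unbounded): cap on interaction order. Unbounded mining is
  affordable for tens of SNPs; for wider panels raise `delta` or cap `l_max`.
* `zero_redundancy` (default `"literal"`): see above.

`grid_search_prs()` tunes `(delta, K)` by stratified cross-validated AUC,
refitting the whole pipeline per fold; `delta` is always interpreted as a
minority-class frequency, matching the mining definition.

## The synthetic cohort generator

`simulate_epistasis()` draws `p ≥ 10` SNPs i.i.d. uniform on {0, 1, 2} and
labels a sample a case exactly when one of three allele rules fires:

* **A**: `S4=2, S5=2, S6=2, S7=2` (an order-4 interaction),
* **B**: `S4=1, S5=1, S6≠2, S7≠2`,
* **C**: `S8=S9=S10` at any common level (three order-3 interactions).

Rules A and B are mutually exclusive, and the full indicator-product
expansion of `A ∨ B ∨ C` (`rule_expansion()`) contains surviving terms up to
order 7 (rule A crossed with rule C). The noiseless case probability is
exactly 121/729 ≈ 16.6% by enumeration of the 3⁷ relevant configurations.
The observed label flips independently per sample with probability `epsilon`,
which induces a closed-form *missing heritability*
(`missing_heritability()`): about half the outcome variance is unexplainable
from genotypes already at `epsilon = 0.1`. SNPs S1–S3 and S11–S15 are pure
noise predictors kept to preserve the 15-SNP search space.

One printed form of rule B elsewhere reads "not both S6 and S7 at level 2";
we use the per-SNP reading (`S6≠2` **and** `S7≠2`) because only it yields the
stated event probability 4/81 and the 121/729 total, and the generator and
expansion agree on it by construction.

Defaults mirror the study design the package is organized around: 1000
training and 500 test samples, `epsilon = 0.01`, `delta = 0.05`, unbounded
`l_max`, `K ∈ {10, 40}`, 30 repetitions per experimental condition.

**Imbalance control.** `subsample_imbalance()` fixes the training case
fraction at an exact quota `q`: fresh batches are drawn until both class
quotas are met, then each class is truncated to its quota keeping the
earliest draws (quotas are `round(n·q)` and the remainder). Within-class
genotype laws are untouched; test sets are never undersampled, since AUC and
average precision are insensitive to the test class mix.

**What the generator does not emulate.** Real cohorts have linkage
disequilibrium (correlated SNPs), allele-frequency spectra far from uniform,
covariates, and genotyping error. Passing the simulation suite therefore
demonstrates that the pipeline recovers *rule-based epistatic structure under
label noise and imbalance*, not that it handles LD-induced redundancy among
SNPs — on real panels the mRMR redundancy term mitigates but does not model
LD. `bootstrap_from_table()` narrows this gap for small panels by resampling
any published genotype-by-class joint distribution directly.

## Evaluation conventions

`auc()` integrates the ROC curve by the trapezoidal rule with tied scores
grouped into a single threshold step; this is numerically the Mann–Whitney
pair statistic with ties counted ½, which is how the tests cross-check it.
`average_precision()` uses the right-anchored rectangular step sum
$\sum_n (R_n - R_{n-1}) P_n$, again with tie grouping. AP is the metric to
watch under imbalance; AUC alone flatters weak minority-class rankings.

`run_experiment()` repeats simulate–fit–evaluate over a condition grid with
seeds derived deterministically from one master seed, pairing methods that
share a condition on identical datasets. Confidence bands in
`summarize_experiment()` are normal-approximation 95% intervals,
mean ± 1.96·sd/√reps — a deliberate, documented choice since band
construction is otherwise unspecified. Additive lasso/ridge/elastic-net
baselines (`fit_additive_prs()`) use one 0/1 dummy per SNP level with no
standardization and a default penalty of `lambda = 1/N` on glmnet's
mean-likelihood scale, i.e. a unit-strength penalty on the summed
log-likelihood — the customary "library default" strength.

## Numerical choices and degenerate inputs

* Strict `> delta` mining is enforced on integer counts with a tiny relative
  slack (`1e-12`) so binary-representation artifacts of thresholds like 0.3
  cannot flip a boundary decision either way.
* Mutual information clamps tiny negative totals (floating cancellation) to 0.
* Missing genotype entries are rejected at load time with the offending row
  and column named: pattern indicators have no meaningful value on missing
  data, and silent imputation would change supports.
* An empty candidate set (too-large `delta`) raises an error suggesting a
  smaller threshold; `K` beyond the candidate count returns all candidates
  with a warning; mining a dataset whose cases are the majority warns but
  still scans the `Y = 1` class.
* A worked example of this scale: the acceptance experiments use 30
  repetitions of 1000/500-sample cohorts, the sizes above; a full pipeline
  fit takes on the order of a second at `p = 15`, dominated by the mining and
  mutual-information stages when `delta` is small or cases are few.

## Limitations

The candidate search is exponential in the number of SNPs; with `delta =
0.05` the practical ceiling is a few tens of SNPs, so wide panels need a
prior SNP-selection step. The selection stage is quadratic in the number of
candidates. Outcomes must be binary; continuous dosages, phased haplotypes,
and more than three allele categories are out of scope (the level alphabet is
a parameter internally, so other categorical codings work unchanged).
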