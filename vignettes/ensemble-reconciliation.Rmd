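---
title: "Reconciling multi-method DE profiles: models and design notes"
author: "armonize"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconciling multi-method DE profiles: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armonize)
```

# The setting

Five or so differential-expression callers applied to the same tumor
vs. control RNA-Seq samples produce five partially overlapping log2
fold-change profiles. Disagreement has several sources — different
normalizations, count vs. FPKM inputs, different test statistics — and
manifests as genes called by only one method, fold changes of different
magnitude for identical calls, and occasional sign discordance. The
package treats the merged gene × method matrix $Y$ (with missing cells
where a method made no call) as the object of inference and offers two
reductions of it: a regression ensemble and a principal-component
projection, each followed by a robust boxplot selection.

# The Alternating Regression Model

For each method $m$ in turn, ordinary least squares is fit over genes
$g$ where the response and regressors are observed:

$$y_{gm} = \beta_0 + \sum_{j \ne m} \beta_j\, y_{gj} + \varepsilon_g .$$

Two-sided t-tests on the coefficients drive backward elimination: while
any regressor has $p \ge \alpha$, the one with the largest p-value is
dropped and the model refit (the usable gene rows are recomputed for
the current regressor set, since removing a regressor can only enlarge
the complete-case row set). The loop ends with every retained
coefficient significant at $\alpha$, or with none retained, in which
case the response is flagged *not predictable*.

The flag is the mechanism behind an important behavior: a method whose
profile is unrelated to the shared signal — because it covers gene-space
regions no other method confirms — ends up excluded from the final
average automatically. The exclusion is a reproducible property of such
profiles, not a hard-coded method name; the same method still appears
as a regressor in the other rotations, where non-significant
coefficients neutralize it.

## Fitted values and coverage

A fitted rotation predicts $\hat y_{gm}$ for every gene whose retained
regressors are all observed, not only for the rows used in the fit.
This choice is what makes the ensemble useful under missingness: a gene
dropped by method $m$ but observed by the retained regressors still
receives a prediction from rotation $m$, so the rotations fill each
other's gaps. Restricting predictions to the fit rows would collapse
every rotation's domain to the genes complete in all retained columns
(about half the genes at 15% dropout) and cap the ensemble's recall
accordingly; predicting from the retained regressors raises coverage to
roughly nine genes in ten under the same dropout. Per gene, the mean
and the median of the covering rotations' fitted values are both
computed; the mean is the default input to selection and the median is
kept for comparison, since the two summaries can be confronted when
choosing a threshold.

## Selection by Tukey fences

Given per-gene values $v$, quartiles are computed by linear
interpolation of the order statistics at positions
$(n-1)\cdot\{0.25, 0.75\}$, and genes strictly outside
$[Q_1 - k\,\mathrm{IQR},\; Q_3 + k\,\mathrm{IQR}]$ are selected. The
interpolation is evaluated directly at those positions (rather than
through `stats::quantile`, whose internal $1+(n-1)p$ index arithmetic
can differ in the last bit and flip a value lying exactly on a fence);
fence membership is strict, so ties with a fence are *not* selected.
$k = 3$ is the default for ensemble predictions — the stringent choice
appropriate for a profile that is already a shrunken linear combination
of methods — while $k = 1.5$ (the boxplot whisker convention) is the
default for PC1 scores and for recovery benchmarking.

# The PCA alternative

Genes are observations and methods variables. Only complete-case genes
enter (no imputation before the decomposition: an imputation rule would
dominate PC1 under heavy dropout). Columns are centered, optionally
unit-scaled (off by default — log2FC columns share a unit, so
covariance PCA is the natural choice), and the first right singular
vector defines the principal axis. Per-gene scores are projections on
that axis; the sign is anchored so the method with the largest absolute
loading loads positively, making outputs deterministic across BLAS
implementations. Scores feed the same fence selection at $k = 1.5$.
Note that with an outlier method in the panel, PC1 may align with that
method's high-variance axis rather than with the shared signal; the
selection overlap between ARM and PCA is reported rather than assumed.

# Significance, filtering and accounting parameters

* `q_max` (default 0.05, **inclusive**) and `lfc_min` (default 0,
  **strict** when positive): per-method significance. The inclusive /
  strict pairing matches how such cutoffs are conventionally stated —
  an FDR of at most 5%, a fold change exceeding the floor. Genes
  lacking a q-value are never called.
* Expression inclusion filter: FPKM strictly > 1 and read count
  strictly > 10 in at least `ceiling(0.10 · n)` samples. The
  sample-fraction condition is inclusive (a 10% minimum); with
  `per_group = TRUE` (default) the rule must hold within every
  condition group separately — the stricter reading of requiring
  expression in both conditions — and a pooled mode is exposed for
  comparison.
* Annotation-version percentages are rounded half-up at two decimals so
  the shared and absent percentages of a split are complementary and
  reproducible.
* A log2FC of exactly 0 renders a gene sign-discordant when co-detected
  with any signed call: zero carries no direction.
* Best-hit association ranks by e-value with ties broken by bitscore,
  then lexicographically smallest subject id. The tie-breakers beyond
  e-value are a determinism choice (alignment tables carry frequent
  e-value ties at zero); the 90%-identity flag preserves the
  sequence-similarity caveat downstream without changing the winner.

# The synthetic generator

`sim_config()` defaults define the reference scenario: 5,000 genes, 5
methods, 10% truly DE with effect sizes $|\theta| \sim U(2, 4)$ log2
units and random sign, method channels
$y = a_m + b_m\theta + N(0, \sigma_m^2)$ with $\sigma_m \sim U(0.3,
0.8)$, 15% per-cell dropout, and one outlier method emitting
independent $N(0, 2^2)$. Effects of at least 2 log2 units against
sub-unit noise make true DE genes genuine boxplot outliers at 10%
prevalence, so recovery is a meaningful benchmark rather than a tuned
one. The generator is a pure function of its config (seed included).

What it emulates is exactly the structure ARM assumes — a shared signal
observed through biased, noisy, incomplete channels plus one unrelated
channel. What it does **not** emulate: count-level sampling noise and
library-size effects (the callers are upstream of this package, so
simulation targets their output scale), correlation between genes,
missingness that depends on expression level (dropout here is
independent of $\theta$), and fold-change-dependent variance. Passing
recovery tests therefore demonstrates the reconciliation machinery, not
robustness to every pathology of real RNA-Seq matrices.

# Numerical and degenerate-input policy

* OLS is solved by QR; a rank-deficient regressor block aborts with the
  dependent columns named (identical method profiles are the typical
  cause), rather than silently dropping columns.
* A fit needs at least (number of regressors + 2) usable rows.
* `iqr_select` requires ≥ 4 finite values; a constant vector yields
  IQR 0 and an empty selection, not an error.
* PCA aborts on zero total variance, on fewer than 4 complete-case
  genes, and on unit-scaling a zero-variance column.
* Benjamini–Hochberg q-values are computed by an in-package step-up
  implementation (the generator needs it to build fixtures); the
  standard library routine serves as a cross-check in the tests, not as
  the implementation.

# Known limitations

* Retention of a spurious regressor: backward elimination tests each
  surviving coefficient at $\alpha = 0.05$ without family-wise
  correction, so for a response truly independent of $p$ regressors the
  chance that some regressor ends up retained is of order
  $1-(1-\alpha)^p$ (10–15% for $p = 4$, selection effects included).
  A pure-noise method is therefore excluded from the ensemble in most
  but not all replicates; analyses that require certainty should
  inspect the per-rotation fit report rather than rely on the flag
  alone.
* Collinearity between method profiles is inherent (they share the
  biological signal); coefficients are interpretable only jointly, and
  the ensemble profile — a linear combination — is the intended output,
  not the individual betas. Penalized regression is a deliberate
  non-goal.
* `mean_fill` imputation is first-moment only and will attenuate
  fitted-value variance under heavy dropout; `complete_case` is the
  default for that reason.
* The test suite and the acceptance script run the reference scenario
  at 5,000 genes × 5 methods with 20 replicates for recovery metrics
  and 100 for the exclusion rate — sizes chosen to make the binomial
  noise on those rates small relative to the margins being checked.
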