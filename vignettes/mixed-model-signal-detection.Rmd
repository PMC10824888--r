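---
title: "Mixed-model disproportionality screening: model, algorithm, and simulation design"
author: "adrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-model disproportionality screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(adrscreen)
```

## The screening problem

Spontaneous reporting databases record suspected adverse drug reactions
(ADRs); disproportionality statistics ask whether ADR $j$ is reported with
drug $i$ more often than its overall reporting share predicts.  With the
2×2 counts $n_{ij}$ (drug and ADR), $n_{i\cdot}$ (drug margin),
$n_{\cdot j}$ (ADR margin) and $n$ (total), the classical measures are the
proportional reporting ratio
$\mathrm{PRR}_{ij} = \frac{n_{ij}/n_{i\cdot}}{(n_{\cdot j}-n_{ij})/(n-n_{i\cdot})}$,
the reporting odds ratio $\mathrm{ROR}_{ij} = ad/bc$, and the relative
reporting ratio $n_{ij}/E_{ij}$ with $E_{ij}=n_{i\cdot}n_{\cdot j}/n$.
A pair is a *signal* when the lower 95% confidence limit of PRR or ROR
exceeds 1.  `prr()`, `ror()` and `rrr()` implement these with the standard
log-scale Wald intervals,
$\mathrm{SE}^2(\log\mathrm{PRR}) = 1/a - 1/n_{i\cdot} + 1/c - 1/(n-n_{i\cdot})$
and $\mathrm{SE}^2(\log\mathrm{ROR}) = 1/a+1/b+1/c+1/d$, and the normal
0.975 quantile.  These are the conventional choices in pharmacovigilance
practice; a Haldane 0.5-cell correction exists behind a flag but is off by
default, because the zero-cell failure of the classical interval is real
behavior a screen comparison must preserve.

## One model for all ADRs

Screening $J$ ADRs classically means $J$ separate analyses, and any ADR with
$n_{ij}=0$ has no interval.  The package's central tool is a single
generalized linear mixed model over the long-format counts frame (one row
per exposure stratum × ADR).  For one drug with exposure indicator $x$:

$$\log \lambda_{j} = \beta_0 + b_{0j} + (\beta + b_j)\,x, \qquad
b_{0j}\sim N(0,\gamma_0),\; b_j \sim N(0,\gamma_1),$$

a Poisson model with offset $\log(\text{stratum denominator})$, so that
$\exp(\beta + b_j)$ is exactly the ADR-specific reporting-proportion ratio
(the PRR estimand); without the offset it would be a count ratio.  The
logistic twin with trials equal to the stratum denominators yields the ROR.
For a drug pair the fixed part is $\beta_1 x_1 + \beta_2 x_2 + \beta_{12}
x_1 x_2$ with four per-ADR random blocks, and
$\exp(\beta_{12} + b_{12,j})$ screens for multiplicative drug–drug
interaction.

Two structural decisions deserve comment:

* **Per-ADR random intercepts.**  A single scalar intercept deviation is
  confounded with $\beta_0$; the intercept block is therefore indexed by
  ADR, which is also what lets the model absorb ADR-to-ADR baseline
  heterogeneity in real data.
* **One shared variance per block.**  A free variance per ADR
  ($b_j \sim N(0,\gamma_j)$ with $J$ separate $\gamma_j$) is not
  identifiable from one observation per ADR per stratum; each block
  (intercept, each slope) carries a single variance component shared
  across ADRs.

## Estimation: restricted pseudo-likelihood

`fit_glmm()` alternates two steps until the fixed effects and variance
components stabilise:

1. **Linearization** about the current $\hat\beta,\hat b$:
   for Poisson, working response $z = (\eta - o) + (y-\mu)/\mu$ and weights
   $w = \mu$; for binomial, $z = \eta + (y/m - p)/(p(1-p))$, $w = m p(1-p)$.
   Means are floored at $10^{-10}$ (with a warning) so weights stay
   positive.
2. **REML on the working model** $z = X\beta + Zb + e$,
   $e \sim (0, \phi W^{-1})$: the variance components minimise
   $\sum_k J\log\gamma_k + n\log\phi - \sum\log w + \log|C| + r'Wr/\phi +
   b'G^{-1}b$, where $C$ is the mixed-model-equation coefficient matrix.
   $C$ is sparse (block-diagonal by ADR apart from the low-dimensional
   fixed rows) and is factored with `Matrix`'s sparse Cholesky, reusing
   the symbolic analysis across evaluations; the optimizer is
   bound-constrained quasi-Newton (`L-BFGS-B`) on $\log\gamma$ with
   $\gamma$ clamped at $10^{-10}$, started from $\gamma = 0.1$ and warm
   started across outer iterations.  Fixed effects start at the
   fixed-effect-only GLM solution.

The residual scale $\phi$ is fixed at 1 by default — the exact
Poisson/binomial variance assumption — with estimation available via
`scale_fixed = FALSE`.  The prediction covariance of $(\hat\beta,
\hat b - b)$ is the inverse of $C$; `predict_linear_combo()` reads any
combination $\ell_f'\hat\beta + \ell_r'\hat b$ and its standard error off
the stored factor, which is how the ADR-specific interval for
$\beta + b_j$ is produced.  Intervals exponentiate the linear-scale Wald
interval with the normal quantile (with $J \ge 100$ ADRs, degrees-of-freedom
corrections are negligible); no multiplicity adjustment is applied across
ADRs, matching the per-ADR signal rule.

**Convergence.**  The outer loop stops when the maximum relative change in
$(\beta, \gamma)$ falls below $10^{-4}$ (at most 100 iterations).  The
alternation has a genuine limit cycle of relative amplitude about
$10^{-5}$ — the inner optimizer with numerical gradients cannot localise
its optimum more finely, and the pseudo-data themselves move at that
order — so demanding much tighter outer tolerances turns healthy fits into
spurious failures without changing any reported digit.  A variance
component pinned at its lower bound is not an error (its BLUPs are zeroed);
failure of the outer loop is, and the error object carries the
per-iteration variance trace.

## What the simulation harness emulates

`generate_single()` draws, independently for each of $J$ ADRs, the exposed
count from $\mathrm{Bin}(n_{1\cdot}, p_{1j})$ and the unexposed count from
$\mathrm{Bin}(n - n_{1\cdot}, p_{1^-j})$, with $n = 10^7$ total reports and
$n_{1\cdot} = 10^4$ exposed by default; probabilities are entered in
percent, as such tables are printed.  `generate_ddi()` draws the four
exposure strata (sizes $10^7/10^5/10^5/10^4$) the same way; the
multiplicative-interaction null is $p_{00}p_{11}/(p_{10}p_{01}) = 1$.
One root seed plus the replicate index determines every stream, so
experiments are reproducible and parallelisable.  `run_experiment()`
generates, screens, and reports the percentage of ADRs flagged with its
Monte-Carlo standard error, counting (never silently dropping)
non-converged replicates.

What this generator deliberately does **not** emulate: multi-drug reports
(stratum denominators are fixed, not competing), ADR-to-ADR heterogeneity
in baseline reporting rates (all $J$ ADRs share one probability within a
setting), within-report correlation of ADR terms, and under-reporting
dynamics.  Passing simulation tests therefore validates calibration of the
machinery under clean binomial sampling, not performance on real FAERS
data, where baseline heterogeneity is large and drives the variance
components well away from zero.

## Shrinkage under homogeneous nulls: a candid analysis

Under the simulation design above, all $J$ ADRs share the same true
probabilities within a setting, so the true between-ADR variances are
zero.  A correctly converged REML fit then estimates $\hat\gamma_1$ at or
near its boundary, the slope BLUPs shrink (fully, at the boundary) toward
the pooled drug effect, and the ADR-specific intervals collapse toward the
pooled interval.  Consequences worth understanding before comparing with
per-ADR methods:

* Under a null with no drug effect, flagging becomes nearly all-or-nothing
  per replicate (the pooled effect is either significant or not), and the
  average flag rate sits near the one-sided 2.5% level rather than the
  small-count-inflated 3–5% of the per-ADR Wald rule.
* Under a uniformly elevated alternative (every ADR elevated by the same
  factor), the pooled effect is estimated from all ADRs jointly and is
  highly significant, so the mixed screen flags essentially *all* ADRs —
  per-ADR sensitivity figures computed from unshrunk per-ADR statistics
  are not reproducible by any correctly estimated shared-variance mixed
  model in this regime.  The two approaches agree closely precisely when
  real between-ADR heterogeneity keeps $\hat\gamma$ large, which is the
  situation in observed reporting databases (see the collapse-to-marginal
  and heterogeneous-recovery tests).

This is a property of the estimand/design combination, not a defect of the
estimation: the parameter-recovery experiment (true
$\gamma_0=\gamma_1=0.25$, $J=200$, large denominators) recovers every
parameter within Monte-Carlo error, and with all variances forced to zero
the engine reproduces GLM maximum likelihood to $10^{-8}$.

## Numerical choices and degenerate inputs

* Counting unit: one (report, ADR) pair counts once; duplicate terms
  within a report are deduplicated so that counts never exceed
  denominators.  All margins are report-level.
* ADRs with zero counts everywhere are retained in the counts frame; they
  remain estimable under the mixed model.
* A frame with a single ADR is rejected with a pointer to `prr()`/`ror()`
  (a mixed model over one group is vacuous).
* Aliased fixed-effect columns are reported by name; empty exposure strata
  are an error instructing to drop the drug combination.
* The parameter-recovery experiment in the test-suite uses exposed
  denominators of $10^6$: pseudo-likelihood linearization is known to bias
  variance components downward when cell counts are small (order
  $10^{-2}$ at counts near 100), and the experiment is designed in the
  asymptotic regime the estimator targets.
* Experiment sizes in the shipped tests and acceptance script — 1000
  replicates for the closed-form classical screens and for the mixed-model
  experiments, 100 replicates for parameter recovery — match the scale at
  which the sparse engine fits comfortably on one core.

## Known limitations

* Only 1- and 2-drug model builders are shipped; the counts-frame type
  accepts arbitrary indicator sets, but higher-order screens would need
  their own builders.
* No Laplace/quadrature maximum likelihood, no Bayesian estimation, and no
  additive-scale DDI criteria; shrinkage estimators of the BCPNN/MGPS
  family are out of scope.
* FAERS ingestion (quarterly ASCII files, MedDRA term mapping, report
  deduplication heuristics) is out of scope; inputs are delimited
  report-level or pre-aggregated count tables.
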