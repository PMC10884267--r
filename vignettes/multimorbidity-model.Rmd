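---
title: "Estimating the prevalence of condition combinations from odds ratios and marginal prevalences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the prevalence of condition combinations from odds ratios and marginal prevalences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multimorb)
```

## The problem

Health systems planning for multimorbidity need to know which pairs of
long-term conditions co-occur most often, and how many comorbidities to
expect in a patient presenting with a given index condition. Direct
estimates of joint prevalences are hard to obtain: national surveys are
underpowered for rare combinations, clinic-based studies are not
representative, and disease definitions vary across studies. What *is*
comparatively plentiful is pairwise association evidence — 2×2 tables from
many heterogeneous studies — and nationally representative estimates of the
*marginal* prevalence of each condition.

`multimorb` combines the two: it synthesises the association evidence into a
single odds ratio per condition pair, standardised to national prevalence
levels, and then converts odds ratios plus marginals into joint prevalences,
conditional comorbidity profiles and expected comorbidity counts, with
parametric-bootstrap uncertainty throughout.

## The model

### From odds ratio and marginals to joint prevalence

For conditions $i$ and $j$ with population prevalences $P_i$, $P_j$ and
joint prevalence $P_{ij}$, the odds ratio is the cross-product ratio of the
2×2 population table:

$$\theta_{ij} \;=\; \frac{P_{ij}\,(1 - P_i - P_j + P_{ij})}
  {(P_i - P_{ij})(P_j - P_{ij})}.$$

Given $\theta_{ij}$, $P_i$ and $P_j$, this is a quadratic in $P_{ij}$. With
$A = 1 + (\theta - 1)(P_i + P_j)$, the admissible root is

$$P_{ij} \;=\; \frac{A - \sqrt{A^2 - 4\theta(\theta - 1) P_i P_j}}
  {2(\theta - 1)},$$

the only root inside the Fréchet bounds
$[\max(0, P_i + P_j - 1),\, \min(P_i, P_j)]$. `solve_joint_prevalence()`
evaluates the algebraically identical rationalised form

$$P_{ij} \;=\; \frac{2\,\theta\, P_i P_j}{A + \sqrt{A^2 - 4\theta(\theta-1) P_i P_j}},$$

which we prefer for two numerical reasons: it is continuous through
$\theta = 1$ (where it reduces exactly to the independence value $P_i P_j$,
so no special-case branch is needed) and it avoids the subtractive
cancellation the textbook form suffers when $\theta$ is large and
$P_i \approx P_j$. A discriminant that is negative by less than $10^{-12}$
is treated as zero (floating-point guard); anything more negative is an
error rather than a silent clip. The test suite verifies the closed form
against an independent bisection oracle to $10^{-10}$ and round-trips
$\theta \to P_{ij} \to \theta$ to a relative $10^{-8}$ over a grid of
marginals and odds ratios spanning $\theta \in [0.1, 50]$.

The conditional prevalence of $j$ in people with $i$ is $P_{ij}/P_i$, and
the expected number of comorbidities in people with index condition $i$ is

$$M_i \;=\; \sum_{j \ne i} \frac{P_{ij}}{P_i},$$

with variance approximated as the sum of the bootstrap variances of the
$P_{ij}/P_i$ terms (independence approximation across partners). A
log-linear regression of $\ln M_i$ on $P_i$ summarises how comorbidity
burden falls with the prevalence of the index condition;
`fit_comorbidity_regression()` reports the slope, the multiplicative change
in $M$ per 10-percentage-point increase in prevalence
($e^{0.1 \cdot \text{slope}}$), and the Pearson correlation computed on the
$(\ln M_i, P_i)$ scale — the scale on which the model is linear.

### Why a meta-regression, not a plain pooled OR

Observed odds ratios for the same condition pair differ systematically
across studies, and much of that heterogeneity is mechanical rather than
biological. Studies recruited at health facilities under-represent people
with *no* conditions. `apply_healthy_exclusion()` formalises this: multiply
the neither-condition cell of the population table by a retention factor
$\phi \in (0, 1]$ and renormalise. Because only one cell is scaled, the
cross-product ratio of the distorted table is *exactly* $\phi$ times the
original odds ratio — an algebraic identity the tests check on a grid. As
$\phi \to 0$ (pure patient samples) a positive association can reverse
sign. Since facility samples also show higher apparent prevalences, the
observed OR ends up negatively related to the product of the study
prevalences $P_i P_j$ — the expected prevalence of the combination under
independence.

`fit_meta_regression()` therefore models, across the $k$ studies of a pair,

$$\log \theta_s \;=\; c + m \,(P_{i,s} P_{j,s}) + u_s + \varepsilon_s,
  \qquad u_s \sim N(0, \tau^2),$$

with random-effects weighting (REML estimate of $\tau^2$; method-of-moments
fallback if REML fails to converge). Predicting at the *national* marginals
standardises the OR: $\hat\theta_{ij} = \exp(m P_i P_j + c)$. With fewer
than three studies the moderator cannot be fit and
`pool_random_effects()` provides a DerSimonian–Laird pooled log OR instead;
pairs with no local evidence at all can be given a fixed external OR. The
rule is automated by `select_synthesis()`. Both fits are delegated to
`metafor::rma()`; the coefficient covariance used by the bootstrap is the
weighted-least-squares information matrix at the final $\tau^2$. The
Knapp–Hartung small-sample adjustment is available via `knha = TRUE` but is
off by default.

Per-study inputs are unadjusted ORs from 2×2 tables, with the Woolf
standard error $\sqrt{\sum 1/n_{kl}}$. When any cell is zero, the
Haldane–Anscombe correction adds 0.5 to all four cells; tables without
zeros are used untouched. Study-level prevalences for the moderator are
taken from the table margins, never supplied separately, so the moderator
is always internally consistent with the effect estimate.

## Uncertainty propagation

`bootstrap_pair()` performs a parametric bootstrap. Per iteration it draws

1. $P_i^* \sim N(P_i, \mathrm{se}_i)$ and $P_j^* \sim N(P_j, \mathrm{se}_j)$,
   truncated into $(\text{floor}, 1 - \text{floor})$ with floor $10^{-6}$
   — truncation rather than redraw, so the iteration count and the seeded
   stream are preserved;
2. association parameters: $(m, c)$ jointly from a bivariate normal with
   their estimated covariance (meta-regression pairs), or
   $\log\theta^* \sim N(\widehat{\log\theta}, \mathrm{se})$ (pooled or
   fixed pairs);
3. $P_{ij}^*$ from the quadratic.

Marginal-prevalence SEs are derived from printed 95% CIs as the full CI
width divided by $2 \times 1.959964$, which handles the asymmetric
intervals that logit-scale survey estimates produce. All draws come from a
single seeded RNG stream in the fixed order above, so a run is bit-for-bit
reproducible from `(seed, n_iter)`; the rare solver failure is redrawn and
counted, and a failure rate above 1% aborts with diagnostics. CIs are
percentile intervals (default 10,000 iterations, 95% level). For $M_i$ the
variance-sum normal approximation $M_i \pm 1.959964\sqrt{\widehat{\mathrm{Var}}(M_i)}$
is reported alongside a percentile interval of the per-iteration sums.
`run_pipeline()` gives each pair its own sub-seed derived deterministically
from the configured seed, so the whole report bundle reproduces from one
integer recorded in the run manifest.

## Key parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `correction` | 0.5 | counts | zero-cell continuity correction, applied only when a cell is zero |
| `n_iter` | 10000 | iterations | bootstrap replicates behind every CI |
| `ci_level` | 0.95 | — | CI level for percentile and normal intervals |
| `prevalence_floor` | 1e-6 | proportion | truncation bound for sampled prevalences |
| `knha` | FALSE | — | Knapp–Hartung adjustment in meta-regression |
| `units` | percent | — | prevalence CSVs may be percent or proportion; all computation is in proportions |

## The synthetic-data generator

`simulate_study_series()` generates the study series the analysis assumes:
per study, prevalences drawn uniformly from stated ranges, a true log OR on
the surface $c + m P_i P_j$ plus $N(0, \tau)$ scatter, the joint prevalence
from the quadratic, an optional healthy-exclusion distortion (applied to
the cell *probabilities* before sampling, so the OR-scaling identity is
exact), and multinomial cell counts at the study size. The defaults —
slope −15, intercept 1.5, $\tau = 0.1$, 50 studies of 5,000 people,
prevalences 2–40% — describe a series of moderately sized epidemiological
studies of conditions in the few-percent to tens-of-percent range with a
mildly negative prevalence dependence; the 2–40% spread covers both
community surveys and the higher prevalences seen in facility samples.

The generator deliberately simulates each study×pair from its own
multinomial rather than from a 10-condition multivariate binary model: the
analysis consumes only pairwise tables, and a full joint model would add
assumptions the method never uses. It has no age or sex structure, no
secular trends, and no three-way dependence, so passing recovery tests show
that the *pipeline* is consistent under its own assumptions — not that real
heterogeneous study series satisfy those assumptions. Real data add
definition heterogeneity and selection effects beyond the single
healthy-retention mechanism modelled here; in the model those appear only
as residual $\tau^2$.

## Numerical and design choices

- **Rationalised quadratic root** (above): continuity at $\theta = 1$ and
  stability at large $\theta$; the minus-root choice is asserted by the
  Fréchet-bound and round-trip tests rather than assumed.
- **Heterogeneity estimators**: REML for meta-regression, DerSimonian–Laird
  for plain pooling — the common defaults in meta-analytic practice; both
  are configuration, not hard-wired science.
- **Truncation, not rejection**, of out-of-range prevalence draws:
  preserves the iteration count and determinism; rejection is reserved for
  solver failures, which are counted and bounded.
- **Degenerate inputs**: all-zero tables, zero margins after correction,
  joints at or outside the Fréchet bounds, non-positive odds ratios, and
  constant moderators are errors with diagnostics, never silent repairs.
- **Problem sizes in the test suite**: the suite exercises a 7×20×20
  oracle grid, 100–200-replicate recovery and coverage experiments at
  $k = 50$ studies of 5,000, and bootstrap runs of 2,000–20,000
  iterations — sizes at which the Monte-Carlo error of each check is small
  relative to its tolerance while the whole suite runs in minutes on one
  core.

## Limitations

- Pairwise only: combinations of three or more conditions are outside the
  odds-ratio model.
- The ORs are crude (unadjusted) by design — the joint-distribution
  inversion requires marginal, not conditional, association measures — so
  they must not be read causally.
- Marginal prevalences are sampled independently across conditions in the
  bootstrap, and the variance of $M_i$ sums conditional variances as if
  partners were independent; both understate dependence between estimates
  that share source data.
- The healthy-retention model is a one-parameter formalisation of
  facility-sampling distortion; real selection mechanisms are richer.
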