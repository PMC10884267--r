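# multimorb

Model-based estimation of the prevalence of disease combinations from
heterogeneous pairwise association evidence and national marginal
prevalences.

## The problem

Estimates of how often two long-term conditions occur *together* are needed
to plan multimorbidity care, but they are hard to measure directly: national
surveys are underpowered for rare combinations, and the many smaller studies
that do report 2×2 co-occurrence tables differ in setting, definitions and
sampling frame. `multimorb` is for epidemiologists and health-systems
analysts who have (a) a pile of per-study 2×2 contingency tables or log
odds-ratio estimates for condition pairs, and (b) nationally representative
marginal prevalence estimates with CIs, and who want nationally standardised
joint prevalences, conditional comorbidity profiles, and expected
comorbidity counts with defensible uncertainty intervals.

## The model in brief

For conditions *i*, *j* with marginal prevalences `Pi`, `Pj`, joint
prevalence `Pij` and odds ratio

```
theta = Pij (1 - Pi - Pj + Pij) / [(Pi - Pij)(Pj - Pij)],
```

knowing `theta`, `Pi`, `Pj` determines `Pij` as the root of a quadratic
inside the Fréchet bounds; with `A = 1 + (theta-1)(Pi+Pj)`,

```
Pij = 2 theta Pi Pj / (A + sqrt(A^2 - 4 theta (theta-1) Pi Pj)).
```

Per-pair odds ratios are synthesised across studies by random-effects
meta-analysis (DerSimonian–Laird), or — when three or more studies exist —
by a REML meta-regression of the log OR on the product of the study
prevalences `Pi*Pj`. That moderator absorbs the mechanical dependence of
observed ORs on the sampling frame (facility samples exclude healthy
people, which scales the OR by exactly the healthy-retention factor), and
predicting at the *national* prevalences standardises the OR. A parametric
bootstrap — normal draws for the marginals, joint multivariate-normal draws
for the meta-regression coefficients — propagates uncertainty into every
output. The expected comorbidity count of an index condition is
`M_i = sum_j Pij / Pi`. See the methods vignette
(`vignettes/multimorbidity-model.Rmd`) for the full account.

## Worked example

South African national marginals (packaged, ages 15+) for four conditions,
with published pooled ORs for the three strongest pairs:

```r
library(multimorb)

prevs <- national_prevalence_fixture(as_estimates = TRUE)[
  c("COPD", "Asthma", "IHD", "Stroke")]
ors <- data.frame(
  cond_a = c("COPD", "COPD", "IHD"),
  cond_b = c("Asthma", "IHD", "Stroke"),
  or        = c(14.6, 9.2, 7.2),
  se_log_or = c(0.168, 0.0527, 0.0899))

res <- run_pipeline(prevs, fixed_or = ors,
                    bootstrap = bootstrap_config(n_iter = 10000, seed = 1))
res$pairs[, c("cond_a", "cond_b", "theta", "p_joint", "p_lo", "p_hi",
              "p_b_given_a", "p_a_given_b")]
#>   cond_a cond_b theta p_joint    p_lo    p_hi p_b_given_a p_a_given_b
#> 1   COPD Asthma  14.6 0.00559 0.00414 0.00726       0.311       0.160
#> 2   COPD    IHD   9.2 0.00595 0.00453 0.00746       0.331       0.106
#> 3    IHD Stroke   7.2 0.00716 0.00485 0.00966       0.128       0.275

round(100 * res$conditional_matrix, 1)
#>        COPD Asthma  IHD Stroke
#> COPD     NA   31.1 33.1     NA
#> Asthma 16.0     NA   NA     NA
#> IHD    10.6     NA   NA   12.8
#> Stroke   NA     NA 27.5     NA
```

Reading the conditional matrix (rows = index condition): 0.56% of adults
have both COPD and asthma; among people with asthma 16% have COPD, while
among the much smaller COPD group 31% have asthma; 13% of people with IHD
have had a stroke, and 33% of people with COPD have IHD. `p_lo`/`p_hi` are
95% percentile bootstrap CIs for the joint prevalence.

The synthetic-data generator closes the loop on the evidence-synthesis
side — simulate a 50-study series from a known log-OR surface and recover
it:

```r
sc  <- simulation_scenario(seed = 7)   # slope -15, intercept 1.5, tau 0.1
fit <- fit_meta_regression(simulate_study_series(sc))
fit
#> <pair_association> A -- B [metareg, k=50]
#>   log OR = 1.4943 + -14.5599 * (Pi*Pj), tau2 = 0.0131
```

A thin command-line wrapper is included at `inst/scripts/multimorb.R`
(`run-all` and `simulate` subcommands over CSV inputs).

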