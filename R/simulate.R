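#' Cell probabilities of the 2x2 population table
#'
#' From the two marginal prevalences and the joint prevalence, returns the
#' four cell probabilities `(both, A only, B only, neither)`.
#'
#' @param p_i,p_j Marginal prevalences.
#' @param p_ij Joint prevalence, within the Frechet bounds.
#' @return Numeric vector `c(p11, p10, p01, p00)` summing to 1.
#' @export
cell_probabilities <- function(p_i, p_j, p_ij) {
  cells <- c(p11 = p_ij, p10 = p_i - p_ij, p01 = p_j - p_ij,
             p00 = 1 - p_i - p_j + p_ij)
  if (any(cells < 0)) {
    stop("negative cell probability: p_ij violates the Frechet bounds")
  }
  cells
}

#' Healthy-exclusion sampling distortion
#'
#' Models a sampling frame that under-represents people with no conditions
#' (clinic or facility samples): the neither-condition cell is multiplied by
#' the retention factor `phi` and the table renormalised. Because only one
#' cell is scaled, the cross-product odds ratio of the distorted table equals
#' exactly `phi` times the original odds ratio -- the mechanism by which the
#' observed association shrinks (and, in pure-patient samples, reverses) as
#' the healthy fraction of the sample falls, and hence why observed ORs fall
#' with the expected prevalence of the combination.
#'
#' @param cells Four cell probabilities `(p11, p10, p01, p00)` summing to 1.
#' @param retention Fraction of the healthy cell retained, in (0, 1].
#' @return Renormalised four-vector of cell probabilities.
#' @export
apply_healthy_exclusion <- function(cells, retention) {
  if (retention <= 0) stop("retention must be positive")
  if (retention > 1) stop("retention must not exceed 1")
  if (abs(sum(cells) - 1) > 1e-8) stop("cells must sum to 1")
  out <- cells
  out[4] <- out[4] * retention
  out / sum(out)
}

#' Simulation scenario for a study series
#'
#' Defines the generative model behind a series of observational studies of
#' one condition pair: study prevalences are drawn uniformly from the given
#' ranges, the true log OR follows the surface
#' `log theta = intercept_c + slope_m * Pi * Pj` with Normal(0, tau)
#' between-study scatter, the joint prevalence is recovered by the quadratic,
#' an optional healthy-exclusion distortion is applied, and cell counts are
#' drawn from a multinomial of the study size. The defaults describe a series
#' of moderately sized epidemiological studies whose condition prevalences
#' span 2-40%, with a mildly negative prevalence dependence of the OR and
#' modest residual heterogeneity.
#'
#' @param slope_m,intercept_c Coefficients of the log-OR surface.
#' @param tau Between-study SD of the log OR (>= 0).
#' @param k_studies Number of studies.
#' @param study_size Individuals per study; a single size or a `(min, max)`
#'   range sampled uniformly per study. Must be at least 20.
#' @param prev_range_a,prev_range_b Ranges of study-level prevalences.
#' @param healthy_retention Retention factor `phi` in (0, 1]; a single value
#'   applied to every study, or a `(min, max)` range drawn per study to
#'   emulate a mix of community and facility-based sampling frames.
#' @param seed Integer seed making the series reproducible.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(slope_m = -15, intercept_c = 1.5, tau = 0.1,
                                k_studies = 50, study_size = 5000,
                                prev_range_a = c(0.02, 0.40),
                                prev_range_b = c(0.02, 0.40),
                                healthy_retention = 1, seed = 1L) {
  stopifnot(tau >= 0, k_studies >= 0,
            all(study_size >= 20), length(study_size) %in% 1:2,
            length(prev_range_a) == 2, length(prev_range_b) == 2,
            all(prev_range_a > 0 & prev_range_a < 1),
            all(prev_range_b > 0 & prev_range_b < 1),
            all(healthy_retention > 0 & healthy_retention <= 1),
            length(healthy_retention) %in% 1:2)
  structure(
    list(slope_m = slope_m, intercept_c = intercept_c, tau = tau,
         k_studies = as.integer(k_studies), study_size = study_size,
         prev_range_a = prev_range_a, prev_range_b = prev_range_b,
         healthy_retention = healthy_retention, seed = as.integer(seed)),
    class = "simulation_scenario"
  )
}

#' Simulate a series of 2x2 studies from a log-OR surface
#'
#' @param scenario A [simulation_scenario()].
#' @return A prepared study table (see [prepare_studies()]) with columns
#'   `study_id`, `cond_a`, `cond_b`, the four counts, `log_or`, `se_log_or`,
#'   `prev_a`, `prev_b`; deterministic given the scenario seed. An attribute
#'   `n_redrawn` counts studies redrawn because a draw left the model domain.
#' @export
simulate_study_series <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed)
  k <- scenario$k_studies
  empty <- data.frame(
    study_id = character(0), cond_a = character(0), cond_b = character(0),
    n11 = integer(0), n10 = integer(0), n01 = integer(0), n00 = integer(0),
    log_or = numeric(0), se_log_or = numeric(0),
    prev_a = numeric(0), prev_b = numeric(0)
  )
  if (k == 0) return(empty)
  rows <- vector("list", k)
  n_redrawn <- 0L
  for (s in seq_len(k)) {
    repeat {
      p_i <- runif(1, scenario$prev_range_a[1], scenario$prev_range_a[2])
      p_j <- runif(1, scenario$prev_range_b[1], scenario$prev_range_b[2])
      log_theta <- scenario$intercept_c + scenario$slope_m * p_i * p_j +
        rnorm(1, 0, scenario$tau)
      cells <- tryCatch({
        p_ij <- solve_joint_prevalence(p_i, p_j, exp(log_theta))
        cell_probabilities(p_i, p_j, p_ij)
      }, error = function(e) NULL)
      if (!is.null(cells)) break
      n_redrawn <- n_redrawn + 1L
    }
    phi <- if (length(scenario$healthy_retention) == 2) {
      runif(1, scenario$healthy_retention[1], scenario$healthy_retention[2])
    } else scenario$healthy_retention
    if (phi < 1) cells <- apply_healthy_exclusion(cells, phi)
    n <- if (length(scenario$study_size) == 2) {
      sample(scenario$study_size[1]:scenario$study_size[2], 1)
    } else scenario$study_size
    counts <- as.integer(rmultinom(1, n, cells))
    rows[[s]] <- data.frame(
      study_id = sprintf("sim%03d", s), cond_a = "A", cond_b = "B",
      n11 = counts[1], n10 = counts[2], n01 = counts[3], n00 = counts[4],
      log_or = NA_real_, se_log_or = NA_real_,
      prev_a = NA_real_, prev_b = NA_real_
    )
  }
  out <- prepare_studies(do.call(rbind, rows))
  attr(out, "n_redrawn") <- n_redrawn
  out
}

#' National prevalence fixture (South Africa, ages 15+)
#'
#' Packaged table of national prevalence estimates with 95% CIs for the ten
#' modelled conditions (arthritis, asthma, COPD, depression, diabetes,
#' HIV/AIDS, hypertension, IHD/angina, stroke, tuberculosis) in the
#' population aged 15 and older, as percentages.
#'
#' @param as_estimates If `TRUE`, return a named list of
#'   [prevalence_estimate()] objects (proportions); otherwise the raw data
#'   frame in percent.
#' @return Data frame with columns `condition`, `prev`, `ci_low`, `ci_high`
#'   (percent), or a list of `prevalence_estimate` objects.
#' @export
national_prevalence_fixture <- function(as_estimates = FALSE) {
  path <- system.file("extdata", "national_prevalence_za.csv",
                      package = "multimorb")
  tab <- read_prevalence_csv(path, units = "percent", as_estimates = FALSE)
  if (!as_estimates) {
    tab[c("prev", "ci_low", "ci_high")] <-
      lapply(tab[c("prev", "ci_low", "ci_high")], function(x) 100 * x)
    return(tab)
  }
  prevalence_list(tab)
}
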