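#' Parametric bootstrap configuration
#'
#' @param n_iter Number of bootstrap iterations (default 10000; at least 100
#'   for CI output).
#' @param seed Integer seed; every draw in a bootstrap run flows from it.
#' @param ci_level CI level in (0, 1), default 0.95.
#' @param prevalence_floor Sampled prevalences are truncated into
#'   `(floor, 1 - floor)` (default 1e-6) so the joint-prevalence solver always
#'   receives valid marginals.
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_iter = 10000, seed = 1L, ci_level = 0.95,
                             prevalence_floor = 1e-6) {
  stopifnot(n_iter >= 100, ci_level > 0, ci_level < 1,
            prevalence_floor > 0, prevalence_floor < 0.5)
  structure(list(n_iter = as.integer(n_iter), seed = as.integer(seed),
                 ci_level = ci_level, prevalence_floor = prevalence_floor),
            class = "bootstrap_config")
}

draw_theta <- function(assoc, p_i, p_j, n) {
  if (assoc$mode == "metareg") {
    mc <- MASS::mvrnorm(n, mu = c(assoc$slope_m, assoc$intercept_c),
                        Sigma = assoc$cov_mc)
    if (n == 1) mc <- matrix(mc, nrow = 1)
    exp(mc[, 1] * p_i * p_j + mc[, 2])
  } else {
    exp(rnorm(n, assoc$pooled_log_or, assoc$pooled_se))
  }
}

#' Parametric bootstrap for one condition pair
#'
#' Propagates the uncertainty in the two marginal prevalences and in the
#' association into the joint prevalence. Each iteration draws
#' `Pi* ~ N(prev_i, se_i)` and `Pj* ~ N(prev_j, se_j)`, truncated into
#' `(floor, 1 - floor)`; then draws the association parameters -- `(m, c)`
#' jointly from a multivariate normal using their covariance for
#' meta-regression pairs, or `log theta* ~ N(pooled_log_or, pooled_se)` for
#' pooled/fixed pairs -- and solves the quadratic for `p_ij*`. Draw order is
#' fixed (all `Pi*`, then all `Pj*`, then the association draws) so results
#' are reproducible given `(seed, n_iter)`. Iterations where the solver fails
#' are redrawn; more than 1% failures is an error.
#'
#' @param prev_i,prev_j [prevalence_estimate()] objects.
#' @param assoc A [pair_association()].
#' @param cfg A [bootstrap_config()].
#' @return A list of class `pair_bootstrap`: the point `estimate`
#'   (a completed [pair_prevalence()] with percentile CI), `replicates`
#'   (data frame with `p_i`, `p_j`, `theta`, `p_ij`), percentile `ci_p_joint`,
#'   `ci_theta`, and conditional-replicate summaries.
#' @export
bootstrap_pair <- function(prev_i, prev_j, assoc, cfg = bootstrap_config()) {
  stopifnot(inherits(cfg, "bootstrap_config"))
  set.seed(cfg$seed)
  n <- cfg$n_iter
  fl <- cfg$prevalence_floor
  pi_star <- pmin(pmax(rnorm(n, prev_i$prev, prev_i$se), fl), 1 - fl)
  pj_star <- pmin(pmax(rnorm(n, prev_j$prev, prev_j$se), fl), 1 - fl)
  theta_star <- draw_theta(assoc, pi_star, pj_star, n)
  p_ij <- solve_joint_prevalence(pi_star, pj_star, theta_star)

  bad <- which(!is.finite(p_ij))
  n_redrawn <- length(bad)
  if (n_redrawn > 0.01 * n) {
    stop(sprintf("solver failed in %d/%d bootstrap iterations for %s-%s",
                 n_redrawn, n, prev_i$condition, prev_j$condition))
  }
  for (i in bad) {
    repeat {
      pi_i <- min(max(rnorm(1, prev_i$prev, prev_i$se), fl), 1 - fl)
      pj_i <- min(max(rnorm(1, prev_j$prev, prev_j$se), fl), 1 - fl)
      th_i <- draw_theta(assoc, pi_i, pj_i, 1)
      val <- tryCatch(solve_joint_prevalence(pi_i, pj_i, th_i),
                      error = function(e) NA_real_)
      if (is.finite(val)) {
        pi_star[i] <- pi_i; pj_star[i] <- pj_i
        theta_star[i] <- th_i; p_ij[i] <- val
        break
      }
    }
  }

  alpha <- (1 - cfg$ci_level) / 2
  qs <- c(alpha, 1 - alpha)
  est <- pair_prevalence(prev_i, prev_j, assoc)
  ci_p <- unname(quantile(p_ij, qs, type = 7))
  est$ci_low <- ci_p[1]
  est$ci_high <- ci_p[2]
  cond_b_given_a <- p_ij / pi_star
  cond_a_given_b <- p_ij / pj_star
  structure(
    list(
      estimate = est,
      replicates = data.frame(p_i = pi_star, p_j = pj_star,
                              theta = theta_star, p_ij = p_ij),
      ci_p_joint = ci_p,
      ci_theta = unname(quantile(theta_star, qs, type = 7)),
      theta_boot_mean = mean(theta_star),
      ci_b_given_a = unname(quantile(cond_b_given_a, qs, type = 7)),
      ci_a_given_b = unname(quantile(cond_a_given_b, qs, type = 7)),
      var_b_given_a = var(cond_b_given_a),
      var_a_given_b = var(cond_a_given_b),
      n_redrawn = n_redrawn
    ),
    class = "pair_bootstrap"
  )
}

#' Bootstrap CI for the expected number of comorbidities
#'
#' Combines per-partner bootstrap replicates of the conditionals
#' `p_ij / p_index` into the expected comorbidity count
#' `M = sum_j p_ij / p_index`. The variance of `M` is approximated as the sum
#' of the per-partner conditional variances (independence approximation) and
#' the CI reported as `M +/- 1.959964 sqrt(var_m)`; a percentile CI of the
#' per-iteration sums is reported alongside.
#'
#' @param index Index condition name.
#' @param conditional_replicates Matrix (iterations x partners) of bootstrap
#'   replicates of `p_ij / p_index`, with partner conditions as column names.
#' @param m_point Point estimate of `M` (sum of plug-in conditionals); if
#'   `NULL`, the mean of the replicate sums is used.
#' @param ci_level CI level (default 0.95).
#' @return List with `m_expected`, `var_m`, normal-approximation
#'   `ci_low`/`ci_high`, and `ci_percentile`.
#' @export
bootstrap_comorbidity <- function(index, conditional_replicates,
                                  m_point = NULL, ci_level = 0.95) {
  if (is.list(conditional_replicates) && !is.data.frame(conditional_replicates)) {
    lens <- lengths(conditional_replicates)
    if (length(unique(lens)) > 1) {
      stop("mismatched replicate lengths across partners: ",
           paste(lens, collapse = ", "))
    }
    conditional_replicates <- do.call(cbind, conditional_replicates)
  }
  reps <- as.matrix(conditional_replicates)
  if (is.null(dim(reps)) || ncol(reps) < 1) stop("no partner replicates")
  if (any(!is.finite(reps))) stop("non-finite conditional replicates")
  var_m <- sum(apply(reps, 2, var))
  m <- if (is.null(m_point)) mean(rowSums(reps)) else m_point
  alpha <- (1 - ci_level) / 2
  z <- qnorm(1 - alpha)
  list(
    index_condition = index,
    m_expected = m,
    var_m = var_m,
    ci_low = m - z * sqrt(var_m),
    ci_high = m + z * sqrt(var_m),
    ci_percentile = unname(quantile(rowSums(reps), c(alpha, 1 - alpha),
                                    type = 7))
  )
}
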