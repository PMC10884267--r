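#' National marginal prevalence estimate
#'
#' Holds a condition's marginal prevalence with its 95% CI; the SE is derived
#' as the full CI width divided by 2 * 1.959964, which also accommodates the
#' asymmetric intervals that survey estimates on the logit scale produce.
#'
#' @param condition Condition name.
#' @param prev Prevalence as a proportion in (0, 1).
#' @param ci_low,ci_high 95% CI bounds (proportions).
#' @return An object of class `prevalence_estimate` with a derived `se`.
#' @export
prevalence_estimate <- function(condition, prev, ci_low = prev, ci_high = prev) {
  stopifnot(is.finite(prev), prev > 0, prev < 1)
  if (ci_low > prev || ci_high < prev) {
    stop(condition, ": requires ci_low <= prev <= ci_high")
  }
  structure(
    list(condition = condition, prev = prev, ci_low = ci_low,
         ci_high = ci_high, se = (ci_high - ci_low) / (2 * Z95)),
    class = "prevalence_estimate"
  )
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat(sprintf("<prevalence_estimate> %s: %.2f%% (%.2f-%.2f), SE %.4f\n",
              x$condition, 100 * x$prev, 100 * x$ci_low, 100 * x$ci_high,
              x$se))
  invisible(x)
}

frechet_bounds <- function(p_i, p_j) {
  c(lower = max(0, p_i + p_j - 1), upper = min(p_i, p_j))
}

#' Odds ratio implied by marginal and joint prevalences
#'
#' The cross-product ratio of the 2x2 population table with margins
#' `p_i`, `p_j` and joint cell `p_ij`:
#' `theta = p_ij (1 - p_i - p_j + p_ij) / ((p_i - p_ij)(p_j - p_ij))`.
#'
#' @param p_i,p_j Marginal prevalences in (0, 1).
#' @param p_ij Joint prevalence, strictly inside the Frechet bounds
#'   `(max(0, p_i + p_j - 1), min(p_i, p_j))`.
#' @return The odds ratio (positive scalar); vectorised over its arguments.
#' @export
odds_ratio_from_joint <- function(p_i, p_j, p_ij) {
  stopifnot(all(p_i > 0 & p_i < 1), all(p_j > 0 & p_j < 1))
  lo <- pmax(0, p_i + p_j - 1)
  hi <- pmin(p_i, p_j)
  if (any(p_ij <= lo | p_ij >= hi)) {
    stop("degenerate joint: p_ij must lie strictly inside the Frechet bounds")
  }
  (p_ij * (1 - p_i - p_j + p_ij)) / ((p_i - p_ij) * (p_j - p_ij))
}

#' Joint prevalence from marginals and an odds ratio
#'
#' Inverts the cross-product relation by solving its quadratic in the joint
#' prevalence. With `A = 1 + (theta - 1)(p_i + p_j)`, the admissible root is
#' `p_ij = (A - sqrt(A^2 - 4 theta (theta - 1) p_i p_j)) / (2 (theta - 1))`,
#' evaluated in the numerically stable rationalised form
#' `2 theta p_i p_j / (A + sqrt(A^2 - 4 theta (theta - 1) p_i p_j))`,
#' which is continuous through `theta = 1` (where it equals `p_i * p_j`, the
#' independence value) and avoids cancellation for large `theta`. The result
#' always lies inside the Frechet bounds for `theta > 0`.
#'
#' @param p_i,p_j Marginal prevalences in (0, 1).
#' @param theta Odds ratio (positive).
#' @return The joint prevalence; vectorised over its arguments.
#' @export
solve_joint_prevalence <- function(p_i, p_j, theta) {
  stopifnot(all(is.finite(p_i) & p_i > 0 & p_i < 1),
            all(is.finite(p_j) & p_j > 0 & p_j < 1))
  if (any(!is.finite(theta) | theta <= 0)) stop("theta must be positive")
  a <- 1 + (theta - 1) * (p_i + p_j)
  disc <- a^2 - 4 * theta * (theta - 1) * p_i * p_j
  neg <- disc < 0
  if (any(disc[neg] < -1e-12)) {
    stop("negative discriminant beyond numerical tolerance: ",
         format(min(disc)), "; inputs outside the model's domain")
  }
  disc[neg] <- 0
  2 * theta * p_i * p_j / (a + sqrt(disc))
}

#' Joint and conditional prevalence for one condition pair
#'
#' Combines two national marginal prevalence estimates with a synthesised
#' association: the OR is predicted at the national prevalences
#' ([predict_or()]), the joint prevalence recovered by
#' [solve_joint_prevalence()], and both conditionals `p_ij / p_i` (partner
#' prevalence in the index condition's patients) are reported. CI fields are
#' filled by [bootstrap_pair()].
#'
#' @param prev_i,prev_j [prevalence_estimate()] objects.
#' @param assoc A [pair_association()] for the same pair.
#' @return An object of class `pair_prevalence`.
#' @export
pair_prevalence <- function(prev_i, prev_j, assoc) {
  stopifnot(inherits(prev_i, "prevalence_estimate"),
            inherits(prev_j, "prevalence_estimate"))
  theta <- predict_or(assoc, prev_i$prev, prev_j$prev)
  p_ij <- solve_joint_prevalence(prev_i$prev, prev_j$prev, theta)
  structure(
    list(cond_a = prev_i$condition, cond_b = prev_j$condition,
         p_joint = p_ij,
         p_b_given_a = p_ij / prev_i$prev,
         p_a_given_b = p_ij / prev_j$prev,
         ci_low = NA_real_, ci_high = NA_real_,
         theta_used = theta),
    class = "pair_prevalence"
  )
}

#' @export
print.pair_prevalence <- function(x, ...) {
  cat(sprintf("<pair_prevalence> %s & %s: Pij = %.4f%% (theta = %.2f)\n",
              x$cond_a, x$cond_b, 100 * x$p_joint, x$theta_used))
  cat(sprintf("  P(%s | %s) = %.1f%%, P(%s | %s) = %.1f%%\n",
              x$cond_b, x$cond_a, 100 * x$p_b_given_a,
              x$cond_a, x$cond_b, 100 * x$p_a_given_b))
  invisible(x)
}

#' Comorbidity profile of an index condition
#'
#' Collects the conditional prevalences `P(j | index)` over all partner
#' conditions and sums them into the expected number of comorbidities
#' `M_index = sum_j p_ij / p_index`. The variance of `M` is the sum of the
#' per-partner conditional variances (independence approximation), supplied
#' from the bootstrap via `var_conditionals`.
#'
#' @param index Name of the index condition.
#' @param pairs List of [pair_prevalence()] objects, each involving `index`
#'   and exactly one distinct partner condition.
#' @param var_conditionals Optional named vector of bootstrap variances of
#'   the conditionals `p_ij / p_index`, named by partner condition.
#' @return An object of class `comorbidity_profile`.
#' @export
comorbidity_profile <- function(index, pairs, var_conditionals = NULL) {
  if (length(pairs) == 0) stop("no partner pairs supplied for ", index)
  conds <- vapply(pairs, function(p) {
    if (p$cond_a == index) p$cond_b
    else if (p$cond_b == index) p$cond_a
    else stop("pair ", p$cond_a, "-", p$cond_b, " does not involve ", index)
  }, character(1))
  if (anyDuplicated(conds)) {
    stop("duplicate partner condition(s): ",
         paste(unique(conds[duplicated(conds)]), collapse = ", "))
  }
  conditionals <- vapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    if (p$cond_a == index) p$p_b_given_a else p$p_a_given_b
  }, numeric(1))
  names(conditionals) <- conds
  m <- sum(conditionals)
  var_m <- NA_real_
  ci <- c(NA_real_, NA_real_)
  if (!is.null(var_conditionals)) {
    if (!all(conds %in% names(var_conditionals))) {
      stop("var_conditionals missing partners: ",
           paste(setdiff(conds, names(var_conditionals)), collapse = ", "))
    }
    var_m <- sum(var_conditionals[conds])
    ci <- m + c(-1, 1) * Z95 * sqrt(var_m)
  }
  structure(
    list(index_condition = index, conditionals = conditionals,
         m_expected = m, var_m = var_m,
         ci_low = ci[1], ci_high = ci[2]),
    class = "comorbidity_profile"
  )
}

#' @export
print.comorbidity_profile <- function(x, ...) {
  cat(sprintf("<comorbidity_profile> %s: M = %.2f", x$index_condition,
              x$m_expected))
  if (is.finite(x$ci_low)) {
    cat(sprintf(" (95%% CI %.2f-%.2f)", x$ci_low, x$ci_high))
  }
  cat("\n")
  print(round(x$conditionals, 3))
  invisible(x)
}

#' Log-linear regression of comorbidity burden on prevalence
#'
#' Ordinary least squares of `ln(M_i)` on the index condition's prevalence
#' `P_i`, quantifying how the expected comorbidity count falls as the index
#' condition becomes more common. `factor_per_10pct = exp(0.10 * slope)` is
#' the multiplicative change in `M` per 10-percentage-point increase in
#' prevalence; the Pearson correlation is computed between `ln(M_i)` and
#' `P_i`, the scale on which the model is linear.
#'
#' @param profiles List of [comorbidity_profile()] objects (at least 3).
#' @param prevalences Named list or vector of index-condition prevalences
#'   (proportions), covering every profile's index condition.
#' @return List with `slope`, `intercept`, `factor_per_10pct`, `pearson_r`.
#' @export
fit_comorbidity_regression <- function(profiles, prevalences) {
  if (length(profiles) < 3) stop("need at least 3 profiles")
  m <- vapply(profiles, `[[`, numeric(1), "m_expected")
  if (any(m <= 0)) stop("all expected comorbidity counts must be positive")
  idx <- vapply(profiles, `[[`, character(1), "index_condition")
  if (inherits(prevalences[[1]], "prevalence_estimate")) {
    p_all <- vapply(prevalences, `[[`, numeric(1), "prev")
    names(p_all) <- vapply(prevalences, `[[`, character(1), "condition")
  } else {
    p_all <- unlist(prevalences)
  }
  if (!all(idx %in% names(p_all))) {
    stop("prevalence missing for: ",
         paste(setdiff(idx, names(p_all)), collapse = ", "))
  }
  p <- as.numeric(p_all[idx])
  fit <- lm(log(m) ~ p)
  slope <- unname(coef(fit)[2])
  r <- if (var(log(m)) == 0) 0 else cor(log(m), p)
  list(slope = slope, intercept = unname(coef(fit)[1]),
       factor_per_10pct = exp(0.10 * slope), pearson_r = r)
}
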