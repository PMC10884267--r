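test_that("odds ratio from joint prevalence matches direct evaluation", {
  expect_equal(odds_ratio_from_joint(0.1, 0.2, 0.02), 1)
  expect_equal(odds_ratio_from_joint(0.339, 0.102, 0.075),
               (0.075 * (1 - 0.339 - 0.102 + 0.075)) /
                 ((0.339 - 0.075) * (0.102 - 0.075)))
  expect_equal(odds_ratio_from_joint(0.5, 0.5, 0.4), 16)
  expect_error(odds_ratio_from_joint(0.1, 0.2, 0.1), "degenerate joint")
  expect_error(odds_ratio_from_joint(0.1, 0.2, 0), "degenerate joint")
})

test_that("quadratic solution matches the bisection oracle on a grid", {
  p_grid <- seq(0.01, 0.6, length.out = 20)
  thetas <- c(0.1, 0.5, 1, 2, 5, 15, 50)
  for (theta in thetas) {
    for (p_i in p_grid) {
      p_j_vec <- p_grid
      got <- solve_joint_prevalence(p_i, p_j_vec, theta)
      want <- vapply(p_j_vec, function(p_j) bisect_joint(p_i, p_j, theta),
                     numeric(1))
      expect_true(all(abs(got - want) < 1e-10),
                  info = sprintf("theta=%g p_i=%g", theta, p_i))
      # round trip through the forward map
      back <- odds_ratio_from_joint(p_i, p_j_vec, got)
      expect_true(all(abs(back / theta - 1) < 1e-8),
                  info = sprintf("roundtrip theta=%g p_i=%g", theta, p_i))
      # Frechet bounds respected strictly
      expect_true(all(got > pmax(0, p_i + p_j_vec - 1) &
                        got < pmin(p_i, p_j_vec)))
    }
  }
})

test_that("independence, limits and continuity at theta = 1", {
  p_i <- c(0.018, 0.1, 0.35)
  p_j <- c(0.035, 0.4, 0.6)
  expect_equal(solve_joint_prevalence(p_i, p_j, 1), p_i * p_j)
  for (k in seq_along(p_i)) {
    expect_lt(abs(solve_joint_prevalence(p_i[k], p_j[k], 1 + 1e-9) -
                    p_i[k] * p_j[k]), 1e-8)
    expect_lt(abs(solve_joint_prevalence(p_i[k], p_j[k], 1 - 1e-9) -
                    p_i[k] * p_j[k]), 1e-8)
    # strictly increasing in theta, approaching the Frechet bounds
    thetas <- c(1e-6, 1e-3, 0.1, 1, 10, 1e3, 1e6)
    path <- solve_joint_prevalence(p_i[k], p_j[k], thetas)
    expect_true(all(diff(path) > 0))
    expect_equal(path[length(path)], min(p_i[k], p_j[k]), tolerance = 1e-3)
    expect_equal(path[1], max(0, p_i[k] + p_j[k] - 1), tolerance = 1e-3)
  }
  expect_error(solve_joint_prevalence(0.1, 0.2, -1), "positive")
  expect_error(solve_joint_prevalence(0.1, 0.2, 0), "positive")
})

test_that("prevalence estimates derive their SE from the CI width", {
  stroke <- prevalence_estimate("Stroke", 0.026, 0.020, 0.035)
  expect_equal(stroke$se, (0.035 - 0.020) / (2 * qnorm(0.975)),
               tolerance = 1e-9)
  expect_error(prevalence_estimate("X", 0.05, 0.06, 0.07), "ci_low")
  expect_error(prevalence_estimate("X", 1.2), "prev")
})

test_that("pair prevalence combines marginals with the association", {
  copd <- prevalence_estimate("COPD", 0.018, 0.015, 0.022)
  asthma <- prevalence_estimate("Asthma", 0.035, 0.031, 0.040)
  assoc <- pair_association("COPD", "Asthma", "fixed",
                            pooled_log_or = log(14.6), pooled_se = 0)
  pp <- pair_prevalence(copd, asthma, assoc)
  expect_equal(pp$theta_used, 14.6)
  expect_equal(pp$p_joint, bisect_joint(0.018, 0.035, 14.6),
               tolerance = 1e-10)
  expect_equal(pp$p_b_given_a, pp$p_joint / 0.018)
  expect_equal(pp$p_a_given_b, pp$p_joint / 0.035)

  null <- pair_association("COPD", "Asthma", "pooled",
                           pooled_log_or = 0, pooled_se = 0.1)
  expect_equal(pair_prevalence(copd, asthma, null)$p_joint, 0.018 * 0.035)
})

test_that("comorbidity profile sums conditionals into the expected count", {
  idx <- prevalence_estimate("X", 0.05, 0.04, 0.06)
  partners <- list(
    prevalence_estimate("P1", 0.1, 0.08, 0.12),
    prevalence_estimate("P2", 0.2, 0.18, 0.22)
  )
  indep <- lapply(partners, function(p) {
    pair_prevalence(idx, p, pair_association("X", p$condition, "pooled",
                                             pooled_log_or = 0,
                                             pooled_se = 0.1))
  })
  prof <- comorbidity_profile("X", indep)
  expect_equal(prof$m_expected, 0.3, tolerance = 1e-12)
  expect_equal(prof$conditionals, c(P1 = 0.1, P2 = 0.2))

  # three-partner toy set with tabulated thetas: hand-sum from the solver
  thetas <- c(P1 = 3, P2 = 0.5, P3 = 8)
  prevs <- c(P1 = 0.1, P2 = 0.2, P3 = 0.03)
  pairs <- lapply(names(thetas), function(nm) {
    pair_prevalence(idx, prevalence_estimate(nm, prevs[[nm]]),
                    pair_association("X", nm, "fixed",
                                     pooled_log_or = log(thetas[[nm]]),
                                     pooled_se = 0))
  })
  prof2 <- comorbidity_profile("X", pairs)
  hand <- sum(vapply(names(thetas), function(nm) {
    solve_joint_prevalence(0.05, prevs[[nm]], thetas[[nm]]) / 0.05
  }, numeric(1)))
  expect_equal(prof2$m_expected, hand, tolerance = 1e-12)

  expect_error(comorbidity_profile("X", list()), "no partner")
  expect_error(comorbidity_profile("X", c(indep, indep[1])), "duplicate")
  expect_error(comorbidity_profile("Z", indep), "does not involve")
})

test_that("comorbidity regression recovers exact and flat responses", {
  make_prof <- function(nm, m) {
    structure(list(index_condition = nm, conditionals = m, m_expected = m,
                   var_m = NA_real_, ci_low = NA_real_, ci_high = NA_real_),
              class = "comorbidity_profile")
  }
  p <- seq(0.02, 0.35, length.out = 10)
  nms <- paste0("C", seq_along(p))
  exact <- Map(function(nm, pi) make_prof(nm, exp(1 - 3 * pi)), nms, p)
  fit <- fit_comorbidity_regression(exact, setNames(p, nms))
  expect_equal(fit$slope, -3, tolerance = 1e-10)
  expect_equal(fit$factor_per_10pct, exp(-0.3), tolerance = 1e-10)
  expect_equal(fit$pearson_r, -1, tolerance = 1e-10)

  flat <- Map(function(nm, pi) make_prof(nm, 1.4), nms, p)
  fit0 <- fit_comorbidity_regression(flat, setNames(p, nms))
  expect_equal(fit0$slope, 0)
  expect_equal(fit0$factor_per_10pct, 1)
  expect_equal(fit0$pearson_r, 0)

  set.seed(99)
  noisy <- Map(function(nm, pi) make_prof(nm, exp(1 - 3 * pi +
                                                    rnorm(1, 0, 0.05))),
               nms, p)
  fitn <- fit_comorbidity_regression(noisy, setNames(p, nms))
  expect_lt(abs(fitn$slope + 3), 0.5)

  expect_error(fit_comorbidity_regression(exact[1:2], setNames(p, nms)),
               "at least 3")
  bad <- exact
  bad[[1]]$m_expected <- 0
  expect_error(fit_comorbidity_regression(bad, setNames(p, nms)), "positive")
})
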