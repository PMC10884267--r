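test_that("pooling identical effects gives the common value with tau2 = 0", {
  st <- effect_studies(rep(0.7, 5), rep(0.2, 5))
  pooled <- pool_random_effects(st)
  expect_equal(pooled$mode, "pooled")
  expect_equal(pooled$pooled_log_or, 0.7, tolerance = 1e-10)
  expect_equal(pooled$tau2, 0)
  expect_equal(pooled$k_studies, 5L)
})

test_that("equal-SE pooling of two symmetric effects is their midpoint", {
  st <- effect_studies(c(0, log(4)), c(0.3, 0.3))
  pooled <- pool_random_effects(st)
  expect_equal(pooled$pooled_log_or, log(2), tolerance = 1e-10)
})

test_that("pooling agrees with a hand-rolled DerSimonian-Laird oracle", {
  set.seed(101)
  for (i in 1:10) {
    k <- sample(3:12, 1)
    y <- rnorm(k, 0.5, 0.4)
    se <- runif(k, 0.1, 0.5)
    got <- pool_random_effects(effect_studies(y, se))
    want <- dl_pool(y, se)
    expect_equal(got$pooled_log_or, want$b, tolerance = 1e-8)
    expect_equal(got$pooled_se, want$se, tolerance = 1e-8)
    expect_equal(got$tau2, want$tau2, tolerance = 1e-8)
  }
})

test_that("pooling recovers a simulated common effect", {
  set.seed(202)
  k <- 200
  y <- rnorm(k, 0.8, sqrt(0.2^2 + 0.15^2))
  pooled <- pool_random_effects(effect_studies(y, rep(0.15, k)))
  expect_lt(abs(pooled$pooled_log_or - 0.8), 0.05)
})

test_that("pooling input validation", {
  expect_error(pool_random_effects(effect_studies(numeric(0), numeric(0))),
               "no studies")
  expect_error(pool_random_effects(effect_studies(c(0.1, 0.2), c(0.2, 0))),
               "positive")
})

test_that("meta-regression reproduces exact linear data", {
  prev_a <- seq(0.05, 0.5, length.out = 8)
  prev_b <- seq(0.3, 0.05, length.out = 8)
  x <- prev_a * prev_b
  st <- effect_studies(-20 * x + 2, rep(0.2, 8), prev_a, prev_b)
  fit <- fit_meta_regression(st)
  expect_equal(fit$mode, "metareg")
  expect_equal(fit$slope_m, -20, tolerance = 1e-8)
  expect_equal(fit$intercept_c, 2, tolerance = 1e-8)
  expect_equal(fit$tau2, 0, tolerance = 1e-8)
})

test_that("meta-regression coefficient covariance is symmetric PSD", {
  set.seed(303)
  prev_a <- runif(10, 0.05, 0.4)
  prev_b <- runif(10, 0.05, 0.4)
  y <- 1.2 - 8 * prev_a * prev_b + rnorm(10, 0, 0.3)
  fit <- fit_meta_regression(effect_studies(y, runif(10, 0.1, 0.3),
                                            prev_a, prev_b))
  expect_equal(fit$cov_mc, t(fit$cov_mc))
  ev <- eigen(fit$cov_mc, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-12))
})

test_that("rescaling the moderator rescales the slope, not the intercept", {
  set.seed(404)
  prev_a <- runif(12, 0.05, 0.5)
  prev_b <- runif(12, 0.05, 0.5)
  y <- 1.5 - 12 * prev_a * prev_b + rnorm(12, 0, 0.2)
  se <- runif(12, 0.1, 0.3)
  fit1 <- fit_meta_regression(effect_studies(y, se, prev_a, prev_b))
  s <- 0.5
  fit2 <- fit_meta_regression(effect_studies(y, se, s * prev_a, prev_b))
  expect_equal(fit2$slope_m, fit1$slope_m / s, tolerance = 1e-6)
  expect_equal(fit2$intercept_c, fit1$intercept_c, tolerance = 1e-6)
})

test_that("meta-regression coefficient CIs achieve nominal coverage", {
  set.seed(505)
  m_true <- -15
  c_true <- 1.5
  tau <- 0.15
  n_rep <- 200
  cover_m <- cover_c <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    prev_a <- runif(50, 0.05, 0.45)
    prev_b <- runif(50, 0.05, 0.45)
    se <- runif(50, 0.1, 0.3)
    x <- prev_a * prev_b
    y <- c_true + m_true * x + rnorm(50, 0, tau) + rnorm(50, 0, se)
    fit <- fit_meta_regression(effect_studies(y, se, prev_a, prev_b))
    z <- qnorm(0.975)
    se_m <- sqrt(fit$cov_mc["m", "m"])
    se_c <- sqrt(fit$cov_mc["c", "c"])
    cover_m[r] <- abs(fit$slope_m - m_true) <= z * se_m
    cover_c[r] <- abs(fit$intercept_c - c_true) <= z * se_c
  }
  expect_gte(mean(cover_m), 0.90)
  expect_gte(mean(cover_c), 0.90)
})

test_that("meta-regression input validation", {
  st <- effect_studies(c(0.1, 0.2), c(0.2, 0.2), c(0.1, 0.2), c(0.1, 0.2))
  expect_error(fit_meta_regression(st), "pool_random_effects")
  st3 <- effect_studies(c(0.1, 0.2, 0.3), rep(0.2, 3),
                        rep(0.2, 3), rep(0.1, 3))
  expect_error(fit_meta_regression(st3), "degenerate moderator")
})

test_that("synthesis mode follows the three-or-more rule", {
  prev_a <- c(0.1, 0.2, 0.3, 0.4)
  prev_b <- c(0.2, 0.1, 0.3, 0.2)
  st4 <- effect_studies(rnorm(4, 0.5, 0.1), rep(0.2, 4), prev_a, prev_b)
  expect_equal(select_synthesis(st4)$mode, "metareg")
  expect_equal(select_synthesis(st4[1:2, ])$mode, "pooled")
  fx <- select_synthesis(fixed_or = 2.3, fixed_se = 0.2,
                         cond_a = "TB", cond_b = "Depression")
  expect_equal(fx$mode, "fixed")
  expect_equal(fx$pooled_log_or, log(2.3))
  expect_equal(fx$tau2, 0)
  expect_error(select_synthesis(st4[0, ]), "no evidence")
})

test_that("predicted OR follows the fitted surface or the pooled value", {
  flat <- pair_association("A", "B", "metareg", slope_m = 0,
                           intercept_c = log(3), cov_mc = matrix(0, 2, 2),
                           k_studies = 3L)
  expect_equal(predict_or(flat, 0.2, 0.4), 3)
  surf <- pair_association("A", "B", "metareg", slope_m = -10,
                           intercept_c = 1, cov_mc = matrix(0, 2, 2),
                           k_studies = 3L)
  expect_equal(predict_or(surf, 0.1, 0.1), exp(0.9))
  null <- pair_association("A", "B", "pooled", pooled_log_or = 0,
                           pooled_se = 0.1)
  expect_equal(predict_or(null, 0.3, 0.3), 1)
})

test_that("synthesize_pairs groups by unordered pair and merges fixed ORs", {
  st <- rbind(
    effect_studies(c(0.2, 0.3), c(0.2, 0.2), c(0.1, 0.3), c(0.2, 0.1),
                   cond_a = "A", cond_b = "B"),
    effect_studies(0.5, 0.2, 0.25, 0.4, cond_a = "B", cond_b = "A")
  )
  fx <- data.frame(cond_a = c("C", "A"), cond_b = c("D", "B"),
                   or = c(2.3, 99), se_log_or = c(0.2, 0))
  assocs <- synthesize_pairs(st, fx)
  expect_setequal(names(assocs), c("A|B", "C|D"))
  # three rows for A-B (one flipped) -> meta-regression, local evidence wins
  expect_equal(assocs[["A|B"]]$mode, "metareg")
  expect_equal(assocs[["A|B"]]$k_studies, 3L)
  expect_equal(assocs[["C|D"]]$mode, "fixed")
  expect_equal(assocs[["C|D"]]$pooled_log_or, log(2.3))
  tab <- association_table(assocs)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$mode, c("metareg", "fixed"))
})
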