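#' Pairwise association object
#'
#' Container for the synthesised association between two conditions. Three
#' modes exist: `"pooled"` (random-effects pooled log OR), `"metareg"`
#' (meta-regression of the log OR on the product of study prevalences, with
#' slope `m`, intercept `c` and their joint covariance) and `"fixed"` (an
#' externally supplied OR, used when no local evidence exists for a pair).
#'
#' @param cond_a,cond_b Condition names.
#' @param mode One of `"pooled"`, `"metareg"`, `"fixed"`.
#' @param pooled_log_or,pooled_se Pooled log OR and its SE (pooled/fixed).
#' @param slope_m,intercept_c Meta-regression coefficients (metareg).
#' @param cov_mc 2x2 covariance matrix of `(m, c)` (metareg).
#' @param tau2 Between-study variance of the log OR.
#' @param k_studies Number of studies behind the estimate.
#' @return An object of class `pair_association`.
#' @export
pair_association <- function(cond_a, cond_b, mode,
                             pooled_log_or = NA_real_, pooled_se = NA_real_,
                             slope_m = NA_real_, intercept_c = NA_real_,
                             cov_mc = NULL, tau2 = 0, k_studies = 1L) {
  mode <- match.arg(mode, c("pooled", "metareg", "fixed"))
  if (mode %in% c("pooled", "fixed")) {
    stopifnot(is.finite(pooled_log_or), is.finite(pooled_se), pooled_se >= 0)
  } else {
    stopifnot(is.finite(slope_m), is.finite(intercept_c))
    if (is.null(cov_mc)) cov_mc <- matrix(0, 2, 2)
    cov_mc <- as.matrix(cov_mc)
    stopifnot(identical(dim(cov_mc), c(2L, 2L)))
    if (max(abs(cov_mc - t(cov_mc))) > 1e-8) stop("cov_mc must be symmetric")
    cov_mc <- (cov_mc + t(cov_mc)) / 2
    if (min(eigen(cov_mc, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
      stop("cov_mc must be positive semi-definite")
    }
    dimnames(cov_mc) <- list(c("m", "c"), c("m", "c"))
    if (k_studies < 3) stop("meta-regression requires at least 3 studies")
  }
  if (mode == "fixed") tau2 <- 0
  structure(
    list(cond_a = cond_a, cond_b = cond_b, mode = mode,
         pooled_log_or = pooled_log_or, pooled_se = pooled_se,
         slope_m = slope_m, intercept_c = intercept_c, cov_mc = cov_mc,
         tau2 = tau2, k_studies = as.integer(k_studies)),
    class = "pair_association"
  )
}

#' @export
print.pair_association <- function(x, ...) {
  cat(sprintf("<pair_association> %s -- %s [%s, k=%d]\n",
              x$cond_a, x$cond_b, x$mode, x$k_studies))
  if (x$mode == "metareg") {
    cat(sprintf("  log OR = %.4f + %.4f * (Pi*Pj), tau2 = %.4f\n",
                x$intercept_c, x$slope_m, x$tau2))
  } else {
    cat(sprintf("  log OR = %.4f (SE %.4f), tau2 = %.4f\n",
                x$pooled_log_or, x$pooled_se, x$tau2))
  }
  invisible(x)
}

check_effects <- function(studies) {
  if (nrow(studies) == 0) stop("no studies supplied")
  if (any(!is.finite(studies$log_or)) || any(!is.finite(studies$se_log_or))) {
    stop("all studies need finite log_or and se_log_or; ",
         "run prepare_studies() on count data first")
  }
  if (any(studies$se_log_or <= 0)) stop("se_log_or must be positive")
  invisible(studies)
}

#' Random-effects pooling of study log odds ratios
#'
#' DerSimonian-Laird random-effects meta-analysis of the per-study log ORs
#' (inverse-variance weights 1/(se^2 + tau^2), tau^2 floored at zero).
#'
#' @param studies Data frame of study rows for one condition pair with
#'   complete `log_or` and `se_log_or` columns (see [prepare_studies()]).
#' @param knha Apply the Knapp-Hartung small-sample adjustment (default off).
#' @return A `pair_association` with `mode = "pooled"`.
#' @export
pool_random_effects <- function(studies, knha = FALSE) {
  check_effects(studies)
  fit <- metafor::rma(yi = studies$log_or, sei = studies$se_log_or,
                      method = "DL", test = if (knha) "knha" else "z")
  pair_association(
    cond_a = studies$cond_a[1], cond_b = studies$cond_b[1], mode = "pooled",
    pooled_log_or = as.numeric(fit$beta[1]), pooled_se = fit$se[1],
    tau2 = fit$tau2, k_studies = nrow(studies)
  )
}

#' Meta-regression of the log odds ratio on the prevalence product
#'
#' Fits `log_or = c + m * (prev_a * prev_b)` across studies with
#' random-effects weighting (REML estimate of the between-study variance;
#' DerSimonian-Laird method-of-moments fallback if REML does not converge).
#' The moderator is the expected prevalence of the combination if the two
#' conditions occurred independently within each study; a negative slope is
#' the signature of healthy-exclusion sampling heterogeneity (see
#' [apply_healthy_exclusion()]). The coefficient covariance matrix is taken
#' from the weighted-least-squares information matrix at the final tau^2 and
#' is needed to bootstrap `(m, c)` jointly.
#'
#' @inheritParams pool_random_effects
#' @return A `pair_association` with `mode = "metareg"`.
#' @export
fit_meta_regression <- function(studies, knha = FALSE) {
  check_effects(studies)
  if (nrow(studies) < 3) {
    stop("fewer than 3 studies: use pool_random_effects() for this pair")
  }
  if (any(!is.finite(studies$prev_a)) || any(!is.finite(studies$prev_b))) {
    stop("meta-regression needs prev_a and prev_b for every study")
  }
  x <- studies$prev_a * studies$prev_b
  if (var(x) == 0) stop("degenerate moderator: prevalence product is constant")
  test <- if (knha) "knha" else "z"
  fit <- tryCatch(
    metafor::rma(yi = studies$log_or, sei = studies$se_log_or,
                 mods = ~ x, method = "REML", test = test),
    error = function(e)
      metafor::rma(yi = studies$log_or, sei = studies$se_log_or,
                   mods = ~ x, method = "DL", test = test)
  )
  b <- as.numeric(fit$beta)          # (intercept, slope)
  v <- vcov(fit)
  cov_mc <- rbind(c(v[2, 2], v[2, 1]), c(v[1, 2], v[1, 1]))
  pair_association(
    cond_a = studies$cond_a[1], cond_b = studies$cond_b[1], mode = "metareg",
    slope_m = b[2], intercept_c = b[1], cov_mc = cov_mc,
    tau2 = fit$tau2, k_studies = nrow(studies)
  )
}

#' Choose the synthesis mode for one condition pair
#'
#' Meta-regression when three or more study estimates exist, random-effects
#' pooling otherwise, and an externally supplied fixed OR when there is no
#' local evidence at all.
#'
#' @inheritParams pool_random_effects
#' @param fixed_or Optional externally pooled OR (natural scale) used when
#'   `studies` is empty.
#' @param fixed_se SE of the fixed log OR (default 0).
#' @param cond_a,cond_b Condition names, required when only a fixed OR is
#'   given.
#' @return A `pair_association`.
#' @export
select_synthesis <- function(studies = NULL, fixed_or = NULL, fixed_se = 0,
                             cond_a = NULL, cond_b = NULL, knha = FALSE) {
  k <- if (is.null(studies)) 0L else nrow(studies)
  if (k == 0) {
    if (is.null(fixed_or)) stop("no evidence for pair: no studies and no fixed OR")
    if (fixed_or <= 0) stop("fixed OR must be positive")
    return(pair_association(cond_a = cond_a, cond_b = cond_b, mode = "fixed",
                            pooled_log_or = log(fixed_or), pooled_se = fixed_se,
                            tau2 = 0, k_studies = 1L))
  }
  if (k >= 3) fit_meta_regression(studies, knha = knha)
  else pool_random_effects(studies, knha = knha)
}

#' Predicted odds ratio at given marginal prevalences
#'
#' For a meta-regression association the OR is standardised to the supplied
#' prevalences, `theta = exp(m * prev_a * prev_b + c)`; pooled and fixed
#' associations return `exp(pooled_log_or)` regardless of the prevalences.
#'
#' @param assoc A [pair_association()].
#' @param prev_a,prev_b Marginal prevalences in (0, 1).
#' @return The predicted odds ratio (positive scalar).
#' @export
predict_or <- function(assoc, prev_a, prev_b) {
  stopifnot(inherits(assoc, "pair_association"))
  if (assoc$mode == "metareg") {
    exp(assoc$slope_m * prev_a * prev_b + assoc$intercept_c)
  } else {
    exp(assoc$pooled_log_or)
  }
}

#' Synthesise every condition pair in a study table
#'
#' Splits the prepared study table by unordered condition pair and applies
#' [select_synthesis()] to each, merging in any fixed external ORs for pairs
#' with no study rows. Pair orientation follows the first study row seen
#' (or the fixed-OR row).
#'
#' @inheritParams pool_random_effects
#' @param fixed_or Optional data frame with columns `cond_a`, `cond_b`, `or`
#'   and optionally `se_log_or`, supplying external ORs for pairs absent from
#'   `studies`.
#' @return Named list of `pair_association` objects, keyed
#'   `"condA|condB"`.
#' @export
synthesize_pairs <- function(studies = NULL, fixed_or = NULL, knha = FALSE) {
  out <- list()
  if (!is.null(studies) && nrow(studies) > 0) {
    key <- pair_key(studies$cond_a, studies$cond_b)
    for (k in unique(key)) {
      rows <- studies[key == k, , drop = FALSE]
      # orient every row like the first so prev_a/prev_b stay aligned
      flip <- rows$cond_a != rows$cond_a[1]
      if (any(flip)) {
        tmp <- rows$prev_a[flip]
        rows$prev_a[flip] <- rows$prev_b[flip]
        rows$prev_b[flip] <- tmp
        rows$cond_a[flip] <- rows$cond_a[1]
        rows$cond_b[flip] <- rows$cond_b[1]
      }
      out[[k]] <- select_synthesis(rows, knha = knha)
    }
  }
  if (!is.null(fixed_or) && nrow(fixed_or) > 0) {
    for (i in seq_len(nrow(fixed_or))) {
      k <- pair_key(fixed_or$cond_a[i], fixed_or$cond_b[i])
      if (!is.null(out[[k]])) next  # local evidence wins
      se <- if (is.null(fixed_or$se_log_or)) 0 else fixed_or$se_log_or[i]
      if (is.na(se)) se <- 0
      out[[k]] <- select_synthesis(
        fixed_or = fixed_or$or[i], fixed_se = se,
        cond_a = fixed_or$cond_a[i], cond_b = fixed_or$cond_b[i]
      )
    }
  }
  if (length(out) == 0) stop("no evidence: empty study table and no fixed ORs")
  out
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Flatten a list of associations to the pair-level output table
#'
#' @param assocs Named list of [pair_association()] objects.
#' @return Data frame with one row per pair (the pair CSV dialect).
#' @export
association_table <- function(assocs) {
  do.call(rbind, lapply(assocs, function(a) {
    data.frame(
      cond_a = a$cond_a, cond_b = a$cond_b, mode = a$mode,
      k_studies = a$k_studies,
      m = a$slope_m, c = a$intercept_c,
      var_m = if (is.null(a$cov_mc)) NA_real_ else a$cov_mc[1, 1],
      var_c = if (is.null(a$cov_mc)) NA_real_ else a$cov_mc[2, 2],
      cov_mc = if (is.null(a$cov_mc)) NA_real_ else a$cov_mc[1, 2],
      tau2 = a$tau2,
      pooled_log_or = a$pooled_log_or, pooled_se = a$pooled_se,
      row.names = NULL
    )
  }))
}
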