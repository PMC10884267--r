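#' Unadjusted odds ratio from a 2x2 contingency table
#'
#' Computes the log odds ratio and its standard error (Woolf formula) from the
#' four cells of a 2x2 table cross-classifying two conditions. The
#' Haldane-Anscombe continuity correction is applied to *all four* cells, but
#' only when at least one cell is zero; tables with no zero cells are used as
#' given.
#'
#' @param n11 Count with both conditions.
#' @param n10 Count with condition A only.
#' @param n01 Count with condition B only.
#' @param n00 Count with neither condition.
#' @param correction Continuity correction added to every cell when any cell
#'   is zero (default 0.5). Set to 0 to disable; tables that remain degenerate
#'   then raise an error rather than returning an infinite estimate.
#' @return A list with components `log_or`, `se_log_or` and `or`.
#' @examples
#' compute_odds_ratio(20, 80, 10, 90) # OR 2.25
#' @export
compute_odds_ratio <- function(n11, n10, n01, n00, correction = 0.5) {
  cells <- c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop("contingency cells must be finite and nonnegative")
  }
  if (correction < 0) stop("correction must be nonnegative")
  if (sum(cells) == 0) stop("empty table: all four cells are zero")
  if (any(cells == 0)) cells <- cells + correction
  # a zero margin makes the OR unidentifiable even after correction
  if (cells["n11"] + cells["n10"] == 0 || cells["n01"] + cells["n00"] == 0 ||
      cells["n11"] + cells["n01"] == 0 || cells["n10"] + cells["n00"] == 0) {
    stop("degenerate table: a full row or column is zero after correction; ",
         "cells = ", paste(round(cells, 3), collapse = ", "))
  }
  if (any(cells == 0)) {
    stop("zero cell with correction disabled; cells = ",
         paste(cells, collapse = ", "))
  }
  log_or <- log(cells[["n11"]]) + log(cells[["n00"]]) -
    log(cells[["n10"]]) - log(cells[["n01"]])
  se <- sqrt(sum(1 / cells))
  list(log_or = log_or, se_log_or = se, or = exp(log_or))
}

#' Study-level prevalences from table margins
#'
#' The margins of the 2x2 table give the within-study prevalence of each
#' condition; these are the inputs to the meta-regression moderator
#' (the product of the two prevalences, i.e. the expected prevalence of the
#' combination under independence).
#'
#' @inheritParams compute_odds_ratio
#' @return A list with `prev_a` = (n11+n10)/N and `prev_b` = (n11+n01)/N.
#' @export
study_prevalences <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  if (n < 1) stop("table total must be at least 1")
  if (any(c(n11, n10, n01, n00) < 0)) stop("contingency cells must be nonnegative")
  list(prev_a = (n11 + n10) / n, prev_b = (n11 + n01) / n)
}

#' Prepare a study table for evidence synthesis
#'
#' Takes a data frame of study rows (one row per study x condition pair) in
#' the study CSV dialect and fills in `log_or`, `se_log_or`, `prev_a` and
#' `prev_b` from the contingency counts wherever counts are present. Each row
#' must carry exactly one evidence source: either the four counts
#' (`n11`, `n10`, `n01`, `n00`) or a precomputed effect (`log_or`,
#' `se_log_or`). Rows supplying both, or neither, are rejected.
#'
#' @param studies Data frame with columns `study_id`, `cond_a`, `cond_b` and
#'   either count columns or effect columns (missing values allowed where the
#'   other source is used).
#' @param correction Continuity correction passed to [compute_odds_ratio()].
#' @return The same data frame with effect and prevalence columns completed.
#' @export
prepare_studies <- function(studies, correction = 0.5) {
  studies <- as.data.frame(studies)
  required <- c("study_id", "cond_a", "cond_b")
  missing_cols <- setdiff(required, names(studies))
  if (length(missing_cols) > 0) {
    stop("study table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("n11", "n10", "n01", "n00", "log_or", "se_log_or",
                "prev_a", "prev_b")) {
    if (is.null(studies[[col]])) studies[[col]] <- NA_real_
  }
  if (any(studies$cond_a == studies$cond_b)) {
    stop("cond_a and cond_b must differ in every row")
  }
  count_cols <- c("n11", "n10", "n01", "n00")
  has_counts <- stats::complete.cases(studies[count_cols])
  has_effect <- !is.na(studies$log_or) & !is.na(studies$se_log_or)
  bad <- which(has_counts & has_effect)
  if (length(bad) > 0) {
    stop("rows ", paste(bad, collapse = ", "),
         ": both counts and effect columns filled; exactly one source allowed")
  }
  bad <- which(!has_counts & !has_effect)
  if (length(bad) > 0) {
    stop("rows ", paste(bad, collapse = ", "),
         ": neither complete counts nor (log_or, se_log_or) supplied")
  }
  if (any(studies$se_log_or[has_effect] <= 0)) {
    stop("se_log_or must be positive")
  }
  for (i in which(has_counts)) {
    eff <- compute_odds_ratio(studies$n11[i], studies$n10[i],
                              studies$n01[i], studies$n00[i],
                              correction = correction)
    prev <- study_prevalences(studies$n11[i], studies$n10[i],
                              studies$n01[i], studies$n00[i])
    studies$log_or[i] <- eff$log_or
    studies$se_log_or[i] <- eff$se_log_or
    studies$prev_a[i] <- prev$prev_a
    studies$prev_b[i] <- prev$prev_b
  }
  studies
}
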