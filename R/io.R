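#' Read a marginal prevalence table
#'
#' Reads `condition, prev, ci_low, ci_high` (extra columns kept) and converts
#' to proportions. Rows are validated (`ci_low <= prev <= ci_high`, values in
#' range) with row numbers in error messages.
#'
#' @param path CSV path.
#' @param units `"percent"` or `"proportion"` -- the units the file is in.
#' @param as_estimates Return a named list of [prevalence_estimate()] objects
#'   instead of a data frame.
#' @return Data frame in proportions, or a list of `prevalence_estimate`.
#' @export
read_prevalence_csv <- function(path, units = c("percent", "proportion"),
                                as_estimates = FALSE) {
  units <- match.arg(units)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("condition", "prev", "ci_low", "ci_high")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop(path, ": missing columns ", paste(missing_cols, collapse = ", "))
  }
  if (units == "percent") {
    tab[c("prev", "ci_low", "ci_high")] <-
      lapply(tab[c("prev", "ci_low", "ci_high")], function(x) x / 100)
  }
  bad <- which(tab$ci_low > tab$prev | tab$ci_high < tab$prev |
                 tab$prev <= 0 | tab$prev >= 1 | tab$ci_low < 0 |
                 tab$ci_high >= 1)
  if (length(bad) > 0) {
    stop(path, ": invalid prevalence rows (need 0 < ci_low <= prev <= ",
         "ci_high < 1 as proportions): rows ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(tab$condition)) {
    stop(path, ": duplicated condition names")
  }
  if (as_estimates) prevalence_list(tab) else tab
}

#' Build prevalence estimates from a prevalence data frame (proportions)
#' @param tab Data frame with `condition`, `prev`, `ci_low`, `ci_high` as
#'   proportions.
#' @return Named list of [prevalence_estimate()] objects.
#' @export
prevalence_list <- function(tab) {
  out <- lapply(seq_len(nrow(tab)), function(i) {
    prevalence_estimate(tab$condition[i], tab$prev[i],
                        tab$ci_low[i], tab$ci_high[i])
  })
  names(out) <- tab$condition
  out
}

#' Read a study evidence table
#'
#' One row per study x condition pair, with either the four 2x2 counts or a
#' precomputed `(log_or, se_log_or)`; validated and completed by
#' [prepare_studies()].
#'
#' @param path CSV path.
#' @param correction Continuity correction for zero cells.
#' @return Prepared study data frame.
#' @export
read_study_csv <- function(path, correction = 0.5) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  prepare_studies(tab, correction = correction)
}

#' Read externally supplied fixed odds ratios
#'
#' Columns `cond_a, cond_b, or` and either `se_log_or` or a CI pair
#' `ci_low, ci_high` (natural OR scale) from which the log-scale SE is
#' derived as `(log(ci_high) - log(ci_low)) / (2 * 1.959964)`.
#'
#' @param path CSV path.
#' @return Data frame with `cond_a`, `cond_b`, `or`, `se_log_or`.
#' @export
read_fixed_or_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("cond_a", "cond_b", "or")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop(path, ": missing columns ", paste(missing_cols, collapse = ", "))
  }
  if (any(tab$or <= 0)) stop(path, ": fixed ORs must be positive")
  if (is.null(tab$se_log_or)) tab$se_log_or <- NA_real_
  derive <- is.na(tab$se_log_or) &
    !is.null(tab$ci_low) & !is.null(tab$ci_high)
  if (!is.null(tab$ci_low) && any(derive)) {
    tab$se_log_or[derive] <-
      (log(tab$ci_high[derive]) - log(tab$ci_low[derive])) / (2 * Z95)
  }
  tab$se_log_or[is.na(tab$se_log_or)] <- 0
  tab[c("cond_a", "cond_b", "or", "se_log_or")]
}

#' Write a prevalence table
#'
#' Inverse of [read_prevalence_csv()]: writes in the requested units so that
#' a read of the written file reproduces the input.
#'
#' @param tab Data frame in proportions.
#' @param path Output path.
#' @param units Units to write (`"percent"` or `"proportion"`).
#' @export
write_prevalence_csv <- function(tab, path,
                                 units = c("percent", "proportion")) {
  units <- match.arg(units)
  out <- tab
  if (units == "percent") {
    out[c("prev", "ci_low", "ci_high")] <-
      lapply(out[c("prev", "ci_low", "ci_high")], function(x) 100 * x)
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a square condition-by-condition matrix as CSV
#' @param mat Matrix with condition dimnames.
#' @param path Output path.
#' @export
write_matrix_csv <- function(mat, path) {
  df <- data.frame(condition = rownames(mat), as.data.frame(mat),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
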