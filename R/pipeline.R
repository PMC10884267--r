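#' Run the full estimation pipeline
#'
#' End-to-end driver: synthesise the per-pair associations from the study
#' evidence (meta-regression where at least three estimates exist, pooling
#' otherwise, fixed external ORs where supplied), standardise each OR to the
#' national marginal prevalences, invert to joint pairwise prevalences,
#' propagate uncertainty by parametric bootstrap, and summarise conditional
#' comorbidity profiles and expected comorbidity counts.
#'
#' @param prevalences Marginal prevalence input: a data frame in proportions
#'   (see [read_prevalence_csv()]) or a named list of
#'   [prevalence_estimate()] objects.
#' @param studies Prepared study table ([prepare_studies()] /
#'   [read_study_csv()]), or `NULL` when only fixed ORs are used.
#' @param fixed_or Optional data frame of external ORs
#'   (see [read_fixed_or_csv()]).
#' @param bootstrap A [bootstrap_config()]; each pair gets a sub-seed derived
#'   deterministically from its seed, so a run is exactly reproducible from
#'   the single configured seed.
#' @param knha Knapp-Hartung adjustment flag passed to the synthesis step.
#' @param profiles `"auto"` computes comorbidity profiles only for index
#'   conditions whose pairs with every other modelled condition are all
#'   available; `"require"` errors when any is missing; `"skip"` computes
#'   none.
#' @param out_dir Optional directory; when given, writes the OR matrix,
#'   joint-prevalence matrix, conditional matrix, pair-level table,
#'   association table, comorbidity table and a JSON run manifest. On error
#'   any partially written outputs are removed.
#' @return List of class `multimorb_run` with elements `associations`,
#'   `pairs` (data frame), `theta_matrix`, `joint_matrix`,
#'   `conditional_matrix` (rows = index condition), `profiles`,
#'   `comorbidity` (data frame), `regression`, `bootstraps`, `config`.
#' @export
run_pipeline <- function(prevalences, studies = NULL, fixed_or = NULL,
                         bootstrap = bootstrap_config(),
                         knha = FALSE,
                         profiles = c("auto", "require", "skip"),
                         out_dir = NULL) {
  profiles <- match.arg(profiles)
  if (is.data.frame(prevalences)) prevalences <- prevalence_list(prevalences)
  stopifnot(length(prevalences) > 0,
            all(vapply(prevalences, inherits, logical(1),
                       "prevalence_estimate")))

  assocs <- with_stage("synthesis",
                       synthesize_pairs(studies, fixed_or, knha = knha))

  known <- names(prevalences)
  used <- unique(unlist(lapply(assocs, function(a) c(a$cond_a, a$cond_b))))
  unknown <- setdiff(used, known)
  if (length(unknown) > 0) {
    stop("[joint] conditions in evidence but not in the prevalence table: ",
         paste(unknown, collapse = ", "))
  }
  conds <- known[known %in% used]

  boots <- list()
  pair_rows <- list()
  for (i in seq_along(assocs)) {
    a <- assocs[[i]]
    cfg_i <- bootstrap
    cfg_i$seed <- as.integer((bootstrap$seed + 7919 * i) %% .Machine$integer.max)
    bt <- with_stage("bootstrap",
                     bootstrap_pair(prevalences[[a$cond_a]],
                                    prevalences[[a$cond_b]], a, cfg_i))
    boots[[names(assocs)[i]]] <- bt
    est <- bt$estimate
    pair_rows[[i]] <- data.frame(
      cond_a = a$cond_a, cond_b = a$cond_b, mode = a$mode,
      theta = est$theta_used, theta_boot_mean = bt$theta_boot_mean,
      theta_lo = bt$ci_theta[1], theta_hi = bt$ci_theta[2],
      p_joint = est$p_joint, p_lo = est$ci_low, p_hi = est$ci_high,
      p_b_given_a = est$p_b_given_a, p_a_given_b = est$p_a_given_b,
      row.names = NULL
    )
  }
  pairs_tab <- do.call(rbind, pair_rows)

  nc <- length(conds)
  theta_m <- joint_m <- cond_m <-
    matrix(NA_real_, nc, nc, dimnames = list(conds, conds))
  for (row in pair_rows) {
    a <- row$cond_a; b <- row$cond_b
    theta_m[a, b] <- theta_m[b, a] <- row$theta
    joint_m[a, b] <- joint_m[b, a] <- row$p_joint
    cond_m[a, b] <- row$p_b_given_a  # row = index condition
    cond_m[b, a] <- row$p_a_given_b
  }

  prof_list <- list()
  comorb_rows <- list()
  if (profiles != "skip" && nc >= 2) {
    for (idx in conds) {
      partners <- setdiff(conds, idx)
      have <- !is.na(cond_m[idx, partners])
      if (!all(have)) {
        if (profiles == "require") {
          stop("[comorbidity] index ", idx, " missing pairs with: ",
               paste(partners[!have], collapse = ", "))
        }
        next
      }
      reps <- vapply(partners, function(p) {
        bt <- boots[[pair_key(idx, p)]]
        r <- bt$replicates
        if (bt$estimate$cond_a == idx) r$p_ij / r$p_i else r$p_ij / r$p_j
      }, numeric(bootstrap$n_iter))
      var_cond <- apply(reps, 2, var)
      prof <- with_stage("comorbidity", comorbidity_profile(
        idx,
        pairs = lapply(boots[pair_key(idx, partners)], `[[`, "estimate"),
        var_conditionals = var_cond
      ))
      bc <- bootstrap_comorbidity(idx, reps, m_point = prof$m_expected,
                                  ci_level = bootstrap$ci_level)
      prof_list[[idx]] <- prof
      comorb_rows[[idx]] <- data.frame(
        condition = idx, prev = prevalences[[idx]]$prev,
        m_expected = prof$m_expected, var_m = prof$var_m,
        ci_low = prof$ci_low, ci_high = prof$ci_high,
        ci_pct_low = bc$ci_percentile[1], ci_pct_high = bc$ci_percentile[2],
        row.names = NULL
      )
    }
  }
  comorb_tab <- if (length(comorb_rows) > 0) do.call(rbind, comorb_rows) else NULL

  regression <- NULL
  if (length(prof_list) >= 3) {
    regression <- with_stage(
      "regression",
      fit_comorbidity_regression(prof_list, prevalences[names(prof_list)])
    )
  }

  result <- structure(
    list(associations = assocs, pairs = pairs_tab,
         theta_matrix = theta_m, joint_matrix = joint_m,
         conditional_matrix = cond_m, profiles = prof_list,
         comorbidity = comorb_tab, regression = regression,
         bootstraps = boots, config = bootstrap),
    class = "multimorb_run"
  )
  if (!is.null(out_dir)) write_reports(result, out_dir)
  result
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Write the report bundle of a pipeline run
#'
#' Writes the OR, joint-prevalence and conditional matrices, the pair-level
#' and association tables, the comorbidity table (when computed) and a JSON
#' manifest with the seed and configuration needed to reproduce the run.
#' Any partial output is removed if a write fails.
#'
#' @param result A `multimorb_run` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_reports <- function(result, out_dir) {
  stopifnot(inherits(result, "multimorb_run"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop("[report] ", conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    f <- file.path(out_dir, "or_matrix.csv")
    write_matrix_csv(result$theta_matrix, f); written <- c(written, f)
    f <- file.path(out_dir, "joint_prevalence_matrix.csv")
    write_matrix_csv(result$joint_matrix, f); written <- c(written, f)
    f <- file.path(out_dir, "conditional_matrix.csv")
    write_matrix_csv(result$conditional_matrix, f); written <- c(written, f)
    f <- file.path(out_dir, "pairs.csv")
    write.csv(result$pairs, f, row.names = FALSE); written <- c(written, f)
    f <- file.path(out_dir, "associations.csv")
    write.csv(association_table(result$associations), f, row.names = FALSE)
    written <- c(written, f)
    if (!is.null(result$comorbidity)) {
      f <- file.path(out_dir, "comorbidity.csv")
      write.csv(result$comorbidity, f, row.names = FALSE)
      written <- c(written, f)
    }
    f <- file.path(out_dir, "manifest.json")
    manifest <- list(
      package = "multimorb",
      version = as.character(utils::packageVersion("multimorb")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = result$config$seed,
      n_iter = result$config$n_iter,
      ci_level = result$config$ci_level,
      prevalence_floor = result$config$prevalence_floor,
      n_pairs = nrow(result$pairs),
      conditions = rownames(result$theta_matrix)
    )
    jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, f)
  }, error = on_fail)
  invisible(written)
}

#' @export
print.multimorb_run <- function(x, ...) {
  cat(sprintf("<multimorb_run> %d conditions, %d pairs, %d bootstrap iter\n",
              nrow(x$theta_matrix), nrow(x$pairs), x$config$n_iter))
  if (!is.null(x$comorbidity)) {
    cat("Expected comorbidities by index condition:\n")
    print(x$comorbidity[order(-x$comorbidity$m_expected),
                        c("condition", "m_expected", "ci_low", "ci_high")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}
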