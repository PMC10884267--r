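# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Bisection on the monotone map p_ij -> theta over the open Frechet interval.
bisect_joint <- function(p_i, p_j, theta, iters = 120) {
  lo <- max(0, p_i + p_j - 1)
  hi <- min(p_i, p_j)
  # g(p) < 0 below the root, > 0 above it; g is increasing in p
  g <- function(p) p * (1 - p_i - p_j + p) - theta * (p_i - p) * (p_j - p)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Hand-rolled DerSimonian-Laird pooling (method-of-moments tau^2, floored).
dl_pool <- function(y, se) {
  w <- 1 / se^2
  yw <- sum(w * y) / sum(w)
  q <- sum(w * (y - yw)^2)
  cc <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - (length(y) - 1)) / cc)
  wstar <- 1 / (se^2 + tau2)
  list(b = sum(wstar * y) / sum(wstar), se = sqrt(1 / sum(wstar)),
       tau2 = tau2)
}

# Study table built directly from effect rows (no contingency counts).
effect_studies <- function(log_or, se, prev_a = NULL, prev_b = NULL,
                           cond_a = "A", cond_b = "B") {
  k <- length(log_or)
  data.frame(
    study_id = sprintf("s%02d", seq_len(k)),
    cond_a = rep_len(cond_a, k), cond_b = rep_len(cond_b, k),
    n11 = rep(NA_real_, k), n10 = rep(NA_real_, k),
    n01 = rep(NA_real_, k), n00 = rep(NA_real_, k),
    log_or = log_or, se_log_or = se,
    prev_a = if (is.null(prev_a)) rep(NA_real_, k) else prev_a,
    prev_b = if (is.null(prev_b)) rep(NA_real_, k) else prev_b
  )
}
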