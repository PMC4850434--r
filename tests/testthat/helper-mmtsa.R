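# Shared helpers: small effect sets built in code, plus independent
# brute-force oracles kept deliberately separate from the implementation.

# an effects tibble from raw vectors (no 2x2 cells, so IV pooling applies)
make_effects <- function(log_or, se, ids = NULL) {
  tibble::tibble(
    study_id = ids %||% sprintf("s%02d", seq_along(log_or)),
    log_or = log_or, se = se, weight_fixed = 1 / se^2
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force Kendall tau over all pairs (ties count for neither side)
oracle_kendall <- function(u, v) {
  k <- length(u)
  con <- 0L; dis <- 0L
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      s <- sign(u[j] - u[i]) * sign(v[j] - v[i])
      if (s > 0) con <- con + 1L else if (s < 0) dis <- dis + 1L
    }
  }
  list(tau = (con - dis) / choose(k, 2), con = con, dis = dis)
}

# closed-form simple OLS of y on x, coded independently of lm()
oracle_ols <- function(x, y) {
  n <- length(x)
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  resid <- y - b0 - b1 * x
  s2 <- sum(resid^2) / (n - 2)
  se_b0 <- sqrt(s2 * (1 / n + mean(x)^2 / sum((x - mean(x))^2)))
  list(intercept = b0, slope = b1, se_intercept = se_b0, t = b0 / se_b0)
}

# case/control arm sizes of the packaged nine studies
fixture_sizes <- function() {
  s <- mthfr_mm_studies()
  list(cases = s$case_cc + s$case_ct + s$case_tt,
       controls = s$ctrl_cc + s$ctrl_ct + s$ctrl_tt)
}
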