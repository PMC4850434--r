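#' Wald-ratio Mendelian randomization estimate
#'
#' Scales the gene-outcome association (the pooled per-T-allele log odds
#' ratio for disease) by the gene-exposure association (the per-T-allele
#' effect on the exposure, in SD of natural-log plasma homocysteine) to
#' obtain the causal odds ratio per 1 SD increase in ln-homocysteine:
#'
#' `log_or = log_or_outcome / beta` and, by the first-order delta method,
#' `se = se_outcome / |beta|`. When the instrument's own standard error is
#' supplied, the second-order delta term
#' `log_or_outcome^2 * beta_se^2 / beta^4` is added to the variance.
#'
#' The default `beta_per_allele = 0.158` is the per-T-allele difference in
#' SD units of ln-homocysteine reported by the large GWAS meta-analysis
#' (44,147 individuals) that the gene-exposure side of this design rests
#' on.
#'
#' @param gene_outcome A `meta_pool` object (normally the allele-model
#'   pooled result), or any list with elements `log_or` and `se`.
#' @param beta_per_allele Gene-exposure effect, SD ln-Hcy per T allele
#'   (nonzero; default 0.158).
#' @param beta_se Optional standard error of `beta_per_allele`; when given,
#'   the second-order delta variance is used.
#' @param conf_level Confidence level (default 0.95).
#' @return An `mr_result` object; see [tidy.mr_result()].
#' @examples
#' mthfr_mm_studies() |> study_effects("allele") |> meta_pool() |> wald_ratio()
#' @export
wald_ratio <- function(gene_outcome, beta_per_allele = 0.158, beta_se = NULL,
                       conf_level = 0.95) {
  if (!is.list(gene_outcome) ||
      !all(c("log_or", "se") %in% names(gene_outcome))) {
    abort("gene_outcome must carry log_or and se (e.g. a meta_pool object)",
          class = "mmtsa_validation_error")
  }
  if (beta_per_allele == 0) {
    abort("beta_per_allele must be nonzero", class = "mmtsa_validation_error")
  }
  log_or <- gene_outcome$log_or / beta_per_allele
  v <- (gene_outcome$se / beta_per_allele)^2
  if (!is.null(beta_se)) {
    v <- v + gene_outcome$log_or^2 * beta_se^2 / beta_per_allele^4
  }
  se <- sqrt(v)
  zcrit <- qnorm(1 - (1 - conf_level) / 2)
  z <- log_or / se
  structure(
    list(
      or_per_sd = exp(log_or), log_or = log_or, se = se,
      ci95 = exp(log_or + c(-1, 1) * zcrit * se),
      z = z, p = 2 * pnorm(-abs(z)),
      beta_per_allele = beta_per_allele, beta_se = beta_se,
      conf_level = conf_level,
      gene_outcome = list(log_or = gene_outcome$log_or, se = gene_outcome$se)
    ),
    class = "mr_result"
  )
}

#' @describeIn wald_ratio One-row tidy summary.
#' @param x An `mr_result` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mr_result <- function(x, ...) {
  tibble::tibble(
    or_per_sd = x$or_per_sd, log_or = x$log_or, se = x$se,
    ci_low = x$ci95[1], ci_high = x$ci95[2], z = x$z, p = x$p,
    beta_per_allele = x$beta_per_allele
  )
}

#' @describeIn wald_ratio Same as `tidy()` (a Wald ratio has a single row).
#' @exportS3Method generics::glance
glance.mr_result <- function(x, ...) tidy(x)

#' @export
print.mr_result <- function(x, ...) {
  cat("Wald-ratio Mendelian randomization estimate\n")
  cat(sprintf("  OR per 1 SD ln-Hcy: %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
              x$or_per_sd, x$ci95[1], x$ci95[2], x$p))
  cat(sprintf("  instrument effect: %.3f SD ln-Hcy per T allele%s\n",
              x$beta_per_allele,
              if (is.null(x$beta_se)) "" else
                sprintf(" (se %.3f, second-order delta)", x$beta_se)))
  invisible(x)
}

#' Analytic power of single-instrument MR with a binary outcome
#'
#' Approximation used by the standard online MR power calculator for binary
#' outcomes:
#' `power = pnorm(sqrt(n_total * r2 * p * (1 - p)) * |log(causal_or)| -
#' z_{1-alpha/2})` with `p` the case fraction and `r2` the proportion of
#' exposure variance explained by the instrument.
#'
#' @param n_total Total number of subjects.
#' @param case_fraction Fraction of subjects who are cases, in (0, 1).
#' @param causal_or Causal odds ratio per SD of exposure to be detected.
#' @param r2 Variance in the exposure explained by the instrument (default
#'   0.01).
#' @param alpha Two-sided type-I error (default 0.05).
#' @return Power as a fraction in (0, 1); vectorised over its arguments.
#' @examples
#' mr_power(7046, 2092 / 7046, causal_or = 2.67)
#' @export
mr_power <- function(n_total, case_fraction, causal_or, r2 = 0.01,
                     alpha = 0.05) {
  stopifnot(all(case_fraction > 0 & case_fraction < 1),
            all(r2 > 0 & r2 < 1), all(n_total > 0), all(causal_or > 0))
  ncp <- sqrt(n_total * r2 * case_fraction * (1 - case_fraction)) *
    abs(log(causal_or))
  pnorm(ncp - qnorm(1 - alpha / 2))
}

#' Back-derive the instrument effect from two odds ratios
#'
#' Inverts the Wald ratio: given a gene-outcome pooled OR and the causal OR
#' per SD of exposure, returns the implied gene-exposure effect
#' `beta = log(pooled_or) / log(mr_or)`. A utility for reconstructing an
#' unreported instrument effect from published headline numbers.
#'
#' @param pooled_or Gene-outcome pooled odds ratio (> 0).
#' @param mr_or Causal odds ratio per SD of exposure (> 0, not 1).
#' @return The implied beta, SD of exposure per allele.
#' @examples
#' infer_beta(1.17, 2.67)  # about 0.16
#' @export
infer_beta <- function(pooled_or, mr_or) {
  stopifnot(pooled_or > 0, mr_or > 0)
  if (any(mr_or == 1)) {
    abort("mr_or = 1 leaves beta undefined", class = "mmtsa_validation_error")
  }
  log(pooled_or) / log(mr_or)
}
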