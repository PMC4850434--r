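#' The five genetic contrasts
#'
#' Labels of the genetic models under which genotype counts are collapsed to
#' 2x2 tables: `allele` (T vs C, allele counts), `homozygous` (TT vs CC),
#' `heterozygous` (CT vs CC), `dominant` (TT+CT vs CC) and `recessive`
#' (TT vs CT+CC).
#'
#' @return Character vector of the five model labels.
#' @export
genetic_models <- function() {
  c("allele", "homozygous", "heterozygous", "dominant", "recessive")
}

#' Human-readable contrast label for a genetic model
#' @param model One of [genetic_models()].
#' @return A label such as `"T vs C"`.
#' @export
model_contrast <- function(model) {
  model <- match.arg(model, genetic_models(), several.ok = TRUE)
  unname(c(allele = "T vs C", homozygous = "TT vs CC",
           heterozygous = "CT vs CC", dominant = "TT+CT vs CC",
           recessive = "TT vs CT+CC")[model])
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson one-degree-of-freedom chi-square test (no continuity correction)
#' of observed genotype counts against the Hardy-Weinberg expectation
#' computed from the sample allele frequency. A monomorphic sample carries
#' no information about HWE and returns `chi2 = 0`, `p = 1`.
#'
#' The continuity-uncorrected form is deliberate: it is what reproduces the
#' published per-study control HWE p-values; Yates' correction does not.
#'
#' @param cc,ct,tt Genotype counts (vectorised; recycled to a common
#'   length). `cc` counts major-allele homozygotes, `tt` minor-allele
#'   homozygotes.
#' @return Tibble with columns `chi2`, `df`, `p` and the expected counts
#'   `exp_cc`, `exp_ct`, `exp_tt` (which sum to the observed total).
#' @examples
#' hwe_test(144, 196, 94)  # p = 0.08 to 2 dp
#' @export
hwe_test <- function(cc, ct, tt) {
  n <- cc + ct + tt
  if (any(n <= 0)) {
    abort("hwe_test needs a positive genotype total", class = "mmtsa_validation_error")
  }
  q <- (ct + 2 * tt) / (2 * n)  # minor (T) allele frequency
  exp_cc <- (1 - q)^2 * n
  exp_ct <- 2 * q * (1 - q) * n
  exp_tt <- q^2 * n
  mono <- q == 0 | q == 1
  chi2 <- ifelse(
    mono, 0,
    (cc - exp_cc)^2 / exp_cc + (ct - exp_ct)^2 / exp_ct + (tt - exp_tt)^2 / exp_tt
  )
  p <- ifelse(mono, 1, pchisq(chi2, df = 1, lower.tail = FALSE))
  tibble::tibble(chi2 = chi2, df = 1L, p = p,
                 exp_cc = exp_cc, exp_ct = exp_ct, exp_tt = exp_tt)
}

#' HWE test of every study's control arm
#'
#' @param studies A study table.
#' @return Tibble with `study_id` and the columns of [hwe_test()].
#' @export
hwe_controls <- function(studies) {
  studies <- validate_studies(studies)
  dplyr::bind_cols(
    tibble::tibble(study_id = studies$study_id),
    hwe_test(studies$ctrl_cc, studies$ctrl_ct, studies$ctrl_tt)
  )
}

#' Collapse genotype counts to per-study 2x2 contrast tables
#'
#' Under the allele model the units are alleles (exposed = T allele count =
#' CT + 2 TT per arm; margins are twice the subject totals); under the
#' subject models the units are subjects, with the homozygous and
#' heterozygous contrasts dropping the excluded genotype from both arms.
#'
#' @param studies A study table.
#' @param model One of [genetic_models()].
#' @return Tibble with columns `study_id`, `model`, `exposed_cases`,
#'   `unexposed_cases`, `exposed_controls`, `unexposed_controls`.
#' @export
build_contrast <- function(studies, model = genetic_models()) {
  studies <- validate_studies(studies)
  model <- match.arg(model)
  f <- switch(model,
    allele = function(cc, ct, tt) {
      t_alleles <- ct + 2L * tt
      list(exp = t_alleles, unexp = 2L * (cc + ct + tt) - t_alleles)
    },
    homozygous   = function(cc, ct, tt) list(exp = tt, unexp = cc),
    heterozygous = function(cc, ct, tt) list(exp = ct, unexp = cc),
    dominant     = function(cc, ct, tt) list(exp = tt + ct, unexp = cc),
    recessive    = function(cc, ct, tt) list(exp = tt, unexp = ct + cc)
  )
  ca <- f(studies$case_cc, studies$case_ct, studies$case_tt)
  co <- f(studies$ctrl_cc, studies$ctrl_ct, studies$ctrl_tt)
  tibble::tibble(
    study_id = studies$study_id,
    model = model,
    exposed_cases = ca$exp, unexposed_cases = ca$unexp,
    exposed_controls = co$exp, unexposed_controls = co$unexp
  )
}

#' Log odds ratio and Woolf standard error from 2x2 counts
#'
#' `log_or = ln(ad/bc)` with `se = sqrt(1/a + 1/b + 1/c + 1/d)` where
#' `a` = exposed cases, `b` = unexposed cases, `c` = exposed controls,
#' `d` = unexposed controls. If any cell of a table is zero, the continuity
#' correction is added to all four cells of that table first.
#'
#' @param exposed_cases,unexposed_cases,exposed_controls,unexposed_controls
#'   Non-negative counts, vectorised.
#' @param correction Continuity correction added to every cell of a table
#'   containing a zero (default 0.5).
#' @return Tibble with the (possibly corrected) cells `a`, `b`, `c`, `d`, a
#'   `corrected` flag, `log_or`, `se` and `weight_fixed = 1/se^2`.
#' @export
effect_from_counts <- function(exposed_cases, unexposed_cases,
                               exposed_controls, unexposed_controls,
                               correction = 0.5) {
  a <- as.numeric(exposed_cases);    b <- as.numeric(unexposed_cases)
  c <- as.numeric(exposed_controls); d <- as.numeric(unexposed_controls)
  needs <- a == 0 | b == 0 | c == 0 | d == 0
  a[needs] <- a[needs] + correction; b[needs] <- b[needs] + correction
  c[needs] <- c[needs] + correction; d[needs] <- d[needs] + correction
  if (any(a == 0 | b == 0 | c == 0 | d == 0)) {
    abort("undefined effect: a margin is zero even after continuity correction",
          class = "mmtsa_validation_error")
  }
  log_or <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  tibble::tibble(a = a, b = b, c = c, d = d, corrected = needs,
                 log_or = log_or, se = se, weight_fixed = 1 / se^2)
}

#' Per-study effect estimates under a genetic model
#'
#' Builds the 2x2 contrast for each study and computes its log odds ratio
#' with the Woolf standard error. This is the study-level input to all
#' pooling, bias and sequential analyses.
#'
#' @inheritParams build_contrast
#' @inheritParams effect_from_counts
#' @return Tibble with one row per study: `study_id`, `model`, the 2x2
#'   cells `a` (exposed cases), `b` (unexposed cases), `c` (exposed
#'   controls), `d` (unexposed controls), `corrected`, `log_or`, `se`,
#'   `weight_fixed`.
#' @examples
#' mthfr_mm_studies() |> study_effects("allele")
#' @export
study_effects <- function(studies, model = genetic_models(), correction = 0.5) {
  model <- match.arg(model)
  contrast <- build_contrast(studies, model)
  eff <- effect_from_counts(contrast$exposed_cases, contrast$unexposed_cases,
                            contrast$exposed_controls, contrast$unexposed_controls,
                            correction = correction)
  dplyr::bind_cols(contrast[, c("study_id", "model")], eff)
}

# minimal structural check for an effects tibble
check_effects <- function(effects, k_min = 1, caller = "this function") {
  if (!is.data.frame(effects) || !all(c("log_or", "se") %in% names(effects))) {
    abort("expected a data frame with columns log_or and se",
          class = "mmtsa_validation_error")
  }
  if (nrow(effects) < k_min) {
    abort(sprintf("%s needs at least %d effect estimate(s), got %d",
                  caller, k_min, nrow(effects)),
          class = "mmtsa_validation_error")
  }
  if (any(effects$se <= 0)) {
    abort("standard errors must be positive", class = "mmtsa_validation_error")
  }
  invisible(effects)
}
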