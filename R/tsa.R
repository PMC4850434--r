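#' Diversity (D-squared) of a meta-analysis
#'
#' Diversity is the relative increase in the variance of the pooled estimate
#' when moving from fixed- to random-effects weighting:
#' `d2 = (v_random - v_fixed) / v_random`, with
#' `v_fixed = 1/sum(1/se^2)` and `v_random = 1/sum(1/(se^2 + tau2))`.
#' It is the heterogeneity adjustment used when sizing a sequential
#' meta-analysis, and is always at least as large as I-squared on the same
#' data (I-squared alone under-sizes the required information).
#'
#' @inheritParams heterogeneity
#' @param tau2 Optional between-study variance override (default: the
#'   DerSimonian-Laird estimate).
#' @return One-row tibble: `d2` (fraction), `tau2`, `v_fixed`, `v_random`.
#' @export
diversity <- function(effects, tau2 = NULL) {
  check_effects(effects, k_min = 2, caller = "diversity")
  if (is.null(tau2)) tau2 <- heterogeneity(effects)$tau2
  v_fixed <- 1 / sum(1 / effects$se^2)
  v_random <- 1 / sum(1 / (effects$se^2 + tau2))
  tibble::tibble(d2 = (v_random - v_fixed) / v_random, tau2 = tau2,
                 v_fixed = v_fixed, v_random = v_random)
}

#' Diversity-adjusted required information size
#'
#' Number of subjects a meta-analysis needs in order to detect a relative
#' risk increase `rri` over a control event proportion `p_c` with two-sided
#' type-I error `alpha` and power `power`, inflated by the adjustment factor
#' `1/(1 - d2)`:
#'
#' `IS = ceil( (z_{1-alpha/2} + z_{power})^2 * 2 * pbar * (1 - pbar) / delta^2
#'  * 1/(1 - d2) )`
#'
#' with `p_e = p_c * (1 + rri)`, `pbar = (p_c + p_e)/2` and
#' `delta = p_e - p_c`. The default `variant = "per_group"` uses the
#' constant above, which is the convention the published analysis follows;
#' `variant = "total"` doubles it (the classical two-arm total sample-size
#' constant `4 * pbar * (1 - pbar)`).
#'
#' @param control_event_proportion Event proportion in the control arm, in
#'   (0, 1).
#' @param rri Relative risk increase anticipated for the exposed arm, as a
#'   fraction (> -1, nonzero).
#' @param alpha Two-sided type-I error (default 0.05).
#' @param power Desired power (default 0.80).
#' @param d2 Diversity fraction in [0, 1) (default 0: no adjustment).
#' @param variant `"per_group"` (default) or `"total"`; see above.
#' @return One-row tibble: `required_is` (subjects, rounded up),
#'   `required_is_raw`, `unadjusted` (before the diversity inflation),
#'   `adjustment_factor`, `p_control`, `p_experimental`.
#' @export
required_information_size <- function(control_event_proportion, rri,
                                      alpha = 0.05, power = 0.80, d2 = 0,
                                      variant = c("per_group", "total")) {
  variant <- match.arg(variant)
  p_c <- control_event_proportion
  stopifnot(p_c > 0, p_c < 1, alpha > 0, alpha < 1, power > 0, power < 1)
  if (rri == 0) {
    abort("rri = 0 implies an infinite information size",
          class = "mmtsa_validation_error")
  }
  if (d2 < 0 || d2 >= 1) {
    abort("d2 must lie in [0, 1)", class = "mmtsa_validation_error")
  }
  p_e <- p_c * (1 + rri)
  if (p_e <= 0 || p_e >= 1) {
    abort("experimental event proportion outside (0, 1); check rri",
          class = "mmtsa_validation_error")
  }
  pbar <- (p_c + p_e) / 2
  delta <- p_e - p_c
  base <- (qnorm(1 - alpha / 2) + qnorm(power))^2 * 2 * pbar * (1 - pbar) / delta^2
  if (variant == "total") base <- 2 * base
  af <- 1 / (1 - d2)
  tibble::tibble(
    required_is = ceiling(base * af), required_is_raw = base * af,
    unadjusted = base, adjustment_factor = af,
    p_control = p_c, p_experimental = p_e
  )
}

#' O'Brien-Fleming-type alpha-spending function
#'
#' Cumulative two-sided alpha spent by information fraction `t`:
#' `min(alpha, 4 * (1 - pnorm(qnorm(1 - alpha/4) / sqrt(t))))`. Spends
#' almost nothing early and reaches exactly `alpha` at `t = 1`.
#'
#' @param t Information fraction(s) in (0, 1]; vectorised.
#' @param alpha Total two-sided type-I error (default 0.05).
#' @return Cumulative spent alpha, same length as `t`.
#' @export
obf_spending <- function(t, alpha = 0.05) {
  out <- 4 * (1 - pnorm(qnorm(1 - alpha / 4) / sqrt(pmax(t, 0)))) # 0 at t = 0
  pmin(alpha, out)
}

#' Lan-DeMets monitoring boundary for given looks
#'
#' Solves the two-sided group-sequential boundary for looks at the given
#' information fractions under the O'Brien-Fleming-type spending function:
#' at each look the boundary z is chosen so that the cumulative probability,
#' under the null, of having crossed at any look so far equals the spent
#' alpha. Crossing probabilities are computed by the standard recursive
#' numerical integration of the non-crossing sub-density of the Brownian
#' motion on a trapezoidal grid.
#'
#' @param information_fractions Strictly increasing fractions in (0, 1].
#' @param alpha Total two-sided type-I error (default 0.05).
#' @param grid_points Integration grid size (default 512; accuracy is well
#'   below 1e-3 on the z scale at this setting).
#' @return Tibble: `information_fraction`, `z_boundary`, `alpha_spent`
#'   (cumulative), `alpha_increment`. A look whose alpha increment is
#'   essentially zero gets the cap `z_boundary = 8.5`.
#' @examples
#' obf_boundary(c(0.5, 1))  # approx (2.96, 1.97)
#' @export
obf_boundary <- function(information_fractions, alpha = 0.05,
                         grid_points = 512) {
  t <- information_fractions
  if (length(t) < 1 || any(t <= 0) || any(t > 1)) {
    abort("information fractions must lie in (0, 1]",
          class = "mmtsa_validation_error")
  }
  if (length(t) > 1 && any(diff(t) <= 0)) {
    abort("information fractions must be strictly increasing",
          class = "mmtsa_validation_error")
  }
  z_cap <- 8.5
  eps <- 1e-12
  K <- length(t)
  spent <- obf_spending(t, alpha)
  inc <- diff(c(0, spent))
  bounds <- numeric(K)

  trap_w <- function(grid) {
    h <- diff(grid[1:2])
    w <- rep(h, length(grid)); w[c(1, length(grid))] <- h / 2
    w
  }

  bounds[1] <- if (inc[1] < eps) z_cap else qnorm(1 - inc[1] / 2)
  half <- min(bounds[1], z_cap) * sqrt(t[1])
  grid <- seq(-half, half, length.out = grid_points)
  dens <- dnorm(grid, sd = sqrt(t[1]))   # sub-density of the score at look 1

  if (K > 1) {
    for (k in 2:K) {
      sigma <- sqrt(t[k] - t[k - 1])
      w <- trap_w(grid)
      mass_prev <- sum(dens * w)          # P(no crossing through look k-1)
      surv <- function(cz) {              # P(no crossing through look k)
        up <- cz * sqrt(t[k])
        sum(dens * w * (pnorm((up - grid) / sigma) - pnorm((-up - grid) / sigma)))
      }
      if (inc[k] < eps) {
        bounds[k] <- z_cap
      } else {
        f <- function(cz) (mass_prev - surv(cz)) - inc[k]
        bounds[k] <- uniroot(f, c(1e-6, z_cap), tol = 1e-9)$root
      }
      up <- min(bounds[k], z_cap) * sqrt(t[k])
      newgrid <- seq(-up, up, length.out = grid_points)
      kernel <- outer(newgrid, grid, function(s, u) dnorm(s - u, sd = sigma))
      dens <- as.vector(kernel %*% (dens * w))
      grid <- newgrid
    }
  }
  tibble::tibble(information_fraction = t, z_boundary = bounds,
                 alpha_spent = spent, alpha_increment = inc)
}

#' Cumulative random-effects Z-curve
#'
#' Adds the studies in chronological order (ascending year, ties broken by
#' `study_id`) and records, after each addition, the DerSimonian-Laird
#' random-effects pooled z statistic and the cumulative number of subjects.
#' The final point equals the full random-effects meta-analysis.
#'
#' @param studies A study table.
#' @param model Genetic model for the contrast (default `"allele"`).
#' @return Tibble, one row per look: `look`, `study_id`, `year`, `n`,
#'   `cumulative_n`, `log_or`, `se`, `z`.
#' @export
cumulative_z <- function(studies, model = "allele") {
  studies <- sort_chronological(studies)
  model <- match.arg(model, genetic_models())
  effects <- study_effects(studies, model)
  n <- studies$case_cc + studies$case_ct + studies$case_tt +
    studies$ctrl_cc + studies$ctrl_ct + studies$ctrl_tt
  purrr::map_dfr(seq_len(nrow(studies)), function(j) {
    sub <- effects[seq_len(j), , drop = FALSE]
    if (j == 1) {
      est <- sub$log_or[1]; se <- sub$se[1]
    } else {
      pooled <- pool_random(sub)
      est <- pooled$log_or; se <- pooled$se
    }
    cum_n <- sum(n[seq_len(j)])
    tibble::tibble(look = j, study_id = studies$study_id[j],
                   year = studies$year[j], n = n[j],
                   cumulative_n = cum_n,
                   log_or = est, se = se, z = est / se)
  })
}

#' Trial sequential analysis of a cumulative meta-analysis
#'
#' Runs the full sequential analysis of the chosen genetic contrast:
#' diversity-adjusted required information size, O'Brien-Fleming-type
#' monitoring boundaries at the looks defined by the studies' cumulative
#' subject counts, the cumulative random-effects Z-curve, and the
#' sequential-testing-adjusted confidence interval.
#'
#' Defaults are derived from the data unless supplied: the control event
#' proportion is the pooled exposure frequency of the control arms under the
#' chosen contrast (the T allele frequency for the allele model), the
#' relative risk increase is the pooled random-effects odds ratio minus one,
#' and `d2` is computed from the same effects via [diversity()].
#'
#' The adjusted 95% CI widens the conventional Wald interval of the pooled
#' random-effects estimate by the ratio of the final-look boundary to
#' `z_{1-alpha/2}`; once the accrued information reaches the required size
#' the final-look fraction is capped at 1 and the adjusted interval
#' coincides with the conventional one.
#'
#' @param studies A study table.
#' @param model Genetic contrast (default `"allele"`).
#' @param alpha Two-sided type-I error (default 0.05).
#' @param power Power used in the information-size calculation (default
#'   0.80).
#' @param control_event_proportion Override for the control event
#'   proportion (default `NULL`: derived from the data).
#' @param rri Override for the relative risk increase (default `NULL`:
#'   pooled OR minus 1).
#' @param d2 `"auto"` (default) or a diversity fraction in [0, 1).
#' @param variant Information-size constant, see
#'   [required_information_size()].
#' @return A `tsa_result` object; see [tidy.tsa_result()] and
#'   [autoplot.tsa_result()].
#' @examples
#' mthfr_mm_studies() |> tsa(rri = 0.1681, d2 = 0.67)
#' @export
tsa <- function(studies, model = "allele", alpha = 0.05, power = 0.80,
                control_event_proportion = NULL, rri = NULL, d2 = "auto",
                variant = c("per_group", "total")) {
  variant <- match.arg(variant)
  studies <- sort_chronological(studies)
  model <- match.arg(model, genetic_models())
  effects <- study_effects(studies, model)
  pooled <- if (nrow(effects) >= 2) pool_random(effects) else
    pool_fixed(effects, weights = "iv")

  div <- if (nrow(effects) >= 2) diversity(effects) else
    tibble::tibble(d2 = 0, tau2 = 0, v_fixed = pooled$se^2,
                   v_random = pooled$se^2)
  d2_used <- if (identical(d2, "auto")) div$d2 else as.numeric(d2)

  if (is.null(control_event_proportion)) {
    contrast <- build_contrast(studies, model)
    control_event_proportion <- sum(contrast$exposed_controls) /
      sum(contrast$exposed_controls + contrast$unexposed_controls)
  }
  if (is.null(rri)) rri <- pooled$or - 1

  ris <- required_information_size(control_event_proportion, rri,
                                   alpha = alpha, power = power,
                                   d2 = d2_used, variant = variant)

  curve <- cumulative_z(studies, model)
  frac <- pmin(curve$cumulative_n / ris$required_is, 1)
  ufrac <- unique(frac)
  btab <- obf_boundary(ufrac, alpha = alpha)
  z_bound <- btab$z_boundary[match(frac, btab$information_fraction)]
  curve$information_fraction <- frac
  curve$z_boundary <- z_bound

  final_boundary <- z_bound[length(z_bound)]
  zcrit <- qnorm(1 - alpha / 2)
  inflation <- final_boundary / zcrit
  adjusted_ci <- exp(pooled$log_or +
                       c(-1, 1) * inflation * zcrit * pooled$se)

  structure(
    list(
      genetic_model = model,
      alpha = alpha, power = power,
      control_event_proportion = control_event_proportion,
      rri = rri, d2 = d2_used, diversity = div,
      adjustment_factor = ris$adjustment_factor,
      required_is = ris$required_is, ris = ris,
      boundary = btab, z_curve = curve,
      boundary_crossed = any(abs(curve$z) >= curve$z_boundary),
      is_reached = max(curve$cumulative_n) >= ris$required_is,
      adjusted_ci95 = adjusted_ci,
      pooled = pooled
    ),
    class = "tsa_result"
  )
}

#' @describeIn tsa Per-look table: Z-curve, information fractions and
#'   boundary values.
#' @param x A `tsa_result` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.tsa_result <- function(x, ...) {
  x$z_curve
}

#' @describeIn tsa One-row summary of the sequential analysis.
#' @exportS3Method generics::glance
glance.tsa_result <- function(x, ...) {
  tibble::tibble(
    genetic_model = x$genetic_model,
    k = nrow(x$z_curve),
    control_event_proportion = x$control_event_proportion,
    rri = x$rri, d2 = x$d2, adjustment_factor = x$adjustment_factor,
    required_is = x$required_is,
    accrued = max(x$z_curve$cumulative_n),
    is_reached = x$is_reached,
    boundary_crossed = x$boundary_crossed,
    final_z = x$z_curve$z[nrow(x$z_curve)],
    or = x$pooled$or,
    adj_ci_low = x$adjusted_ci95[1], adj_ci_high = x$adjusted_ci95[2]
  )
}

#' @export
print.tsa_result <- function(x, ...) {
  cat(sprintf("Trial sequential analysis (%s model), %d looks\n",
              x$genetic_model, nrow(x$z_curve)))
  cat(sprintf("  control event proportion %.4f, RRI %.2f%%, D2 %.1f%%\n",
              x$control_event_proportion, 100 * x$rri, 100 * x$d2))
  cat(sprintf("  required information size %d subjects; accrued %d (%s)\n",
              x$required_is, max(x$z_curve$cumulative_n),
              if (x$is_reached) "reached" else "not reached"))
  cat(sprintf("  final Z = %.2f; boundary %s\n",
              x$z_curve$z[nrow(x$z_curve)],
              if (x$boundary_crossed) "crossed" else "not crossed"))
  cat(sprintf("  OR %.2f, TSA-adjusted 95%% CI %.2f-%.2f\n",
              x$pooled$or, x$adjusted_ci95[1], x$adjusted_ci95[2]))
  invisible(x)
}

#' @describeIn tsa Z-curve with the two-sided monitoring boundaries.
#' @param object A `tsa_result` object.
#' @exportS3Method ggplot2::autoplot
autoplot.tsa_result <- function(object, ...) {
  cz <- object$z_curve
  zcrit <- qnorm(1 - object$alpha / 2)
  bshow <- dplyr::filter(cz, .data$z_boundary < 8.5)
  ggplot2::ggplot(cz, ggplot2::aes(x = .data$cumulative_n)) +
    ggplot2::geom_hline(yintercept = c(-zcrit, zcrit), linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(data = bshow, ggplot2::aes(y = .data$z_boundary),
                       colour = "red3", linetype = "dashed") +
    ggplot2::geom_line(data = bshow, ggplot2::aes(y = -.data$z_boundary),
                       colour = "red3", linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$z), colour = "blue3") +
    ggplot2::geom_point(ggplot2::aes(y = .data$z), colour = "blue3") +
    ggplot2::geom_vline(xintercept = object$required_is,
                        linetype = "longdash", colour = "grey40") +
    ggplot2::labs(x = "Cumulative number of subjects", y = "Cumulative Z",
                  title = sprintf(
                    "Trial sequential analysis (%s model); RIS = %d",
                    object$genetic_model, object$required_is)) +
    ggplot2::theme_minimal()
}
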