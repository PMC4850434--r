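#' Egger regression test for funnel-plot asymmetry
#'
#' Ordinary least squares of the standardized effect (`log_or/se`) on
#' precision (`1/se`), in Egger's classical unweighted form. The intercept
#' estimates small-study asymmetry; its t statistic has `k - 2` degrees of
#' freedom. The weighted variant of the test gives different t values and is
#' deliberately not used here.
#'
#' @param effects Per-study effects (columns `log_or`, `se`); at least 3.
#' @return One-row tibble: `intercept`, `intercept_se`, `t`, `df`, `p`
#'   (two-sided), `slope`, `slope_se`.
#' @examples
#' mthfr_mm_studies() |> study_effects("recessive") |> egger_test()
#' @export
egger_test <- function(effects) {
  check_effects(effects, k_min = 3, caller = "egger_test")
  y <- effects$log_or / effects$se
  x <- 1 / effects$se
  fit <- lm(y ~ x)
  cf <- summary(fit)$coefficients
  tibble::tibble(
    intercept = cf[1, 1], intercept_se = cf[1, 2],
    t = cf[1, 3], df = nrow(effects) - 2L, p = cf[1, 4],
    slope = cf[2, 1], slope_se = cf[2, 2]
  )
}

#' Begg-Mazumdar rank correlation test
#'
#' Kendall's tau between the variance-standardized deviates of the study
#' effects (centred on the inverse-variance fixed-effect mean) and the
#' study variances, with a normal approximation for the p-value
#' (continuity-corrected by default). Ties contribute to neither the
#' concordant nor the discordant count.
#'
#' @inheritParams egger_test
#' @param continuity Apply the continuity correction to the z statistic
#'   (default `TRUE`).
#' @return One-row tibble: `kendall_tau`, `concordant`, `discordant`, `z`,
#'   `p`.
#' @export
begg_test <- function(effects, continuity = TRUE) {
  check_effects(effects, k_min = 3, caller = "begg_test")
  k <- nrow(effects)
  v <- effects$se^2
  w <- 1 / v
  ybar <- sum(w * effects$log_or) / sum(w)
  vj <- v - 1 / sum(w)           # variance of the deviate from the pooled mean
  dev <- (effects$log_or - ybar) / sqrt(vj)
  pairs <- utils::combn(k, 2)
  s <- sign(dev[pairs[2, ]] - dev[pairs[1, ]]) * sign(v[pairs[2, ]] - v[pairs[1, ]])
  con <- sum(s > 0)
  dis <- sum(s < 0)
  tau <- (con - dis) / choose(k, 2)
  denom <- sqrt(k * (k - 1) * (2 * k + 5) / 18)
  num <- if (continuity) max(0, abs(con - dis) - 1) else abs(con - dis)
  z <- sign(con - dis) * num / denom
  tibble::tibble(kendall_tau = tau, concordant = con, discordant = dis,
                 z = z, p = 2 * pnorm(-abs(z)))
}

#' Funnel-plot coordinates
#'
#' One point per study (`log_or`, `se`) plus the pooled log odds ratio as
#' the reference line value (column `ref_log_or`, constant).
#'
#' @inheritParams egger_test
#' @param pooled Optional `meta_pool` object supplying the reference line;
#'   by default the effects are pooled with [meta_pool()] defaults.
#' @return Tibble: `study_id`, `log_or`, `se`, `ref_log_or`.
#' @export
funnel_coordinates <- function(effects, pooled = NULL) {
  check_effects(effects, k_min = 1, caller = "funnel_coordinates")
  if (is.null(pooled)) {
    pooled <- if (nrow(effects) == 1)
      list(log_or = effects$log_or[1]) else meta_pool(effects,
        weights = if (all(c("a", "b", "c", "d") %in% names(effects))) "mh" else "iv")
  }
  tibble::tibble(
    study_id = if ("study_id" %in% names(effects)) effects$study_id
               else as.character(seq_len(nrow(effects))),
    log_or = effects$log_or, se = effects$se,
    ref_log_or = pooled$log_or
  )
}

#' Begg-style funnel plot
#'
#' Scatter of per-study log odds ratios against their standard errors
#' (inverted axis), with the pooled estimate as a dashed reference line and
#' the pseudo 95% confidence funnel around it.
#'
#' @inheritParams funnel_coordinates
#' @return A ggplot object.
#' @export
plot_funnel <- function(effects, pooled = NULL) {
  pts <- funnel_coordinates(effects, pooled)
  se_max <- max(pts$se) * 1.05
  funnel <- tibble::tibble(
    se = seq(0, se_max, length.out = 50),
    lo = pts$ref_log_or[1] - qnorm(0.975) * se,
    hi = pts$ref_log_or[1] + qnorm(0.975) * se
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$log_or, y = .data$se)) +
    ggplot2::geom_line(data = funnel, ggplot2::aes(x = .data$lo, y = .data$se),
                       linetype = "dotted", colour = "grey40") +
    ggplot2::geom_line(data = funnel, ggplot2::aes(x = .data$hi, y = .data$se),
                       linetype = "dotted", colour = "grey40") +
    ggplot2::geom_vline(xintercept = pts$ref_log_or[1], linetype = "dashed") +
    ggplot2::geom_point(shape = 1, size = 2.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "log OR", y = "Standard error of log OR",
                  title = "Funnel plot") +
    ggplot2::theme_minimal()
}
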