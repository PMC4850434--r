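#' Heterogeneity statistics (Cochran's Q, I-squared, DerSimonian-Laird tau2)
#'
#' Q is the inverse-variance weighted sum of squared deviations of the study
#' log odds ratios from the fixed-effect mean; `i2 = max(0, (Q - df)/Q) * 100`
#' and `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` with
#' `w = 1/se^2` (DerSimonian & Laird moment estimator).
#'
#' @param effects Per-study effects, e.g. from [study_effects()]; needs
#'   columns `log_or` and `se` and at least two rows.
#' @return One-row tibble: `k`, `q`, `df`, `p_q`, `i2` (percent), `tau2`.
#' @export
heterogeneity <- function(effects) {
  check_effects(effects, k_min = 2, caller = "heterogeneity")
  y <- effects$log_or
  w <- 1 / effects$se^2
  k <- length(y)
  yf <- sum(w * y) / sum(w)
  q <- sum(w * (y - yf)^2)
  df <- k - 1
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  tibble::tibble(k = k, q = q, df = df,
                 p_q = pchisq(q, df, lower.tail = FALSE),
                 i2 = i2, tau2 = tau2)
}

#' Choose between fixed- and random-effects pooling
#'
#' Returns `"random"` when the heterogeneity is substantial -- Q's p-value
#' below `p_threshold` or I-squared above `i2_threshold` percent -- and
#' `"fixed"` otherwise.
#'
#' @param het One-row tibble from [heterogeneity()].
#' @param p_threshold Q p-value threshold (default 0.10).
#' @param i2_threshold I-squared threshold in percent (default 50).
#' @return `"fixed"` or `"random"`.
#' @export
select_model <- function(het, p_threshold = 0.10, i2_threshold = 50) {
  if (het$p_q < p_threshold || het$i2 > i2_threshold) "random" else "fixed"
}

new_meta_pool <- function(log_or, se, model_used, weights_type, effects, het,
                          weights, conf_level = 0.95) {
  zcrit <- qnorm(1 - (1 - conf_level) / 2)
  z <- log_or / se
  structure(
    list(
      genetic_model = if ("model" %in% names(effects)) effects$model[1] else NA_character_,
      model_used = model_used,
      weights_type = weights_type,
      k = nrow(effects),
      log_or = log_or, se = se,
      or = exp(log_or),
      ci95 = exp(log_or + c(-1, 1) * zcrit * se),
      z = z,
      p = 2 * pnorm(-abs(z)),
      conf_level = conf_level,
      het = het,
      effects = dplyr::mutate(effects, weight = weights / sum(weights))
    ),
    class = "meta_pool"
  )
}

#' Fixed-effect pooling of per-study odds ratios
#'
#' Default is Mantel-Haenszel pooling of the 2x2 cells with the
#' Robins-Breslow-Greenland variance, the convention of standard
#' meta-analysis software for count data (and the one that reproduces the
#' published fixed-effect rows); `weights = "iv"` gives classical
#' inverse-variance pooling of the Woolf log odds ratios instead.
#'
#' @param effects Per-study effects from [study_effects()] (at least one
#'   row; Mantel-Haenszel additionally needs the cell columns `a`..`d`).
#' @param weights `"mh"` (Mantel-Haenszel, default) or `"iv"`
#'   (inverse-variance).
#' @return A `meta_pool` object; see [tidy.meta_pool()].
#' @export
pool_fixed <- function(effects, weights = c("mh", "iv")) {
  weights <- match.arg(weights)
  check_effects(effects, k_min = 1, caller = "pool_fixed")
  het <- if (nrow(effects) >= 2) heterogeneity(effects) else NULL
  if (weights == "mh") {
    if (!all(c("a", "b", "c", "d") %in% names(effects))) {
      abort("Mantel-Haenszel pooling needs the 2x2 cell columns a, b, c, d",
            class = "mmtsa_validation_error")
    }
    n <- effects$a + effects$b + effects$c + effects$d
    R <- effects$a * effects$d / n
    S <- effects$b * effects$c / n
    P <- (effects$a + effects$d) / n
    Q <- (effects$b + effects$c) / n
    log_or <- log(sum(R) / sum(S))
    v <- sum(P * R) / (2 * sum(R)^2) +
      (sum(P * S) + sum(Q * R)) / (2 * sum(R) * sum(S)) +
      sum(Q * S) / (2 * sum(S)^2)
    new_meta_pool(log_or, sqrt(v), "fixed", "mh", effects, het, weights = S)
  } else {
    w <- 1 / effects$se^2
    log_or <- sum(w * effects$log_or) / sum(w)
    new_meta_pool(log_or, 1 / sqrt(sum(w)), "fixed", "iv", effects, het,
                  weights = w)
  }
}

#' Random-effects pooling (DerSimonian-Laird)
#'
#' Inverse-variance pooling with weights `1/(se^2 + tau2)`, where `tau2` is
#' the DerSimonian-Laird moment estimate from [heterogeneity()] (or a value
#' supplied explicitly). With `tau2 = 0` this reduces exactly to
#' inverse-variance fixed-effect pooling.
#'
#' @inheritParams heterogeneity
#' @param tau2 Optional between-study variance override; default `NULL`
#'   estimates it from the data.
#' @return A `meta_pool` object.
#' @export
pool_random <- function(effects, tau2 = NULL) {
  check_effects(effects, k_min = 2, caller = "pool_random")
  het <- heterogeneity(effects)
  if (!is.null(tau2)) het$tau2 <- tau2
  w <- 1 / (effects$se^2 + het$tau2)
  log_or <- sum(w * effects$log_or) / sum(w)
  new_meta_pool(log_or, 1 / sqrt(sum(w)), "random", "iv", effects, het,
                weights = w)
}

#' Pool per-study effects, choosing the model from the heterogeneity
#'
#' @inheritParams pool_fixed
#' @param method `"auto"` (default: [select_model()] decides), `"fixed"`,
#'   or `"random"`.
#' @inheritParams select_model
#' @return A `meta_pool` object.
#' @examples
#' mthfr_mm_studies() |> study_effects("allele") |> meta_pool()
#' @export
meta_pool <- function(effects, method = c("auto", "fixed", "random"),
                      weights = c("mh", "iv"),
                      p_threshold = 0.10, i2_threshold = 50) {
  method <- match.arg(method)
  weights <- match.arg(weights)
  check_effects(effects, k_min = 1, caller = "meta_pool")
  if (method == "auto") {
    method <- if (nrow(effects) < 2) "fixed"
      else select_model(heterogeneity(effects), p_threshold, i2_threshold)
  }
  if (method == "fixed") pool_fixed(effects, weights = weights)
  else pool_random(effects)
}

#' Meta-analysis of every genetic model
#'
#' Runs [study_effects()] and [meta_pool()] for each requested genetic model
#' and returns one summary row per model, mirroring the usual published
#' layout (OR with 95% CI, p, model used, I-squared).
#'
#' @param studies A study table.
#' @param models Genetic models to run (default all five).
#' @inheritParams meta_pool
#' @return Tibble with columns `genetic_model`, `contrast`, `k`, `or`,
#'   `ci_low`, `ci_high`, `p`, `model_used`, `q`, `p_q`, `i2`, `tau2`.
#' @export
meta_table <- function(studies, models = genetic_models(),
                       weights = c("mh", "iv")) {
  weights <- match.arg(weights)
  studies <- validate_studies(studies)
  purrr::map_dfr(models, function(m) {
    pooled <- meta_pool(study_effects(studies, m), weights = weights)
    tidy(pooled)
  })
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools the effects `k` times, omitting one study each time, with the
#' fixed/random choice re-made on every subset.
#'
#' @inheritParams meta_pool
#' @return Tibble with one row per omitted study: `omitted` plus the
#'   columns of [tidy.meta_pool()].
#' @export
leave_one_out <- function(effects, weights = c("mh", "iv")) {
  weights <- match.arg(weights)
  check_effects(effects, k_min = 3, caller = "leave_one_out")
  ids <- if ("study_id" %in% names(effects)) effects$study_id
         else as.character(seq_len(nrow(effects)))
  purrr::map_dfr(seq_len(nrow(effects)), function(i) {
    dplyr::bind_cols(
      tibble::tibble(omitted = ids[i]),
      tidy(meta_pool(effects[-i, , drop = FALSE], weights = weights))
    )
  })
}

#' @describeIn meta_pool Tidy one-row summary of a pooled result.
#' @param x A `meta_pool` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.meta_pool <- function(x, ...) {
  tibble::tibble(
    genetic_model = x$genetic_model,
    contrast = if (x$genetic_model %in% genetic_models())
      model_contrast(x$genetic_model) else NA_character_,
    k = x$k,
    log_or = x$log_or, se = x$se,
    or = x$or, ci_low = x$ci95[1], ci_high = x$ci95[2],
    z = x$z, p = x$p,
    model_used = x$model_used,
    q = if (is.null(x$het)) NA_real_ else x$het$q,
    p_q = if (is.null(x$het)) NA_real_ else x$het$p_q,
    i2 = if (is.null(x$het)) NA_real_ else x$het$i2,
    tau2 = if (is.null(x$het)) NA_real_ else x$het$tau2
  )
}

#' @describeIn meta_pool Heterogeneity-focused one-row summary.
#' @exportS3Method generics::glance
glance.meta_pool <- function(x, ...) {
  if (is.null(x$het)) {
    tibble::tibble(k = x$k, q = NA_real_, df = NA_real_, p_q = NA_real_,
                   i2 = NA_real_, tau2 = NA_real_)
  } else {
    x$het
  }
}

#' @export
print.meta_pool <- function(x, ...) {
  cat(sprintf("Pooled odds ratio (%s-effect%s, %s), k = %d studies\n",
              x$model_used,
              if (x$model_used == "fixed" && x$weights_type == "mh")
                ", Mantel-Haenszel" else "",
              if (is.na(x$genetic_model)) "custom contrast"
              else model_contrast(x$genetic_model), x$k))
  cat(sprintf("  OR %.2f (95%% CI %.2f-%.2f), z = %.2f, p = %.3g\n",
              x$or, x$ci95[1], x$ci95[2], x$z, x$p))
  if (!is.null(x$het)) {
    cat(sprintf("  Q = %.2f (df %d, p = %.3g), I2 = %.0f%%, tau2 = %.4f\n",
                x$het$q, x$het$df, x$het$p_q, x$het$i2, x$het$tau2))
  }
  invisible(x)
}

#' @describeIn meta_pool Forest plot of the study and pooled odds ratios.
#' @param object A `meta_pool` object.
#' @exportS3Method ggplot2::autoplot
autoplot.meta_pool <- function(object, ...) {
  eff <- object$effects
  zcrit <- qnorm(1 - (1 - object$conf_level) / 2)
  ids <- if ("study_id" %in% names(eff)) eff$study_id
         else as.character(seq_len(nrow(eff)))
  rows <- tibble::tibble(
    label = factor(c(ids, "Pooled"), levels = rev(c(ids, "Pooled"))),
    or = c(exp(eff$log_or), object$or),
    lo = c(exp(eff$log_or - zcrit * eff$se), object$ci95[1]),
    hi = c(exp(eff$log_or + zcrit * eff$se), object$ci95[2]),
    weight = c(eff$weight, NA),
    pooled = c(rep(FALSE, nrow(eff)), TRUE)
  )
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$or, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight,
                                     shape = .data$pooled)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 15, `TRUE` = 18),
                                guide = "none") +
    ggplot2::scale_size_continuous(guide = "none") +
    ggplot2::labs(
      x = "Odds ratio (log scale)", y = NULL,
      title = sprintf("%s (%s-effects pool)",
                      if (is.na(object$genetic_model)) "Pooled odds ratio"
                      else model_contrast(object$genetic_model),
                      object$model_used)
    ) +
    ggplot2::theme_minimal()
}
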