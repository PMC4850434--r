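test_that("heterogeneity closed forms: homogeneity, scale equivariance", {
  ident <- make_effects(rep(0.3, 5), rep(0.1, 5))
  h <- heterogeneity(ident)
  expect_equal(h$q, 0)
  expect_equal(h$i2, 0)
  expect_equal(h$tau2, 0)

  withr::with_seed(3, {
    eff <- make_effects(rnorm(8, 0.2, 0.3), runif(8, 0.05, 0.4))
    h1 <- heterogeneity(eff)
    scaled <- make_effects(eff$log_or * 3, eff$se * 3)
    h2 <- heterogeneity(scaled)
    expect_equal(h2$q, h1$q)            # Q is scale invariant
    expect_equal(h2$i2, h1$i2)
    expect_equal(h2$tau2, h1$tau2 * 9)  # tau2 carries the squared scale
  })

  expect_error(heterogeneity(make_effects(0.2, 0.1)),
               class = "mmtsa_validation_error")
})

test_that("fixed-effect pooling closed forms (k = 1, duplicated effects)", {
  one <- make_effects(0.5, 0.2)
  p1 <- pool_fixed(one, weights = "iv")
  expect_equal(p1$log_or, 0.5)
  expect_equal(p1$se, 0.2)

  two <- make_effects(c(0.5, 0.5), c(0.2, 0.2))
  p2 <- pool_fixed(two, weights = "iv")
  expect_equal(p2$log_or, 0.5)
  expect_equal(p2$se, 0.2 / sqrt(2))

  # Mantel-Haenszel on a single table equals the table's own odds ratio
  eff <- study_effects(mthfr_mm_studies()[3, ], "allele")
  pmh <- pool_fixed(eff, weights = "mh")
  expect_equal(pmh$log_or, eff$log_or)
  expect_equal(pmh$se, eff$se, tolerance = 1e-12)

  expect_error(pool_fixed(make_effects(numeric(0), numeric(0))),
               class = "mmtsa_validation_error")
})

test_that("random-effects pooling with tau2 = 0 equals inverse-variance fixed", {
  withr::with_seed(5, {
    eff <- make_effects(rnorm(6, 0.1, 0.2), runif(6, 0.1, 0.5))
    pr <- pool_random(eff, tau2 = 0)
    pf <- pool_fixed(eff, weights = "iv")
    expect_equal(pr$log_or, pf$log_or)
    expect_equal(pr$se, pf$se)
  })
  # identical effects estimate tau2 = 0, so the equality holds unforced
  ident <- make_effects(rep(0.2, 4), rep(0.15, 4))
  expect_equal(pool_random(ident)$log_or, pool_fixed(ident, "iv")$log_or)
  expect_equal(pool_random(ident)$se, pool_fixed(ident, "iv")$se)
})

test_that("pooled results satisfy their structural invariants", {
  for (m in genetic_models()) {
    eff <- study_effects(mthfr_mm_studies(), m)
    for (meth in c("fixed", "random")) {
      p <- meta_pool(eff, method = meth)
      expect_equal(sum(p$effects$weight), 1)
      expect_true(p$ci95[1] < p$or && p$or < p$ci95[2])
    }
    expect_gte(pool_random(eff)$se, pool_fixed(eff, "iv")$se)
  }
})

test_that("model selection follows the heterogeneity rule", {
  het <- function(p_q, i2) tibble::tibble(p_q = p_q, i2 = i2)
  expect_equal(select_model(het(0.05, 30)), "random")  # p_q below 0.10
  expect_equal(select_model(het(0.50, 60)), "random")  # I2 above 50
  expect_equal(select_model(het(0.50, 30)), "fixed")
  expect_equal(select_model(het(1.00, 0)), "fixed")    # q = 0 case
})

test_that("pooling agrees with metafor (DL random, IV fixed) on the packaged data", {
  s <- mthfr_mm_studies()
  for (m in genetic_models()) {
    eff <- study_effects(s, m)
    fit_re <- metafor::rma(yi = eff$log_or, vi = eff$se^2, method = "DL")
    pr <- pool_random(eff)
    expect_equal(pr$log_or, as.numeric(coef(fit_re)), tolerance = 1e-10)
    expect_equal(pr$se, fit_re$se, tolerance = 1e-10)
    expect_equal(pr$het$tau2, fit_re$tau2, tolerance = 1e-10)
    expect_equal(pr$het$i2, as.numeric(fit_re$I2), tolerance = 1e-6)

    fit_fe <- metafor::rma(yi = eff$log_or, vi = eff$se^2, method = "FE")
    pf <- pool_fixed(eff, weights = "iv")
    expect_equal(pf$log_or, as.numeric(coef(fit_fe)), tolerance = 1e-10)
    expect_equal(pf$se, fit_fe$se, tolerance = 1e-10)
  }
})

test_that("Mantel-Haenszel pooling agrees with metafor::rma.mh", {
  s <- mthfr_mm_studies()
  for (m in c("allele", "recessive", "homozygous")) {
    eff <- study_effects(s, m)
    fit <- metafor::rma.mh(ai = eff$a, bi = eff$b, ci = eff$c, di = eff$d,
                           measure = "OR", add = 0, to = "none",
                           correct = FALSE)
    pmh <- pool_fixed(eff, weights = "mh")
    expect_equal(pmh$log_or, as.numeric(coef(fit)), tolerance = 1e-10)
    expect_equal(pmh$se, fit$se, tolerance = 1e-10)
  }
})

test_that("leave-one-out: identical studies, outlier detection, k guard", {
  ident <- make_effects(rep(0.4, 3), rep(0.2, 3))
  loo <- leave_one_out(ident, weights = "iv")
  expect_equal(nrow(loo), 3)
  expect_equal(loo$or, rep(exp(0.4), 3))

  # brute-force: deleting the planted outlier moves the pool the most
  withr::with_seed(9, {
    eff <- make_effects(c(rnorm(8, 0.2, 0.05), 2.5), rep(0.15, 9))
    loo <- leave_one_out(eff, weights = "iv")
    full <- meta_pool(eff, weights = "iv")$log_or
    shifts <- abs(loo$log_or - full)
    expect_equal(which.max(shifts), 9)
  })

  expect_error(leave_one_out(make_effects(c(0, 0), c(1, 1))),
               class = "mmtsa_validation_error")
})

test_that("tidy and glance return well-formed one-row summaries", {
  p <- meta_pool(study_effects(mthfr_mm_studies(), "allele"))
  td <- tidy(p)
  expect_equal(nrow(td), 1)
  expect_equal(td$genetic_model, "allele")
  expect_equal(td$contrast, "T vs C")
  gl <- glance(p)
  expect_equal(gl$k, 9)
  expect_s3_class(autoplot(p), "ggplot")
})
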