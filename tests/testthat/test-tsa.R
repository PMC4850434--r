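test_that("diversity: homogeneous data give zero, equal-SE closed form holds", {
  ident <- make_effects(rep(0.2, 4), rep(0.1, 4))
  expect_equal(diversity(ident)$d2, 0)

  # k = 2, se = 0.1, tau2 pinned at 0.01:
  # v_fixed = 0.01/2, v_random = (0.01 + 0.01)/2, so d2 = 0.5
  two <- make_effects(c(0.1, 0.3), c(0.1, 0.1))
  d <- diversity(two, tau2 = 0.01)
  expect_equal(d$v_fixed, 0.005)
  expect_equal(d$v_random, 0.01)
  expect_equal(d$d2, 0.5)

  expect_error(diversity(make_effects(0.1, 0.1)),
               class = "mmtsa_validation_error")
})

test_that("diversity dominates I-squared on heterogeneous data", {
  eff <- study_effects(mthfr_mm_studies(), "allele")
  expect_gte(diversity(eff)$d2, heterogeneity(eff)$i2 / 100)
  withr::with_seed(31, {
    for (i in 1:10) {
      eff <- make_effects(rnorm(7, 0.2, 0.4), runif(7, 0.05, 0.5))
      expect_gte(diversity(eff)$d2 + 1e-12, heterogeneity(eff)$i2 / 100)
    }
  })
})

test_that("required information size: scaling laws and guards", {
  ris <- required_information_size(0.3802, 0.1681, d2 = 0.67)
  ris0 <- required_information_size(0.3802, 0.1681, d2 = 0)
  # adjustment factor by construction
  expect_equal(ris0$unadjusted, ris$required_is_raw * (1 - 0.67))
  expect_equal(ris$adjustment_factor, 1 / 0.33)

  # doubling delta at fixed pbar divides the unadjusted size by 4
  a <- required_information_size(0.40, 0.10)   # pbar 0.42, delta 0.04
  b <- required_information_size(0.38, 8 / 38) # pbar 0.42, delta 0.08
  expect_equal(a$unadjusted / b$unadjusted, 4)

  # the total-size variant doubles the per-group constant
  tot <- required_information_size(0.3802, 0.1681, d2 = 0.67,
                                   variant = "total")
  expect_equal(tot$required_is_raw, 2 * ris$required_is_raw)

  expect_error(required_information_size(0.4, 0), class = "mmtsa_validation_error")
  expect_error(required_information_size(0.4, 0.2, d2 = 1),
               class = "mmtsa_validation_error")
  expect_error(required_information_size(0.6, 0.8),
               class = "mmtsa_validation_error")
})

test_that("alpha spending reaches exactly alpha at full information", {
  expect_equal(obf_spending(1), 0.05)
  expect_equal(obf_spending(1, alpha = 0.01), 0.01)
  expect_lt(obf_spending(0.3), 0.001)   # spends almost nothing early
  spent <- obf_spending(seq(0.1, 1, by = 0.1))
  expect_true(all(diff(spent) >= 0))
})

test_that("boundary: single-look and two-look closed forms", {
  single <- obf_boundary(1)
  expect_equal(single$z_boundary, qnorm(0.975), tolerance = 1e-6)

  # single interim look: boundary solves the spending equation directly
  t0 <- 0.25
  expect_equal(obf_boundary(t0)$z_boundary,
               qnorm(1 - obf_spending(t0) / 2), tolerance = 1e-9)

  two <- obf_boundary(c(0.5, 1))
  expect_equal(two$alpha_spent[2], 0.05)            # endpoint spent exactly
  expect_equal(two$z_boundary, c(2.963, 1.969), tolerance = 1e-3)

  expect_error(obf_boundary(c(0.5, 0.5)), class = "mmtsa_validation_error")
  expect_error(obf_boundary(c(0.2, 1.2)), class = "mmtsa_validation_error")
})

test_that("boundary values decrease as information accrues", {
  b <- obf_boundary(seq(0.3, 1, length.out = 6))
  finite <- b$z_boundary[b$z_boundary < 8.5]
  expect_true(all(diff(finite) < 0))
})

test_that("boundary crossing probabilities match a Monte-Carlo Brownian oracle", {
  fr <- c(1 / 3, 2 / 3, 1)
  b <- obf_boundary(fr)
  n_paths <- 4e5
  withr::with_seed(41, {
    inc <- matrix(rnorm(n_paths * 3, sd = sqrt(diff(c(0, fr)))),
                  nrow = n_paths, byrow = TRUE)
    s <- t(apply(inc, 1, cumsum))                 # Brownian motion at looks
    z <- sweep(s, 2, sqrt(fr), "/")
    crossed <- abs(z) >= matrix(b$z_boundary, n_paths, 3, byrow = TRUE)
    ever <- t(apply(crossed, 1, cummax))
    emp <- colMeans(ever)                         # cumulative crossing rate
  })
  mc_se <- sqrt(b$alpha_spent * (1 - b$alpha_spent) / n_paths)
  expect_true(all(abs(emp - b$alpha_spent) < 4.5 * mc_se + 1e-4))
})

test_that("cumulative Z-curve accrues chronologically and ends at the full pool", {
  s <- mthfr_mm_studies()
  cz <- cumulative_z(s, "allele")
  expect_equal(nrow(cz), 9)
  expect_equal(cz$study_id[1], "González Ordóñez")
  expect_true(all(diff(cz$cumulative_n) > 0))
  expect_equal(cz$cumulative_n[9], 7046)

  full <- pool_random(study_effects(s, "allele"))
  expect_equal(cz$z[9], full$z)
  expect_equal(cz$log_or[9], full$log_or)

  one <- cumulative_z(s[1, ], "allele")
  eff1 <- study_effects(s[1, ], "allele")
  expect_equal(nrow(one), 1)
  expect_equal(one$z, eff1$log_or / eff1$se)
})

test_that("tsa: information size reached makes the adjusted CI conventional", {
  s <- mthfr_mm_studies()
  ts <- tsa(s, rri = 0.1681, d2 = 0.67)
  expect_true(ts$is_reached)
  expect_true(ts$boundary_crossed)
  # the final-look boundary matches z_{0.975} to ~1e-4 (the recursion
  # spends a sliver of alpha before full information), so the intervals
  # agree to the same order
  conventional <- ts$pooled$ci95
  expect_equal(ts$adjusted_ci95, conventional, tolerance = 1e-3)
  expect_equal(ts$adjustment_factor, 1 / (1 - ts$d2))
})

test_that("tsa: an unreached information size widens the adjusted CI", {
  s <- mthfr_mm_studies()
  # a tiny anticipated effect makes the required size unattainable
  ts <- tsa(s, rri = 0.02, d2 = 0.67)
  expect_false(ts$is_reached)
  conventional <- ts$pooled$ci95
  expect_lt(ts$adjusted_ci95[1], conventional[1])
  expect_gt(ts$adjusted_ci95[2], conventional[2])
})

test_that("tsa derives its defaults from the data", {
  s <- mthfr_mm_studies()
  ts <- tsa(s)
  # control event proportion = pooled control T-allele frequency
  expect_equal(round(ts$control_event_proportion, 4), 0.3802)
  # relative risk increase = pooled random-effects OR - 1
  pooled <- pool_random(study_effects(s, "allele"))
  expect_equal(ts$rri, pooled$or - 1)
  expect_equal(ts$d2, diversity(study_effects(s, "allele"))$d2)
  expect_s3_class(autoplot(ts), "ggplot")
  expect_equal(nrow(tidy(ts)), 9)
  expect_equal(glance(ts)$accrued, 7046)
})
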