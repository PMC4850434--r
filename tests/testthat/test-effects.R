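test_that("HWE test: exact-fit, monomorphic and published spot values", {
  # counts exactly at the HWE expectation for q = 0.3, n = 100
  exact <- hwe_test(49, 42, 9)
  expect_equal(exact$chi2, 0)
  expect_equal(exact$p, 1)

  mono <- hwe_test(c(50, 0), c(0, 0), c(0, 80))
  expect_equal(mono$chi2, c(0, 0))
  expect_equal(mono$p, c(1, 1))

  expect_equal(round(hwe_test(144, 196, 94)$p, 2), 0.08)  # Moon controls
  expect_equal(round(hwe_test(540, 863, 297)$p, 2), 0.13) # Kim controls

  expect_error(hwe_test(0, 0, 0), class = "mmtsa_validation_error")
})

test_that("HWE expected counts always sum to the observed total", {
  withr::with_seed(11, {
    cc <- rpois(50, 40); ct <- rpois(50, 50); tt <- rpois(50, 15) + 1L
    h <- hwe_test(cc, ct, tt)
    expect_equal(h$exp_cc + h$exp_ct + h$exp_tt, as.numeric(cc + ct + tt))
    expect_true(all(h$chi2 >= 0))
    expect_true(all(h$p >= 0 & h$p <= 1))
  })
})

test_that("contrast construction matches hand arithmetic on the Jiang row", {
  s <- mthfr_mm_studies()
  dom <- dplyr::filter(build_contrast(s, "dominant"), study_id == "Jiang")
  expect_equal(
    unlist(dom[, c("exposed_cases", "unexposed_cases",
                   "exposed_controls", "unexposed_controls")],
           use.names = FALSE),
    c(21, 9, 85, 72)
  )
  all_ <- dplyr::filter(build_contrast(s, "allele"), study_id == "Jiang")
  expect_equal(all_$exposed_cases, 31)
  expect_equal(all_$exposed_cases + all_$unexposed_cases, 60)
  expect_equal(all_$exposed_controls, 104)
  expect_equal(all_$exposed_controls + all_$unexposed_controls, 314)
})

test_that("allele-model margins are exactly twice the subject totals", {
  s <- mthfr_mm_studies()
  ct <- build_contrast(s, "allele")
  expect_equal(ct$exposed_cases + ct$unexposed_cases,
               2L * (s$case_cc + s$case_ct + s$case_tt))
  expect_equal(ct$exposed_controls + ct$unexposed_controls,
               2L * (s$ctrl_cc + s$ctrl_ct + s$ctrl_tt))
})

test_that("homozygous and heterozygous contrasts drop the excluded genotype", {
  s <- mthfr_mm_studies()
  hom <- build_contrast(s, "homozygous")
  expect_equal(hom$exposed_cases, s$case_tt)
  expect_equal(hom$unexposed_cases, s$case_cc)
  het <- build_contrast(s, "heterozygous")
  expect_equal(het$exposed_cases, s$case_ct)
  expect_equal(het$unexposed_controls, s$ctrl_cc)
})

test_that("effect_from_counts: closed forms, antisymmetry, zero-cell handling", {
  null_tab <- effect_from_counts(10, 10, 10, 10)
  expect_equal(null_tab$log_or, 0)
  expect_equal(null_tab$se, sqrt(0.4))

  ones <- effect_from_counts(1, 1, 1, 1)
  expect_equal(exp(ones$log_or), 1)
  expect_equal(ones$se, 2)
  expect_false(ones$corrected)

  # swapping exposure columns negates log_or, preserves se
  withr::with_seed(7, {
    for (i in 1:20) {
      cell <- sample(1:200, 4)
      e1 <- effect_from_counts(cell[1], cell[2], cell[3], cell[4])
      e2 <- effect_from_counts(cell[2], cell[1], cell[4], cell[3])
      expect_equal(e2$log_or, -e1$log_or)
      expect_equal(e2$se, e1$se)
      # independent odds-ratio oracle on the same four counts
      odds_case <- cell[1] / cell[2]
      odds_ctrl <- cell[3] / cell[4]
      expect_equal(exp(e1$log_or), odds_case / odds_ctrl)
    }
  })

  zc <- effect_from_counts(0, 10, 5, 5)
  expect_true(zc$corrected)
  expect_equal(zc$log_or, log((0.5 * 5.5) / (10.5 * 5.5)))
  expect_equal(zc$se, sqrt(1 / 0.5 + 1 / 10.5 + 1 / 5.5 + 1 / 5.5))
})

test_that("study effects agree with metafor's log odds ratios on the packaged data", {
  s <- mthfr_mm_studies()
  for (m in genetic_models()) {
    eff <- study_effects(s, m)
    ref <- metafor::escalc(measure = "OR", ai = eff$a, bi = eff$b,
                           ci = eff$c, di = eff$d, add = 0)
    expect_equal(eff$log_or, as.numeric(ref$yi), tolerance = 1e-12)
    expect_equal(eff$se^2, as.numeric(ref$vi), tolerance = 1e-12)
  }
})
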