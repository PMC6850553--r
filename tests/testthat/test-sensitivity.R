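test_that("timing variants share the main model's code path", {
  m <- small_cohort()$markets
  tv <- run_timing_variants(m)
  direct2 <- fit_count(m, "before_second")
  direct3 <- fit_count(m, "before_third")
  expect_equal(tv$before_second$estimate_ratio, direct2$estimate_ratio)
  expect_equal(tv$before_third$estimate_ratio, direct3$estimate_ratio)
  expect_equal(tv$before_second$robust_se_log, direct2$robust_se_log)
  # exposure only loosens with later timings
  expect_gte(sum(compute_exposure(m, "before_second")),
             sum(compute_exposure(m, "before_first")))
  expect_gte(sum(compute_exposure(m, "before_third")),
             sum(compute_exposure(m, "before_second")))
})

test_that("with no monographs every variant estimates from a null exposure", {
  m <- small_cohort()$markets
  m$product_monograph_date <- as.Date(NA)
  # exposure identically zero is degenerate by design: the fit reports an
  # error rather than a silent null estimate
  tv <- run_timing_variants(m)
  expect_s3_class(tv$before_second, "genentry_failed_fit")
  expect_s3_class(tv$before_third, "genentry_failed_fit")
})

test_that("interval restrictions drop exactly the hand-counted markets", {
  m <- small_cohort()$markets
  iv <- as.numeric(m$first_generic_date - m$nda_approval_date) / 365.25
  expected <- vapply(c(3, 5, 8), function(th) sum(is.na(iv) | iv > th), 0L)
  fits <- run_interval_restrictions(m)
  got <- vapply(fits, function(f) f$n_drugs, 0L)
  expect_equal(unname(got), expected)
  # threshold 0 reproduces the main fit exactly
  f0 <- run_interval_restrictions(m, thresholds_years = 0)[[1]]
  main <- fit_count(m)
  expect_equal(f0$estimate_ratio, main$estimate_ratio)
  # impossible threshold leaves no exposed market: reported as a fit error
  fbig <- run_interval_restrictions(m, thresholds_years = 1000)[[1]]
  expect_s3_class(fbig, "genentry_failed_fit")
})

test_that("class-size restrictions keep strictly smaller classes", {
  m <- small_cohort()$markets
  sizes <- table(m$therapeutic_class)
  fits <- run_class_size_restrictions(m, max_class_sizes = c(45, 1000))
  expect_equal(fits$lt_45$n_drugs,
               sum(sizes[sizes < 45]))
  main <- fit_count(m)
  expect_equal(fits$lt_1000$estimate_ratio, main$estimate_ratio)
  none <- run_class_size_restrictions(m, max_class_sizes = 1)[[1]]
  expect_s3_class(none, "genentry_failed_fit")
})

test_that("route strata partition the cohort and drop the route covariate", {
  m <- small_cohort()$markets
  fits <- run_route_strata(m)
  sizes <- table(m$route_group)
  ok <- !vapply(fits, inherits, TRUE, "genentry_failed_fit")
  expect_gte(sum(ok), 3L)
  for (rg in names(fits)[ok]) {
    f <- fits[[rg]]
    expect_equal(f$n_drugs + f$n_dropped, unname(sizes[rg]), info = rg)
  }
  # strata partition the cohort
  expect_equal(sum(sizes), nrow(m))
  for (f in fits[ok]) {
    expect_false(any(grepl("^route_", names(f$covariate_estimates))))
  }
})

test_that("an oral-only exposure effect is recovered only in the oral stratum", {
  # generator truth: same IRR everywhere; instead verify the stratified
  # machinery by planting a route-specific effect post hoc via subsetting:
  # the oral stratum of a cohort with IRR > 1 must estimate above 1 while a
  # zero-effect cohort's oral stratum stays near 1
  cfg_eff <- simulation_config(n_drugs = 600L, n_classes = 15L,
                               true_irr_count = 1.8, seed = 211L)
  cfg_null <- simulation_config(n_drugs = 600L, n_classes = 15L,
                                true_irr_count = 1.0, seed = 211L)
  f_eff <- run_route_strata(local({
    s <- simulate_cohort(cfg_eff)
    assemble_cohort(s$products, s$monographs, s$sales)$markets
  }))$oral
  f_null <- run_route_strata(local({
    s <- simulate_cohort(cfg_null)
    assemble_cohort(s$products, s$monographs, s$sales)$markets
  }))$oral
  expect_gt(f_eff$estimate_ratio, 1.2)
  expect_lt(abs(log(f_null$estimate_ratio)), 0.45)
})

test_that("the first-to-second gap model runs through the shared Cox path", {
  m <- small_cohort()$markets
  f <- run_gap12(m)
  expect_equal(f$estimand, "gap12_HR")
  expect_true(f$ci_low <= f$estimate_ratio & f$estimate_ratio <= f$ci_high)
  expect_equal(f$n_drugs, sum(m$n_generics >= 1))
})

test_that("the sensitivity report table assembles every analysis", {
  m <- small_cohort()$markets
  t3 <- sensitivity_table(m)
  expect_equal(nrow(t3), 13L)
  expect_true(any(t3$note != "") || all(is.finite(t3$estimate)))
})
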