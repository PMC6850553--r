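test_that("gap-time Cox matches direct maximization of a hand-coded partial likelihood", {
  # four markets with >=2 entrants; two exposed (monograph before the 2nd
  # generic); two observe a third entrant, two are censored at study end
  spec <- data.frame(
    ingredient = c("D1", "D2", "D3", "D4"),
    class = c("C1", "C1", "C2", "C2"), nda = "1990-01-01",
    generics = c("2000-01-01;2001-01-01;2001-07-01",   # event, gap 181d
                 "2000-01-01;2001-01-01",              # censored
                 "2000-01-01;2001-01-01;2002-12-31",   # event, gap 729d
                 "2000-01-01;2001-01-01"),             # censored
    mono_date = c("1999-06-01", "1999-06-01", "", ""),
    stringsAsFactors = FALSE)
  m <- toy_markets(spec)
  fit <- fit_gap_time(m, 2L, 3L, adjusted = FALSE)

  # independent oracle: the partial likelihood written out by hand.
  # risk sets at the two event times (gaps from the 2nd entrant, censoring
  # at 2018-04-03 ~ 6300 days): at t=181 (exposed D1's event) all four are
  # at risk; at t=729 (unexposed D3's event) D2, D3, D4 remain at risk
  x <- c(1, 1, 0, 0)
  logpl <- function(b) {
    (b - log(sum(exp(b * x)))) + (0 - log(sum(exp(b * x[2:4]))))
  }
  b_hat <- optimize(logpl, c(-5, 5), maximum = TRUE)$maximum
  expect_equal(log(fit$estimate_ratio), b_hat, tolerance = 1e-4)
  expect_equal(fit$n_events, 2L)
  expect_equal(fit$n_drugs, 4L)
})

test_that("gap-time model errors when no market reaches the target entrant", {
  spec <- data.frame(ingredient = c("D1", "D2"), class = "C1",
                     nda = "1990-01-01",
                     generics = c("2000-01-01;2001-01-01",
                                  "2000-01-01;2002-01-01"),
                     mono_date = c("", "1999-01-01"),
                     stringsAsFactors = FALSE)
  m <- toy_markets(spec)
  expect_error(fit_gap_time(m, 2L, 3L, adjusted = FALSE),
               class = "genentry_fit_error")
})

test_that("KM median follows the first-crossing rule and handles censoring", {
  km <- km_summary(1:100, rep(1, 100))
  expect_equal(km$median, 50)          # S(50) = 0.5 -> first crossing at 50
  expect_true(km$ci_low <= 50 && km$ci_high >= 50)
  expect_equal(nrow(km$curve), 100L)
  expect_true(all(diff(km$curve$surv) < 0))

  cens <- km_summary(c(5, 8, 13), c(0, 0, 0))
  expect_true(is.na(cens$median))      # not reached

  one <- km_summary(5, 1)              # degenerate single-event input
  expect_equal(one$median, 5)
})

test_that("crude and adjusted fits coincide when every covariate is constant", {
  sim <- simulate_cohort(simulation_config(n_drugs = 300L, n_classes = 10L,
                                           seed = 77L))
  asm <- assemble_cohort(sim$products, sim$monographs, sim$sales)
  m <- asm$markets
  # freeze all adjustment covariates
  m$substance_monograph_date <- as.Date("1990-01-01")
  m$market_size_usd <- 1e7
  m$age_years <- 10
  m$vintage <- 1L
  m$route_group <- "oral"
  crude <- fit_count(m, adjusted = FALSE)
  adj <- fit_count(m, adjusted = TRUE)
  expect_equal(adj$estimate_ratio, crude$estimate_ratio, tolerance = 1e-8)
  expect_equal(adj$robust_se_log, crude$robust_se_log, tolerance = 1e-8)
})

test_that("fitted ratios sit inside their own confidence intervals", {
  m <- small_cohort()$markets
  for (f in list(fit_count(m), fit_any_generic(m), fit_gap_time(m),
                 fit_count(m, adjusted = FALSE))) {
    expect_true(f$ci_low <= f$estimate_ratio &&
                  f$estimate_ratio <= f$ci_high)
    expect_gt(f$ci_low, 0)
    expect_lte(f$n_clusters, f$n_drugs)
  }
})

test_that("null exposure effects are estimated near zero with honest coverage", {
  # light replicate check at small n; the full-scale recovery study lives in
  # the acceptance suite
  cfg <- simulation_config(n_drugs = 250L, n_classes = 10L,
                           true_irr_count = 1, true_or_any_generic = 1,
                           true_hr_gap23 = 1)
  res <- recovery_study(n_reps = 12L, seed = 301L, config = cfg)
  for (est in c("count", "any_generic", "gap23")) {
    s <- recovery_summary(res, truth = 1, estimand = est)
    expect_lt(abs(s$bias_log), 0.25, label = est)
    expect_gte(s$coverage, 0.7)
  }
})

test_that("the main-results table carries crude and adjusted rows per estimand", {
  m <- small_cohort()$markets
  t2 <- fit_main_table(m)
  expect_equal(nrow(t2), 6L)
  expect_setequal(unique(t2$estimand),
                  c("any_generic_OR", "gap23_HR", "count_IRR"))
  expect_true(all(t2$ci_low <= t2$estimate & t2$estimate <= t2$ci_high))
})
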