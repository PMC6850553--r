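test_that("the generator is byte-deterministic in its seed", {
  cfg <- simulation_config(n_drugs = 150L, n_classes = 8L, seed = 13L)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$products, s2$products)
  expect_identical(s1$monographs, s2$monographs)
  expect_identical(s1$sales, s2$sales)
  s3 <- simulate_cohort(simulation_config(n_drugs = 150L, n_classes = 8L,
                                          seed = 14L))
  expect_false(identical(s1$products, s3$products))
})

test_that("generator marginals match the configuration at n = 10000", {
  cfg <- simulation_config(n_drugs = 10000L, n_classes = 30L, seed = 99L)
  sim <- simulate_cohort(cfg)
  tr <- sim$truth
  expect_lt(abs(mean(tr$mono) - 0.403), 0.02)
  expect_lt(abs(mean(tr$substance) - 0.749), 0.02)
  expect_lt(abs(mean(tr$early[tr$mono]) - 0.51), 0.03)
  route_mix <- prop.table(table(tr$route))
  expect_lt(abs(route_mix[["oral"]] - 553 / 982), 0.02)
  expect_lt(abs(route_mix[["intravenous"]] - 183 / 982), 0.02)
  expect_lt(abs(route_mix[["inhalation"]] - 31 / 982), 0.01)
})

test_that("the mean entrant count matches the generative mean structure", {
  cfg <- simulation_config(n_drugs = 10000L, n_classes = 30L, seed = 101L)
  sim <- simulate_cohort(cfg)
  asm <- assemble_cohort(sim$products, sim$monographs, sim$sales)
  # chain construction: E[N] equals mu drug by drug, so the cohort means
  # must agree up to Monte-Carlo error
  expect_lt(abs(mean(asm$markets$n_generics) - mean(sim$truth$mu_count)) /
              mean(sim$truth$mu_count), 0.06)
})

test_that("a covariate-free generator reproduces the crude mean-count ratio", {
  # exposed/unexposed crude ratio targets 7.2 / 1.7 when no covariates or
  # clustering distort the margins
  cfg <- simulation_config(n_drugs = 12000L, n_classes = 30L,
                           class_effect_sd = 0,
                           true_irr_count = 7.2 / 1.7,
                           covariate_effects = c(substance = 0, size = 0,
                                                 age = 0, vintage = 0,
                                                 route = 0),
                           seed = 103L)
  sim <- simulate_cohort(cfg)
  asm <- assemble_cohort(sim$products, sim$monographs, sim$sales)
  m <- asm$markets
  ex <- compute_exposure(m, "before_first")
  ratio <- mean(m$n_generics[ex]) / mean(m$n_generics[!ex])
  expect_lt(abs(log(ratio) - log(7.2 / 1.7)), 0.12)
})

test_that("realized exposure equals the generative exposure at every timing", {
  for (timing in c("before_first", "before_second")) {
    cfg <- simulation_config(n_drugs = 1500L, n_classes = 15L,
                             exposure_timing = timing, seed = 107L)
    sim <- simulate_cohort(cfg)
    asm <- assemble_cohort(sim$products, sim$monographs, sim$sales)
    m <- asm$markets
    idx <- match(m$ingredient_norm,
                 sprintf("DRUG%04d", seq_len(cfg$n_drugs)))
    expect_equal(as.numeric(compute_exposure(m, timing)),
                 sim$truth$exposure[idx])
    # the second-entrant exposure indicator used by the gap-time hazard:
    # must match the generative indicator on every market at risk in that
    # model (those that reached a second entrant)
    at_risk <- m$n_generics >= 2
    expect_equal(as.numeric(compute_exposure(m, "before_second"))[at_risk],
                 sim$truth$z2[idx][at_risk])
  }
})

test_that("every generated market survives the default eligibility cascade", {
  ch <- small_cohort()
  expect_true(all(ch$ledger$n_removed == 0L))
  expect_equal(nrow(ch$markets), 600L)
  expect_false(any(ch$markets$market_size_flag))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(monograph_product_prev = 1.4),
               class = "genentry_config_error")
  expect_error(simulation_config(true_irr_count = -1),
               class = "genentry_config_error")
  expect_error(simulation_config(censor_date = "1981-01-01"),
               class = "genentry_config_error")
  expect_error(simulation_config(exposure_timing = "sometime"),
               class = "genentry_config_error")
})

test_that("attrition fixture handles the empty plan", {
  fx <- make_attrition_fixture(plan = c())
  expect_equal(nrow(fx$products), 0L)
  expect_error(make_attrition_fixture(c(bogus_filter = 2)),
               class = "genentry_config_error")
})

test_that("written cohorts read back through the ingest layer unchanged", {
  sim <- small_cohort()$sim
  dir <- tempfile()
  paths <- write_cohort(sim, dir)
  p <- read_products(paths[["products"]], "csv")
  expect_equal(nrow(p) + nrow(rejects(p)), nrow(sim$products))
  expect_equal(nrow(rejects(p)), 0L)
  s <- read_sales(paths[["sales"]])
  expect_equal(nrow(s), nrow(sim$sales))
  mafter <- read_monographs(paths[["monographs"]])
  expect_equal(nrow(mafter), nrow(sim$monographs))
  expect_true(file.exists(paths[["truth"]]))
})
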