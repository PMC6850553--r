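toy_curve <- function() price_curve(c(0, 1, 2), c(1, 0.8, 0.5))

test_that("price curve validation enforces the invariants", {
  expect_s3_class(toy_curve(), "price_curve")
  expect_error(price_curve(c(1, 2), c(0.8, 0.5)),
               class = "genentry_validation_error")   # must start at 0
  expect_error(price_curve(c(0, 1), c(1, 1.2)),
               class = "genentry_validation_error")   # price > 1
  expect_error(price_curve(c(0, 1, 1), c(1, 0.8, 0.7)),
               class = "genentry_validation_error")   # non-increasing n
  expect_error(price_curve(c(0, 1, 2), c(1, 0.5, 0.8)),
               class = "genentry_validation_error")   # price increases
})

test_that("relative price interpolates linearly and extrapolates flat", {
  cv <- toy_curve()
  expect_equal(relative_price(cv, 0), 1.0)
  expect_equal(relative_price(cv, 1.5), 0.65)
  expect_equal(relative_price(cv, 7), 0.5)
  expect_equal(relative_price(cv, c(0.5, 2)), c(0.9, 0.5))
})

test_that("counterfactual manufacturer count divides out the rate ratio", {
  expect_equal(predict_manufacturers(3, 1.5), 2.0)
  expect_equal(predict_manufacturers(0:5, 1), 0:5)
  expect_equal(predict_manufacturers(0, 42), 0)
  expect_error(predict_manufacturers(3, 0),
               class = "genentry_validation_error")
  expect_error(predict_manufacturers(3, -1),
               class = "genentry_validation_error")
})

test_that("predicted price follows the curve ratio", {
  cv <- toy_curve()
  expect_equal(predicted_price(10, cv, 2, 1), 16.0)
  expect_equal(predicted_price(10, cv, 2, 2), 10.0)
  flat <- price_curve(c(0, 5), c(1, 1))
  expect_equal(predicted_price(c(3, 9), flat, c(4, 1), c(0.5, 0)), c(3, 9))
})

savings_fixture <- function() {
  spec <- data.frame(
    ingredient = c("D1", "D2"),
    class = "C1", nda = "1990-01-01",
    generics = c("2003-01-01;2005-01-01", "2003-01-01"),
    mono_date = c("2001-06-01", ""),     # only D1 exposed
    stringsAsFactors = FALSE)
  m <- toy_markets(spec)
  sales <- data.frame(
    ingredient = c("D1", "D1", "D2"), route = "ORAL",
    year = c(2015L, 2016L, 2015L),
    dollars = c(10 * 1000, 12 * 500, 999),
    volume = c(1000, 500, 10), stringsAsFactors = FALSE)
  list(markets = m, sales = sales)
}

test_that("the one-drug counterfactual chain matches hand arithmetic", {
  fx <- savings_fixture()
  out <- compute_savings(fx$markets, fx$sales, irr = 2, curve = toy_curve(),
                         years = 2015L)
  # exposed drug D1: n_actual 2, n_pred 1, P_A 10, P_P (0.8/0.5)*10 = 16,
  # volume 1000 -> savings (16-10)*1000 = 6000; unexposed D2 contributes 0
  expect_equal(nrow(out$rows), 1L)
  expect_equal(out$rows$n_predicted, 1)
  expect_equal(out$rows$price_predicted, 16)
  expect_equal(out$rows$savings, 6000)
  expect_equal(out$totals$total_savings, 6000)
  expect_equal(out$totals$additional_manufacturers, 1)
})

test_that("unit rate ratio implies zero savings everywhere", {
  fx <- savings_fixture()
  out <- compute_savings(fx$markets, fx$sales, irr = 1, curve = toy_curve(),
                         years = c(2015L, 2016L))
  expect_true(all(out$rows$savings == 0))
  expect_true(all(out$totals$total_savings == 0))
  expect_true(all(out$rows$n_predicted == out$rows$n_actual))
})

test_that("savings are nonnegative and monotone in the rate ratio", {
  fx <- savings_fixture()
  irrs <- c(1, 1.2, 1.53, 2, 3.5)
  tot <- vapply(irrs, function(r) {
    sum(compute_savings(fx$markets, fx$sales, r, toy_curve(),
                        years = c(2015L, 2016L))$totals$total_savings)
  }, 0)
  expect_true(all(tot >= 0))
  expect_true(all(diff(tot) > 0))
})

test_that("a straight-line recomputation reproduces the engine on small inputs", {
  m <- small_cohort()$markets
  sales <- small_cohort()$sim$sales
  cv <- default_price_curve()
  irr <- 1.53
  out <- compute_savings(m, sales, irr, cv, years = 2016L)
  expect_gt(nrow(out$rows), 3)
  take <- head(seq_len(nrow(out$rows)), 5)
  for (i in take) {
    r <- out$rows[i, ]
    p_a <- r$sales_actual / r$volume_actual
    n_p <- r$n_actual / irr
    p_p <- relative_price(cv, n_p) / relative_price(cv, r$n_actual) * p_a
    s_i <- p_p * r$volume_actual - r$sales_actual
    expect_equal(r$savings, s_i, tolerance = 1e-9)
  }
  # totals are the plain sums of the rows
  expect_equal(out$totals$total_savings, sum(out$rows$savings))
  expect_equal(out$totals$additional_manufacturers,
               round(sum(out$rows$n_actual - out$rows$n_predicted)))
})

test_that("zero-volume rows with dollars are flagged and skipped", {
  fx <- savings_fixture()
  fx$sales$volume[1] <- 0
  out <- compute_savings(fx$markets, fx$sales, irr = 2, curve = toy_curve(),
                         years = c(2015L, 2016L))
  expect_false(2015L %in% out$rows$year)
  expect_equal(out$flagged$year, 2015L)
  expect_match(out$flagged$reason, "zero volume")
})

test_that("savings totals are additive over disjoint market sets", {
  m <- small_cohort()$markets
  sales <- small_cohort()$sim$sales
  cv <- default_price_curve()
  full <- compute_savings(m, sales, 1.6, cv, years = 2016L)
  half <- nrow(m) %/% 2
  s1 <- compute_savings(genentry:::subset_markets(m, seq_len(nrow(m)) <= half),
                        sales, 1.6, cv, years = 2016L)
  s2 <- compute_savings(genentry:::subset_markets(m, seq_len(nrow(m)) > half),
                        sales, 1.6, cv, years = 2016L)
  expect_equal(s1$totals$total_savings + s2$totals$total_savings,
               full$totals$total_savings, tolerance = 1e-8)
})
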