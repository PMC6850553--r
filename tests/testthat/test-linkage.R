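test_that("market keys are canonical and idempotent", {
  k <- normalize_key("Furosemide ", "intravenous")
  expect_equal(k$ingredient_norm, "FUROSEMIDE")
  expect_equal(k$route_norm, "INTRAVENOUS")
  expect_equal(normalize_key("A  B", "ORAL")$ingredient_norm, "A B")
  expect_error(normalize_key("", "ORAL"), class = "genentry_validation_error")

  set.seed(11)
  for (i in 1:20) {
    x <- paste(sample(c(LETTERS, letters, " ", "  "), 12, TRUE),
               collapse = "")
    if (trimws(x) == "") next
    k1 <- normalize_key(x, "oral route")
    k2 <- normalize_key(k1$ingredient_norm, k1$route_norm)
    expect_identical(k1, k2)
  }
})

test_that("product monographs match on ingredient+route, substance on ingredient", {
  mk <- data.frame(ingredient_norm = c("DRUGA", "DRUGA", "DRUGB"),
                   route_norm = c("ORAL", "TOPICAL", "ORAL"),
                   stringsAsFactors = FALSE)
  mono <- data.frame(
    ingredient = c("DRUGA", "DRUGA", "DRUGC"),
    route = c("ORAL", "", ""),
    monograph_type = c("product", "substance", "substance"),
    official_date = c("2005-01-01", "2001-06-01", "2000-01-01"),
    stringsAsFactors = FALSE)
  out <- attach_monographs(mk, mono)
  expect_equal(out$product_monograph_date,
               as.Date(c("2005-01-01", NA, NA)))
  # substance monograph reaches both DRUGA markets regardless of route
  expect_equal(out$substance_monograph_date,
               as.Date(c("2001-06-01", "2001-06-01", NA)))
  expect_equal(attr(out, "unmatched_monographs")$ingredient, "DRUGC")

  none <- attach_monographs(mk, mono[0, ])
  expect_true(all(is.na(none$product_monograph_date)))
  expect_true(all(is.na(none$substance_monograph_date)))
})

test_that("earliest official date wins on multiple matches", {
  mk <- data.frame(ingredient_norm = "DRUGA", route_norm = "ORAL",
                   stringsAsFactors = FALSE)
  mono <- data.frame(ingredient = "DRUGA", route = "ORAL",
                     monograph_type = "product",
                     official_date = c("2010-01-01", "2003-03-03"),
                     stringsAsFactors = FALSE)
  out <- attach_monographs(mk, mono)
  expect_equal(out$product_monograph_date, as.Date("2003-03-03"))
})

test_that("eligibility cascade reproduces a planted plan with telescoping ledger", {
  plan <- c(pre_1982 = 3, no_sales_match = 2, otc_or_discontinued = 1,
            eligible = 4)
  fx <- make_attrition_fixture(plan)
  asm <- assemble_cohort(fx$products, fx$monographs, fx$sales)
  led <- asm$ledger
  expect_equal(led$n_removed[led$filter_name == "pre_1982"], 3L)
  expect_equal(led$n_removed[led$filter_name == "no_sales_match"], 2L)
  expect_equal(led$n_removed[led$filter_name == "otc_or_discontinued"], 1L)
  expect_equal(sum(led$n_removed), 6L)
  expect_equal(tail(led$n_remaining, 1), 4L)
  expect_equal(nrow(asm$markets), 4L)
  # telescoping: remaining_k = remaining_{k-1} - removed_k
  expect_equal(led$n_remaining,
               nrow(fx$products) / 2 - cumsum(led$n_removed))
})

test_that("overlapping violations are attributed to the first failing filter", {
  plan <- c(pre_1982 = 2, under_patent = 1, no_class = 2, eligible = 3)
  fx <- make_attrition_fixture(plan, overlap = TRUE)  # all violators also OTC
  asm <- assemble_cohort(fx$products, fx$monographs, fx$sales)
  led <- asm$ledger
  expect_equal(led$n_removed[led$filter_name == "pre_1982"], 2L)
  expect_equal(led$n_removed[led$filter_name == "under_patent"], 1L)
  expect_equal(led$n_removed[led$filter_name == "no_class"], 2L)
  expect_equal(led$n_removed[led$filter_name == "otc_or_discontinued"], 0L)
  expect_equal(nrow(asm$markets), 3L)
})

test_that("row order never changes cohort membership or ledger counts", {
  fx <- make_attrition_fixture(c(pre_1982 = 2, pre_loe = 1,
                                 monograph_before_nda = 1, no_sales_match = 2,
                                 eligible = 5))
  asm1 <- assemble_cohort(fx$products, fx$monographs, fx$sales)
  set.seed(5)
  perm <- sample(nrow(fx$products))
  asm2 <- assemble_cohort(fx$products[perm, ], fx$monographs, fx$sales)
  expect_equal(asm1$ledger$n_removed, asm2$ledger$n_removed)
  expect_setequal(asm1$markets$ingredient_norm, asm2$markets$ingredient_norm)
})

test_that("all-eligible input yields an all-zero ledger", {
  fx <- make_attrition_fixture(c(eligible = 6))
  asm <- assemble_cohort(fx$products, fx$monographs, fx$sales)
  expect_true(all(asm$ledger$n_removed == 0L))
  expect_equal(nrow(asm$markets), 6L)
})

test_that("unknown cascade filter is a config error", {
  fx <- make_attrition_fixture(c(eligible = 2))
  expect_error(
    assemble_cohort(fx$products, fx$monographs, fx$sales,
                    cascade_config(order = c("pre_1982", "quality_check"))),
    class = "genentry_config_error")
})
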