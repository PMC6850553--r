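subset_markets <- function(markets, keep) {
  m <- markets[keep, , drop = FALSE]
  attr(m, "timelines") <- attr(markets, "timelines")[keep]
  attr(m, "study_end") <- attr(markets, "study_end")
  class(m) <- class(markets)
  rownames(m) <- NULL
  m
}

safe_fit <- function(expr, label) {
  tryCatch(expr, error = function(e) {
    structure(list(estimand = label, error = conditionMessage(e)),
              class = c("genentry_failed_fit", "genentry_fit"))
  })
}

fit_row <- function(f, label) {
  if (inherits(f, "genentry_failed_fit")) {
    data.frame(analysis = label, estimate = NA_real_, ci_low = NA_real_,
               ci_high = NA_real_, n_drugs = NA_integer_,
               note = f$error, stringsAsFactors = FALSE)
  } else {
    data.frame(analysis = label, estimate = f$estimate_ratio,
               ci_low = f$ci_low, ci_high = f$ci_high,
               n_drugs = f$n_drugs, note = "", stringsAsFactors = FALSE)
  }
}

#' Timing variants of the count model
#'
#' Re-fits the main count model with the exposure defined as a product
#' monograph before the second, and before the third, generic entrant.
#' Because exposure is monotone in timing, the exposed group only grows as
#' the timing loosens.
#'
#' @param markets cohort market table
#' @param adjusted logical
#' @return named list of `genentry_fit`s (`before_second`, `before_third`)
#' @export
run_timing_variants <- function(markets, adjusted = TRUE) {
  list(before_second = safe_fit(
         fit_count(markets, "before_second", adjusted), "count_IRR"),
       before_third = safe_fit(
         fit_count(markets, "before_third", adjusted), "count_IRR"))
}

#' Restrictions on the NDA-to-first-generic interval
#'
#' Drops markets whose first generic arrived within `threshold` years of NDA
#' approval (markets with no generic are always kept) and re-fits the main
#' count model. A threshold of 0 reproduces the main fit.
#'
#' @param markets cohort market table
#' @param thresholds_years numeric vector of year thresholds
#' @param adjusted logical
#' @return named list of `genentry_fit`s
#' @export
run_interval_restrictions <- function(markets, thresholds_years = c(3, 5, 8),
                                      adjusted = TRUE) {
  iv <- as.numeric(markets$first_generic_date - markets$nda_approval_date) /
    365.25
  out <- lapply(thresholds_years, function(th) {
    keep <- is.na(iv) | iv > th
    safe_fit(fit_count(subset_markets(markets, keep), "before_first",
                       adjusted), "count_IRR")
  })
  names(out) <- paste0("gt_", thresholds_years, "y")
  out
}

#' Restrictions on therapeutic-class size
#'
#' Keeps only drugs in classes with strictly fewer than the stated number of
#' members and re-fits the main count model.
#'
#' @param markets cohort market table
#' @param max_class_sizes strict upper bounds on class size
#' @param adjusted logical
#' @return named list of `genentry_fit`s
#' @export
run_class_size_restrictions <- function(markets,
                                        max_class_sizes = c(10, 21, 54),
                                        adjusted = TRUE) {
  sizes <- table(markets$therapeutic_class)
  out <- lapply(max_class_sizes, function(mx) {
    keep <- markets$therapeutic_class %in%
      names(sizes)[sizes < mx]
    safe_fit(fit_count(subset_markets(markets, keep), "before_first",
                       adjusted), "count_IRR")
  })
  names(out) <- paste0("lt_", max_class_sizes)
  out
}

#' Route-stratified count models
#'
#' Re-fits the main count model within each route group, dropping the route
#' covariates (constant within a stratum) but retaining the class-clustered
#' variance. Strata that cannot be fit (too few drugs or classes) are
#' reported as not estimable.
#'
#' @param markets cohort market table
#' @param adjusted logical
#' @return named list of `genentry_fit`s per route group
#' @export
run_route_strata <- function(markets, adjusted = TRUE) {
  out <- lapply(ROUTE_LEVELS, function(rg) {
    keep <- markets$route_group == rg
    if (sum(keep) == 0) {
      return(structure(list(estimand = "count_IRR",
                            error = "empty stratum"),
                       class = c("genentry_failed_fit", "genentry_fit")))
    }
    safe_fit(fit_count(subset_markets(markets, keep), "before_first",
                       adjusted, drop_route = TRUE), "count_IRR")
  })
  names(out) <- ROUTE_LEVELS
  out
}

#' Gap-time model between the first and second generic entrant
#'
#' Secondary analysis: the same Cox specification as the second-to-third
#' model, applied to the first-to-second gap.
#'
#' @param markets cohort market table
#' @param adjusted logical
#' @return a `genentry_fit`
#' @export
run_gap12 <- function(markets, adjusted = TRUE) {
  fit_gap_time(markets, from_k = 1L, to_k = 2L, adjusted = adjusted)
}

#' Assemble the sensitivity-analysis report table
#'
#' @param markets cohort market table
#' @return data.frame mirroring the sensitivity table layout
#' @export
sensitivity_table <- function(markets) {
  tv <- run_timing_variants(markets)
  ir <- run_interval_restrictions(markets)
  cs <- run_class_size_restrictions(markets)
  rs <- run_route_strata(markets)
  rbind(
    fit_row(tv$before_second, "monograph before 2nd generic"),
    fit_row(tv$before_third, "monograph before 3rd generic"),
    fit_row(ir$gt_3y, "first generic >3y after NDA"),
    fit_row(ir$gt_5y, "first generic >5y after NDA"),
    fit_row(ir$gt_8y, "first generic >8y after NDA"),
    fit_row(cs$lt_10, "classes with <10 drugs"),
    fit_row(cs$lt_21, "classes with <21 drugs"),
    fit_row(cs$lt_54, "classes with <54 drugs"),
    fit_row(rs$oral, "oral route"),
    fit_row(rs$intravenous, "intravenous route"),
    fit_row(rs$topical, "topical route"),
    fit_row(rs$other, "other routes"),
    fit_row(rs$inhalation, "inhalation route"))
}
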