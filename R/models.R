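ROUTE_LEVELS <- c("oral", "inhalation", "intravenous", "topical", "other")

new_model_fit <- function(estimand, fit, exposure_name, n_drugs, n_dropped) {
  b <- fit$coefficients[exposure_name]
  # small-cluster correction on top of the raw sandwich: CR1 scaling and a
  # t reference with clusters - 1 degrees of freedom
  g <- fit$n_clusters
  se <- sqrt(fit$vcov[exposure_name, exposure_name]) * sqrt(g / (g - 1))
  z <- stats::qt(0.975, df = g - 1)
  structure(list(
    estimand = estimand,
    estimate_ratio = exp(unname(b)),
    ci_low = exp(unname(b) - z * se),
    ci_high = exp(unname(b) + z * se),
    robust_se_log = unname(se),
    p_value = 2 * stats::pt(-abs(unname(b) / se), df = g - 1),
    n_drugs = n_drugs,
    n_dropped = n_dropped,
    n_clusters = fit$n_clusters,
    covariate_estimates = fit$coefficients,
    alpha = fit$alpha %||% NA_real_,
    family = fit$family %||% "cox"
  ), class = "genentry_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genentry_fit <- function(x, ...) {
  cat(sprintf("<%s>  %0.2f (95%% CI %0.2f-%0.2f)  [n=%d drugs, %d classes]\n",
              x$estimand, x$estimate_ratio, x$ci_low, x$ci_high,
              x$n_drugs, x$n_clusters))
  invisible(x)
}

# Assemble the adjusted-model design matrix. Markets with a missing market
# size are dropped from adjusted fits (and counted); crude fits keep them.
model_frame <- function(markets, exposure, adjusted, drop_route = FALSE) {
  mf <- data.frame(exposure = as.numeric(exposure))
  keep <- rep(TRUE, nrow(markets))
  if (adjusted) {
    mf$substance_monograph <- as.numeric(!is.na(markets$substance_monograph_date))
    mf$log10_market_size <- log10(markets$market_size_usd + 1)
    mf$age_years <- markets$age_years
    mf$vintage <- markets$vintage
    if (!drop_route) {
      rg <- factor(markets$route_group, levels = ROUTE_LEVELS)
      for (lev in ROUTE_LEVELS[-1]) {
        if (sum(rg == lev, na.rm = TRUE) > 0) {
          mf[[paste0("route_", lev)]] <- as.numeric(rg == lev)
        }
      }
    }
    keep <- stats::complete.cases(mf)
  }
  mf <- mf[keep, , drop = FALSE]
  if (nrow(mf) < 2) {
    ge_error("model frame has fewer than 2 usable markets",
             "genentry_fit_error")
  }
  # covariates constant over the fitted rows carry no information and would
  # alias the intercept; exposure itself is kept so degenerate exposure
  # surfaces as a fit error rather than a silent drop
  constant <- vapply(mf, function(col) length(unique(col)) == 1, TRUE)
  constant["exposure"] <- FALSE
  X <- cbind(`(Intercept)` = 1, as.matrix(mf[, !constant, drop = FALSE]))
  list(X = X, keep = keep)
}

#' Monograph association with having at least one generic competitor
#'
#' Marginal logistic model (GEE, exchangeable working correlation across
#' drugs of the same therapeutic class, cluster sandwich variance) of the
#' indicator of at least one generic manufacturer on the exposure "product
#' monograph established before the first generic entrant". Adjusted fits add
#' the substance monograph indicator, log10 market size, drug age, vintage
#' and route group.
#'
#' @param markets cohort market table (with exposure covariates computed)
#' @param adjusted logical
#' @param corstr working correlation
#' @return a `genentry_fit` with the odds ratio and 95% Wald CI
#' @export
fit_any_generic <- function(markets, adjusted = TRUE,
                            corstr = "exchangeable") {
  y <- as.numeric(markets$n_generics >= 1)
  expo <- compute_exposure(markets, "before_first")
  fr <- model_frame(markets, expo, adjusted)
  fit <- gee_fit(fr$X, y[fr$keep], markets$therapeutic_class[fr$keep],
                 family = "binomial", corstr = corstr)
  new_model_fit("any_generic_OR", fit, "exposure",
                sum(fr$keep), sum(!fr$keep))
}

#' Monograph association with the number of generic manufacturers
#'
#' Main analytical model: marginal log-link count model (GEE with Poisson
#' mean-variance working model, exchangeable working correlation within
#' therapeutic class, cluster sandwich variance -- robust to overdispersion)
#' of the number of generic manufacturers on the monograph exposure at the
#' requested timing.
#'
#' @param markets cohort market table
#' @param exposure_timing passed to [compute_exposure()]
#' @param adjusted logical
#' @param corstr working correlation
#' @param drop_route drop the route covariates (used by route-stratified
#'   sensitivity fits)
#' @return a `genentry_fit` with the incidence rate ratio and 95% Wald CI
#' @export
fit_count <- function(markets, exposure_timing = "before_first",
                      adjusted = TRUE, corstr = "exchangeable",
                      drop_route = FALSE) {
  y <- markets$n_generics
  expo <- compute_exposure(markets, exposure_timing)
  fr <- model_frame(markets, expo, adjusted, drop_route = drop_route)
  fit <- gee_fit(fr$X, y[fr$keep], markets$therapeutic_class[fr$keep],
                 family = "poisson", corstr = corstr)
  mf <- new_model_fit("count_IRR", fit, "exposure", sum(fr$keep), sum(!fr$keep))
  mf$exposure_timing <- exposure_timing
  mf
}

#' Gap-time Cox model between successive generic entrants
#'
#' Restricted to markets with at least `from_k` generic entrants, models the
#' time from the `from_k`-th to the `to_k`-th generic approval; markets where
#' the `to_k`-th entrant had not appeared by the end of the study are
#' administratively censored at that date. The exposure is a product
#' monograph established before the `from_k`-th entrant. Fitted by Cox
#' partial likelihood with Efron tie handling and a cluster-robust
#' (therapeutic class) variance.
#'
#' @param markets cohort market table
#' @param from_k,to_k entrant indices (default second to third)
#' @param adjusted logical
#' @return a `genentry_fit` with the hazard ratio and 95% CI
#' @export
fit_gap_time <- function(markets, from_k = 2L, to_k = 3L, adjusted = TRUE) {
  stopifnot(to_k == from_k + 1L)
  study_end <- attr(markets, "study_end") %||% STUDY_END_DEFAULT
  at_risk <- markets$n_generics >= from_k
  m <- markets[at_risk, , drop = FALSE]
  attr(m, "timelines") <- attr(markets, "timelines")[at_risk]
  attr(m, "study_end") <- study_end
  d_from <- generic_date(m, from_k)
  d_to <- generic_date(m, to_k)
  event <- !is.na(d_to)
  time <- ifelse(event, as.numeric(d_to - d_from),
                 as.numeric(study_end - d_from))
  time <- pmax(time, 0.5)   # same-day approvals: half-day gap to keep t > 0
  if (!any(event)) {
    ge_error("fit_gap_time: no events (no market reached the target entrant)",
             "genentry_fit_error")
  }
  timing <- c("before_first", "before_second", "before_third")[from_k]
  expo <- compute_exposure(m, timing)
  fr <- model_frame(m, expo, adjusted)
  dat <- as.data.frame(fr$X[, -1, drop = FALSE])
  dat$time <- time[fr$keep]
  dat$event <- as.numeric(event[fr$keep])
  dat$class <- m$therapeutic_class[fr$keep]
  rhs <- paste(setdiff(names(dat), c("time", "event", "class")),
               collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs,
                                 "+ cluster(class)"))
  cx <- survival::coxph(fml, data = dat, ties = "efron")
  fit <- list(coefficients = stats::coef(cx), vcov = stats::vcov(cx),
              n_clusters = length(unique(dat$class)), family = "cox",
              alpha = NA_real_)
  mf <- new_model_fit(if (from_k == 1L) "gap12_HR" else "gap23_HR",
                      fit, "exposure", sum(fr$keep), sum(!fr$keep))
  mf$n_events <- sum(dat$event)
  mf
}

#' Kaplan-Meier summary of gap times
#'
#' Product-limit estimator with log-log confidence intervals. The median is
#' the first time at which the survival curve drops to or below 0.5; its CI
#' is where the survival confidence band crosses 0.5. When the curve never
#' reaches 0.5 (heavy censoring) the median is reported as NA ("not
#' reached").
#'
#' @param times nonnegative gap times
#' @param event_flags 1 = event observed, 0 = censored
#' @return list with `median`, `ci_low`, `ci_high` and `curve`
#'   (data.frame time, surv, lower, upper)
#' @export
km_summary <- function(times, event_flags) {
  stopifnot(all(times >= 0))
  sf <- survival::survfit(survival::Surv(times, event_flags) ~ 1,
                          conf.type = "log-log")
  first_at_or_below <- function(surv, t) {
    hit <- which(!is.na(surv) & surv <= 0.5)
    if (length(hit)) t[hit[1]] else NA_real_
  }
  list(median = first_at_or_below(sf$surv, sf$time),
       ci_low = first_at_or_below(sf$lower, sf$time),
       ci_high = first_at_or_below(sf$upper, sf$time),
       curve = data.frame(time = sf$time, surv = sf$surv,
                          lower = sf$lower, upper = sf$upper))
}

#' Fit the three main estimands, crude and adjusted
#'
#' Convenience wrapper mirroring the main results table: logistic
#' (any-generic), gap-time Cox (second to third entrant) and count model,
#' each crude and adjusted.
#'
#' @param markets cohort market table
#' @return data.frame, one row per fit
#' @export
fit_main_table <- function(markets) {
  fits <- list(
    fit_any_generic(markets, adjusted = FALSE),
    fit_any_generic(markets, adjusted = TRUE),
    fit_gap_time(markets, 2L, 3L, adjusted = FALSE),
    fit_gap_time(markets, 2L, 3L, adjusted = TRUE),
    fit_count(markets, adjusted = FALSE),
    fit_count(markets, adjusted = TRUE))
  data.frame(
    estimand = vapply(fits, function(f) f$estimand, ""),
    adjusted = rep(c(FALSE, TRUE), 3),
    estimate = vapply(fits, function(f) f$estimate_ratio, 0),
    ci_low = vapply(fits, function(f) f$ci_low, 0),
    ci_high = vapply(fits, function(f) f$ci_high, 0),
    robust_se_log = vapply(fits, function(f) f$robust_se_log, 0),
    n_drugs = vapply(fits, function(f) f$n_drugs, 0L),
    n_clusters = vapply(fits, function(f) f$n_clusters, 0L),
    stringsAsFactors = FALSE)
}
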