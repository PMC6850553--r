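#' Competition-to-price curve
#'
#' A mapping from the number of generic manufacturers in a market to the
#' relative unit price (1 = the no-generic price). The curve must start at
#' (0, 1), have strictly increasing manufacturer counts and nonincreasing
#' relative prices in (0, 1]. Between knots the curve is interpolated
#' linearly; beyond the last knot it is constant. The empirical curve is a
#' user-supplied input (estimated elsewhere from claims data); the package
#' ships a clearly labelled synthetic illustrative curve for tests and
#' examples only.
#'
#' @param n_generics nonnegative integer knots
#' @param relative_price relative prices at the knots
#' @return a `price_curve` object
#' @export
price_curve <- function(n_generics, relative_price) {
  n <- as.numeric(n_generics)
  p <- as.numeric(relative_price)
  if (length(n) != length(p) || length(n) < 1 ||
      n[1] != 0 || p[1] != 1 ||
      any(diff(n) <= 0) || any(diff(p) > 0) ||
      any(p <= 0) || any(p > 1) || anyNA(n) || anyNA(p)) {
    ge_error(paste("invalid price curve: knots must start at (0, 1), have",
                   "strictly increasing counts and nonincreasing relative",
                   "prices in (0, 1]"), "genentry_validation_error")
  }
  structure(list(n = n, price = p), class = "price_curve")
}

#' Read a competition-to-price curve from CSV
#'
#' Two columns: `n_generics`, `relative_price`.
#' @param path file path
#' @return a `price_curve`
#' @export
read_price_curve <- function(path) {
  df <- read_delim_table(path, ",")
  require_columns(df, c("n_generics", "relative_price"), path)
  price_curve(as.numeric(df$n_generics), as.numeric(df$relative_price))
}

#' Illustrative synthetic price curve bundled with the package
#'
#' @return a `price_curve`
#' @export
default_price_curve <- function() {
  read_price_curve(system.file("extdata", "price_curve_synthetic.csv",
                               package = "genentry", mustWork = TRUE))
}

#' Relative price at a (possibly fractional) manufacturer count
#'
#' Counterfactual manufacturer counts are continuous, so the curve is
#' evaluated by linear interpolation between knots and constant extrapolation
#' beyond the last knot.
#'
#' @param curve a `price_curve`
#' @param n nonnegative manufacturer counts (real-valued)
#' @return relative prices
#' @export
relative_price <- function(curve, n) {
  stopifnot(inherits(curve, "price_curve"), all(n >= 0))
  stats::approx(curve$n, curve$price, xout = n, rule = 2)$y
}

#' Counterfactual manufacturer count without the monograph effect
#'
#' Removes the multiplicative monograph effect from the observed count:
#' n_predicted = n_actual / IRR. The value is kept continuous (not rounded);
#' rounding is applied only when aggregate manufacturer differences are
#' reported.
#'
#' @param n_actual observed generic manufacturer count(s)
#' @param irr fitted incidence rate ratio (> 0)
#' @return predicted counterfactual count(s)
#' @export
predict_manufacturers <- function(n_actual, irr) {
  if (!is.finite(irr) || irr <= 0) {
    ge_error("predict_manufacturers: irr must be a positive number",
             "genentry_validation_error")
  }
  stopifnot(all(n_actual >= 0))
  n_actual / irr
}

#' Counterfactual price from the competition curve
#'
#' P_predicted = D(n_predicted) / D(n_actual) * P_actual, where D is the
#' relative-price curve. When fewer manufacturers are predicted than observed
#' and the curve is nonincreasing, the predicted price is at least the actual
#' price.
#'
#' @param price_actual observed unit price(s) (> 0)
#' @param curve a `price_curve`
#' @param n_actual,n_predicted manufacturer counts
#' @return predicted unit price(s)
#' @export
predicted_price <- function(price_actual, curve, n_actual, n_predicted) {
  stopifnot(all(price_actual > 0))
  relative_price(curve, n_predicted) / relative_price(curve, n_actual) *
    price_actual
}

#' Counterfactual cost savings attributable to product monographs
#'
#' For each exposed market (product monograph before the first generic
#' entrant, or any monograph when `exposure = "any"`) and each requested
#' year: the observed unit price is dollars/volume; the counterfactual
#' manufacturer count removes the fitted monograph rate ratio
#' ([predict_manufacturers()]); the counterfactual price follows from the
#' competition curve ([predicted_price()]); predicted sales are the
#' counterfactual price times the *observed* volume (volume is held fixed --
#' volume response to price is out of scope); and savings are predicted minus
#' actual sales. Unexposed markets contribute zero and are omitted from the
#' row-level output. Manufacturer counts are evaluated per calendar year
#' (entrants approved by Dec 31 of that year).
#'
#' Rows with zero volume but nonzero dollars are flagged and skipped.
#'
#' @param markets cohort market table (exposure computable)
#' @param sales sales table
#' @param irr fitted incidence rate ratio, or a `genentry_fit` from
#'   [fit_count()]
#' @param curve a `price_curve`
#' @param years calendar years to evaluate
#' @param exposure `"before_first"` (default) or `"any"` (sensitivity)
#' @return list with `rows` (per market-year), `totals` (per year: total
#'   savings, additional manufacturers rounded at the total) and `flagged`
#' @export
compute_savings <- function(markets, sales, irr, curve,
                            years = c(2015L, 2016L),
                            exposure = c("before_first", "any")) {
  exposure <- match.arg(exposure)
  if (inherits(irr, "genentry_fit")) irr <- irr$estimate_ratio
  if (!is.finite(irr) || irr <= 0) {
    ge_error("compute_savings: irr must be positive",
             "genentry_validation_error")
  }
  expo <- if (exposure == "any") compute_exposure(markets, "ever")
          else compute_exposure(markets, "before_first")
  em <- markets[expo, , drop = FALSE]
  tl <- attr(markets, "timelines")[expo]
  s <- as.data.frame(sales)
  skey <- paste(market_id(toupper(trim(s$ingredient)), toupper(trim(s$route))),
                s$year, sep = "\r")

  rows <- list()
  flagged <- list()
  for (yr in years) {
    eoy <- as.Date(sprintf("%d-12-31", yr))
    n_act <- vapply(tl, function(x) sum(x <= eoy), 0L)
    want <- paste(market_id(em$ingredient_norm, em$route_norm), yr, sep = "\r")
    idx <- match(want, skey)
    ok <- !is.na(idx)
    dollars <- s$dollars[idx]
    volume <- s$volume[idx]
    zerovol <- ok & volume == 0
    if (any(zerovol & dollars > 0)) {
      flagged[[length(flagged) + 1]] <- data.frame(
        ingredient_norm = em$ingredient_norm[zerovol & dollars > 0],
        route_norm = em$route_norm[zerovol & dollars > 0], year = yr,
        reason = "zero volume with nonzero dollars",
        stringsAsFactors = FALSE)
    }
    use <- ok & !zerovol
    if (!any(use)) next
    p_act <- dollars[use] / volume[use]
    n_a <- n_act[use]
    n_p <- predict_manufacturers(n_a, irr)
    p_pred <- ifelse(p_act > 0,
                     predicted_price(pmax(p_act, .Machine$double.xmin), curve,
                                     n_a, n_p), 0)
    sales_pred <- p_pred * volume[use]
    rows[[length(rows) + 1]] <- data.frame(
      ingredient_norm = em$ingredient_norm[use],
      route_norm = em$route_norm[use],
      year = yr,
      n_actual = n_a,
      n_predicted = n_p,
      price_actual = p_act,
      price_predicted = p_pred,
      volume_actual = volume[use],
      sales_actual = dollars[use],
      sales_predicted = sales_pred,
      savings = sales_pred - dollars[use],
      stringsAsFactors = FALSE)
  }
  rows <- if (length(rows)) do.call(rbind, rows) else data.frame(
    ingredient_norm = character(), route_norm = character(), year = integer(),
    n_actual = numeric(), n_predicted = numeric(), price_actual = numeric(),
    price_predicted = numeric(), volume_actual = numeric(),
    sales_actual = numeric(), sales_predicted = numeric(),
    savings = numeric(), stringsAsFactors = FALSE)
  totals <- data.frame(
    year = years,
    total_savings = vapply(years, function(yr) {
      sum(rows$savings[rows$year == yr]) }, 0),
    additional_manufacturers = vapply(years, function(yr) {
      round(sum(rows$n_actual[rows$year == yr] -
                  rows$n_predicted[rows$year == yr])) }, 0),
    n_markets = vapply(years, function(yr) sum(rows$year == yr), 0),
    stringsAsFactors = FALSE)
  list(rows = rows, totals = totals,
       flagged = if (length(flagged)) do.call(rbind, flagged) else NULL)
}
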