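# Route margins and per-route monograph prevalences of the cohort the
# generator emulates (982 drugs; route mix and monograph prevalence by route).
ROUTE_MARGINS <- c(oral = 553, intravenous = 183, other = 122, topical = 93,
                   inhalation = 31) / 982
ROUTE_PROD_PREV <- c(oral = 0.486, intravenous = 0.361, other = 0.213,
                     topical = 0.312, inhalation = 0.194)
ROUTE_SUBS_PREV <- c(oral = 0.794, intravenous = 0.596, other = 0.779,
                     topical = 0.785, inhalation = 0.613)

#' Configuration of the synthetic cohort generator
#'
#' Defaults are the study conditions the package is designed around: 982
#' drugs in 30 therapeutic classes; 40.3% drug-product and 74.9%
#' drug-substance monograph prevalence with the route mix of the cohort; 51%
#' of product monographs established before the first generic entrant; an
#' unexposed mean of 1.7 generic manufacturers per drug with negative
#' binomial overdispersion; adjusted-effect truths OR 0.64 (any generic),
#' IRR 1.53 (count), HR 0.99 (second-to-third gap), HR 0.88 (first-to-second
#' gap); exponential inter-entrant gaps with median about 180 days; and
#' administrative censoring on 2018-04-03.
#'
#' @param n_drugs,n_classes cohort dimensions
#' @param class_effect_sd SD of the log-scale shared class frailty in the
#'   count layer (the frailty is mean-1 so marginal rate ratios are
#'   preserved)
#' @param monograph_product_prev,monograph_substance_prev directory
#'   prevalences (route-specific prevalences are scaled proportionally)
#' @param frac_monograph_before_first probability that a product monograph
#'   precedes the exposure-defining entrant
#' @param true_or_any_generic,true_irr_count,true_hr_gap23,true_hr_gap12
#'   generative effect sizes on the ratio scale
#' @param baseline_any_generic_prob unexposed probability of any generic
#' @param baseline_count_mean unexposed marginal mean manufacturer count
#' @param count_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 means Poisson
#' @param gap_time_scale_days mean of the exponential inter-entrant gap at
#'   baseline
#' @param censor_date end of the study window
#' @param exposure_timing which entrant defines the generative exposure
#'   (`"before_first"`, `"before_second"`, `"before_third"`)
#' @param covariate_effects named truth vector (log scale) for the adjusted
#'   covariates
#' @param price_curve competition-to-price curve used for the sales panel
#' @param price_noise_sd lognormal noise SD on post-entry prices and volumes
#' @param panel_years calendar years covered by the sales panel
#' @param seed integer seed; the same seed reproduces the tables byte for
#'   byte
#' @return a `simulation_config` list
#' @export
simulation_config <- function(n_drugs = 982L, n_classes = 30L,
                              class_effect_sd = 0.3,
                              monograph_product_prev = 0.403,
                              monograph_substance_prev = 0.749,
                              frac_monograph_before_first = 0.51,
                              true_or_any_generic = 0.64,
                              true_irr_count = 1.53,
                              true_hr_gap23 = 0.99,
                              true_hr_gap12 = 0.88,
                              baseline_any_generic_prob = 0.65,
                              baseline_count_mean = 1.7,
                              count_dispersion = 0.65,
                              gap_time_scale_days = 260,
                              censor_date = as.Date("2018-04-03"),
                              exposure_timing = "before_first",
                              covariate_effects = c(substance = 0.10,
                                                    size = 0.15,
                                                    age = 0.010,
                                                    vintage = -0.015),
                              price_curve = NULL,
                              price_noise_sd = 0.10,
                              panel_years = 1997:2016,
                              seed = 1L) {
  cfg <- list(n_drugs = as.integer(n_drugs), n_classes = as.integer(n_classes),
              class_effect_sd = class_effect_sd,
              monograph_product_prev = monograph_product_prev,
              monograph_substance_prev = monograph_substance_prev,
              frac_monograph_before_first = frac_monograph_before_first,
              true_or_any_generic = true_or_any_generic,
              true_irr_count = true_irr_count,
              true_hr_gap23 = true_hr_gap23, true_hr_gap12 = true_hr_gap12,
              baseline_any_generic_prob = baseline_any_generic_prob,
              baseline_count_mean = baseline_count_mean,
              count_dispersion = count_dispersion,
              gap_time_scale_days = gap_time_scale_days,
              censor_date = as.Date(censor_date),
              exposure_timing = exposure_timing,
              covariate_effects = covariate_effects,
              price_curve = price_curve,
              price_noise_sd = price_noise_sd,
              panel_years = as.integer(panel_years),
              seed = as.integer(seed))
  probs <- c(cfg$monograph_product_prev, cfg$monograph_substance_prev,
             cfg$frac_monograph_before_first)
  if (any(probs < 0 | probs > 1) || cfg$class_effect_sd < 0 ||
      cfg$count_dispersion < 0 || cfg$gap_time_scale_days <= 0 ||
      any(c(cfg$true_or_any_generic, cfg$true_irr_count, cfg$true_hr_gap23,
            cfg$true_hr_gap12, cfg$baseline_count_mean) <= 0) ||
      !cfg$exposure_timing %in% c("before_first", "before_second",
                                  "before_third")) {
    ge_error("invalid simulation config", "genentry_config_error")
  }
  if (cfg$censor_date <= as.Date("1983-01-01")) {
    ge_error("censor date precedes every possible approval date",
             "genentry_config_error")
  }
  class(cfg) <- "simulation_config"
  cfg
}

runif_date <- function(n, from, to) {
  from <- as.numeric(as.Date(from))
  to <- as.numeric(as.Date(to))
  as.Date(from + floor(runif(n) * pmax(to - from, 1)), origin = "1970-01-01")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Emits the three input tables the ingest module reads (a product approval
#' table in the CSV dialect, a monograph directory, a drug-year sales panel)
#' together with a truth record holding every generating parameter and
#' per-drug latent quantities.
#'
#' Generative structure, in order: drugs are assigned to therapeutic classes
#' and routes; approval dates are uniform 1982--2015; pre-entry annual
#' revenue is lognormal with a class-level shift (so covariates, and through
#' them all outcome layers, are correlated within class); product and
#' substance monograph indicators are drawn with route-specific prevalences;
#' the exposure indicator (monograph before the k-th entrant) is drawn
#' up-front; the any-generic indicator follows a logistic model with the
#' exposure log-odds truth; entrants then arrive as a chain -- first entrant
#' uniform in the post-1998 window, second entrant a Bernoulli with a
#' truncated-exponential gap, third entrant after an exponential
#' proportional-hazards gap with the HR truth (administratively censored at
#' the study end), and later entrants a negative-binomial count whose
#' conditional mean is solved analytically so that the unconditional mean
#' number of entrants equals the log-linear count truth (times a mean-1
#' class frailty). Both the OR, the IRR and the gap-time HR truths therefore
#' hold exactly in the same cohort. Finally the monograph official date is
#' placed in the date interval that realizes the drawn exposure exactly
#' (monographs "destined" to appear after the study window get a
#' post-window official date, as in a directory snapshot taken later than
#' the study). Unit prices in the sales panel decline along the
#' competition-to-price curve as entrants accumulate; pre-entry revenue is
#' noise-free so the market-size covariate recomputed by the pipeline equals
#' the generative one.
#'
#' @param config a [simulation_config()]
#' @return list with `products`, `monographs`, `sales` (data.frames in the
#'   ingest schemas) and `truth`
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_drugs
  censor <- config$censor_date
  curve <- config$price_curve
  if (is.null(curve)) curve <- default_price_curve()

  class_id <- sprintf("C%02d", sample.int(config$n_classes, n, replace = TRUE))
  route <- sample(names(ROUTE_MARGINS), n, replace = TRUE,
                  prob = ROUTE_MARGINS)
  nda_date <- runif_date(n, "1982-01-01", "2015-12-31")
  age <- as.numeric(censor - nda_date) / 365.25

  # vintage as the pipeline will compute it (competition ranking within class)
  vintage <- stats::ave(as.numeric(nda_date), class_id,
                        FUN = function(d) rank(d, ties.method = "min"))

  class_size_shift <- stats::rnorm(config$n_classes, 0, 0.35)
  names(class_size_shift) <- sprintf("C%02d", seq_len(config$n_classes))
  log10_rev <- stats::rnorm(n, 7.3 + class_size_shift[class_id], 0.8)
  revenue <- round(10^log10_rev, 2)
  x_size <- log10(revenue + 1)

  subs <- runif(n) < pmin(1, ROUTE_SUBS_PREV[route] *
                            config$monograph_substance_prev / 0.749)
  mono <- runif(n) < pmin(1, ROUTE_PROD_PREV[route] *
                            config$monograph_product_prev / 0.403)
  early <- runif(n) < config$frac_monograph_before_first
  k <- switch(config$exposure_timing, before_first = 1L, before_second = 2L,
              before_third = 3L)
  X <- as.numeric(mono & early)

  # monograph placement bucket relative to entrant indices: bucket b means
  # "after the b-th and before the (b+1)-th entrant" (0 = before the first)
  bucket <- ifelse(early, sample.int(k, n, replace = TRUE) - 1L,
                   k - 1L + sample.int(3L, n, replace = TRUE))
  z1 <- as.numeric(mono & bucket < 1L)
  z2 <- as.numeric(mono & bucket < 2L)

  eff <- config$covariate_effects
  route_scale <- if ("route" %in% names(eff)) eff[["route"]] else 1
  route_eff <- route_scale * c(oral = 0.10, inhalation = -0.10,
                               intravenous = -0.05, topical = 0, other = 0)
  eta_cov <- eff[["substance"]] * subs + eff[["size"]] * x_size +
    eff[["age"]] * age + eff[["vintage"]] * vintage + route_eff[route]
  eta_cov <- unname(eta_cov - mean(eta_cov))

  p_any <- plogis(qlogis(config$baseline_any_generic_prob) +
                    log(config$true_or_any_generic) * X + eta_cov)
  any_gen <- runif(n) < p_any

  frailty <- stats::rnorm(config$n_classes, -config$class_effect_sd^2 / 2,
                          config$class_effect_sd)
  names(frailty) <- names(class_size_shift)
  mu <- config$baseline_count_mean *
    exp(log(config$true_irr_count) * X + eta_cov +
          unname(frailty[class_id]))
  size <- if (config$count_dispersion > 1e-10) 1 / config$count_dispersion
          else Inf

  # Entrant chain, built so each fitted model is exactly correctly
  # specified: the first entrant exists iff the logistic gate fired; the
  # second entrant is a Bernoulli; the third entrant arrives after an
  # exponential proportional-hazards gap (so its only censoring is
  # administrative); later entrants are a count draw whose conditional mean
  # is solved so the unconditional mean number of entrants equals the
  # log-linear count truth mu.
  hcov <- 0.5 * eta_cov
  scale_d <- config$gap_time_scale_days
  lam12 <- config$true_hr_gap12^z1 * exp(hcov) / scale_d
  lam23 <- config$true_hr_gap23^z2 * exp(hcov) / scale_d
  cens <- as.numeric(censor)
  win_lo <- pmax(as.numeric(nda_date) + 365, as.numeric(as.Date("1998-01-02")))
  win_hi <- pmin(cens, as.numeric(as.Date("2017-12-31")))
  d1 <- win_lo + floor(runif(n) * pmax(0.7 * (win_hi - win_lo), 1))
  # first-to-second gap: exponential truncated to half the remaining window,
  # so the second entrant never spills past the study end (the chain's mean
  # balance needs a guaranteed margin for the third entrant)
  cap12 <- 0.5 * (cens - d1)
  u12 <- runif(n)
  gap12 <- 1 + floor(-log(1 - u12 * (1 - exp(-lam12 * cap12))) / lam12)
  d2 <- d1 + gap12
  margin3 <- cens - d2
  q3 <- 1 - exp(-lam23 * (margin3 + 1))   # event = floor(gap23) <= margin3
  S <- mu / p_any - 1
  q2 <- ifelse(S > 0, pmin(0.85, S / (1.3 + q3)), 0)
  m_extra <- ifelse(q2 > 0, (S / q2 - 1 - q3) / q3, 0)
  n_balance_deficit <- sum(any_gen & S <= 0)

  e2 <- any_gen & runif(n) < q2
  gap23 <- pmax(1, floor(rexp(n, rate = lam23)))
  d3 <- d2 + gap23
  third <- e2 & d3 <= cens
  M <- integer(n)
  if (any(third)) {
    M[third] <- if (is.finite(size)) {
      stats::rnbinom(sum(third), size = size, mu = m_extra[third])
    } else {
      stats::rpois(sum(third), m_extra[third])
    }
  }
  timelines <- vector("list", n)
  for (i in seq_len(n)) {
    if (!any_gen[i]) { timelines[[i]] <- numeric(0); next }
    tl <- d1[i]
    if (e2[i]) {
      tl <- c(tl, d2[i])
      if (third[i]) {
        tl <- c(tl, d3[i])
        if (M[i] > 0L) {
          u <- runif(M[i])
          tl <- c(tl, sort(d3[i] + floor(u * (cens - d3[i] + 1))))
        }
      }
    }
    timelines[[i]] <- tl
  }
  n_obs <- vapply(timelines, length, 0L)
  N <- n_obs

  # monograph official date realizing the drawn bucket against the observed
  # timeline; buckets beyond the last observed entrant go past the window
  boundary <- function(i, j) {
    if (j == 0L) return(as.numeric(nda_date[i]))
    if (j <= n_obs[i]) return(timelines[[i]][j])
    cens
  }
  mono_date <- rep(NA_real_, n)
  u_mono <- runif(n)
  for (i in which(mono)) {
    b <- bucket[i]
    if (b > n_obs[i]) {
      if (b < k) {
        # exposed bucket referencing entrants that never materialized: any
        # official date after the last entrant but inside the window still
        # realizes the timing-k exposure (cutoff falls back to the study end)
        lo <- boundary(i, n_obs[i])
        mono_date[i] <- lo + floor(u_mono[i] * max(cens - lo, 1))
      } else {
        mono_date[i] <- cens + 1 + floor(u_mono[i] * 365)
      }
    } else {
      lo <- boundary(i, b)
      hi <- boundary(i, b + 1L)
      mono_date[i] <- lo + floor(u_mono[i] * max(hi - lo, 1))
    }
  }
  subs_date <- rep(NA_real_, n)
  subs_date[subs] <- as.numeric(runif_date(sum(subs),
                                           "1980-01-01", censor - 30))

  # loss of exclusivity for markets that never saw a generic; kept inside
  # the post-1998, pre-panel-end window so the market-size reference year
  # always exists in the panel
  loe <- rep(NA_real_, n)
  no_gen <- N == 0L
  loe[no_gen] <- pmin(pmax(as.numeric(nda_date[no_gen]) + 12 * 365,
                           as.numeric(as.Date("1998-01-02"))),
                      as.numeric(as.Date(sprintf("%d-12-31",
                                                 max(config$panel_years)))))

  ingredient <- sprintf("DRUG%04d", seq_len(n))
  route_str <- toupper(route)
  iso <- function(x) format(as.Date(x, origin = "1970-01-01"), "%Y-%m-%d")

  prod_rows <- data.frame(
    ingredient = ingredient, route = route_str,
    dosage_form = "FORM", trade_name = paste0("BRAND-", ingredient),
    applicant = "ORIGINATOR", application_type = "NDA",
    application_number = sprintf("N%06d", seq_len(n)),
    approval_date = iso(nda_date),
    otc_flag = "FALSE", discontinued_flag = "FALSE",
    therapeutic_class = class_id, loe_date = ifelse(is.na(loe), "", iso(loe)),
    patent_flag = "FALSE", stringsAsFactors = FALSE)
  anda_rows <- do.call(rbind, lapply(which(n_obs > 0L), function(i) {
    data.frame(
      ingredient = ingredient[i], route = route_str[i],
      dosage_form = "FORM", trade_name = "",
      applicant = sprintf("GEN-%04d-%02d", i, seq_len(n_obs[i])),
      application_type = "ANDA",
      application_number = sprintf("A%04d%02d", i, seq_len(n_obs[i])),
      approval_date = iso(timelines[[i]]),
      otc_flag = "FALSE", discontinued_flag = "FALSE",
      therapeutic_class = class_id[i], loe_date = "", patent_flag = "FALSE",
      stringsAsFactors = FALSE)
  }))
  products <- rbind(prod_rows, anda_rows)

  monographs <- rbind(
    if (any(mono)) data.frame(ingredient = ingredient[mono],
                              route = route_str[mono],
                              monograph_type = "product",
                              official_date = iso(mono_date[mono]),
                              stringsAsFactors = FALSE),
    if (any(subs)) data.frame(ingredient = ingredient[subs],
                              route = "",
                              monograph_type = "substance",
                              official_date = iso(subs_date[subs]),
                              stringsAsFactors = FALSE))

  # sales panel: deterministic pre-entry revenue; post-entry prices decline
  # along the competition curve with lognormal noise, volume held near base
  log10_vol <- stats::rnorm(n, 5.2, 0.5)
  vol0 <- round(10^log10_vol)
  vol0 <- pmax(vol0, 100)
  price0 <- revenue / vol0
  sales_list <- vector("list", length(config$panel_years))
  for (jy in seq_along(config$panel_years)) {
    yr <- config$panel_years[jy]
    eoy <- as.numeric(as.Date(sprintf("%d-12-31", yr)))
    live <- as.integer(format(nda_date, "%Y")) <= yr
    ncur <- vapply(timelines, function(tl) sum(tl <= eoy), 0L)
    pre <- ncur == 0L
    price <- price0 * relative_price(curve, ncur) *
      exp(stats::rnorm(n, 0, config$price_noise_sd) * (!pre))
    volume <- vol0 * exp(stats::rnorm(n, 0, config$price_noise_sd) * (!pre))
    dollars <- ifelse(pre, revenue, round(price * volume, 2))
    volume <- ifelse(pre, vol0, round(volume))
    sales_list[[jy]] <- data.frame(
      ingredient = ingredient[live], route = route_str[live], year = yr,
      dollars = dollars[live], volume = volume[live],
      stringsAsFactors = FALSE)
  }
  sales <- do.call(rbind, sales_list)

  truth <- list(config = config,
                exposure = X, bucket = bucket, mono = mono, early = early,
                substance = subs, any_generic = any_gen,
                n_observed = n_obs, z1 = z1, z2 = z2,
                class_id = class_id, route = route,
                eta_cov = eta_cov, mu_count = mu, revenue = revenue,
                frailty = frailty,
                n_balance_deficit = n_balance_deficit)
  list(products = products, monographs = monographs, sales = sales,
       truth = truth)
}

#' Write a simulated cohort to disk in the ingest file formats
#'
#' @param sim output of [simulate_cohort()]
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(products = file.path(dir, "products.csv"),
             monographs = file.path(dir, "monographs.csv"),
             sales = file.path(dir, "sales.csv"))
  write_table(sim$products, paths["products"])
  write_table(sim$monographs, paths["monographs"])
  write_table(sim$sales, paths["sales"])
  truth_path <- file.path(dir, "truth.yaml")
  tr <- sim$truth
  yaml::write_yaml(list(
    seed = tr$config$seed,
    true_or_any_generic = tr$config$true_or_any_generic,
    true_irr_count = tr$config$true_irr_count,
    true_hr_gap23 = tr$config$true_hr_gap23,
    true_hr_gap12 = tr$config$true_hr_gap12,
    exposure_timing = tr$config$exposure_timing,
    n_drugs = tr$config$n_drugs,
    n_exposed = sum(tr$exposure),
    n_balance_deficit = tr$n_balance_deficit), truth_path)
  invisible(c(paths, truth = truth_path))
}

#' Run the linkage and market-construction pipeline on in-memory tables
#'
#' Convenience used by the simulation studies and the pipeline driver:
#' builds markets from product records, attaches monographs, applies the
#' eligibility cascade, and computes vintage, market size and the
#' `sales_match` flag, returning the analysis-ready cohort.
#'
#' @param products,monographs,sales ingest-schema data.frames (as returned
#'   by the readers or by [simulate_cohort()])
#' @param config cascade configuration
#' @param study_end end of observation window
#' @return list with `markets` (cohort), `ledger`, `all_markets`
#' @export
assemble_cohort <- function(products, monographs, sales,
                            config = cascade_config(),
                            study_end = STUDY_END_DEFAULT) {
  products <- as_product_table(products)
  m <- build_markets(products, sales, study_end)
  m <- attach_monographs(m, monographs)
  res <- apply_eligibility_cascade(m, config)
  keep <- is.na(res$markets$removed_by)
  cohort <- subset_markets(m, keep)
  cohort <- compute_vintage(cohort)
  cohort <- compute_market_size(cohort, sales)
  list(markets = cohort, ledger = res$ledger, all_markets = res$markets)
}

#' Build a product table exercising every eligibility filter
#'
#' Constructs a small cohort where a planned number of markets violates each
#' cascade filter (and only filters at or after its own position, so
#' first-failure attribution is exact), plus a planned number of fully
#' eligible markets. Used to test the attrition ledger against known counts.
#'
#' @param plan named integer vector; names are cascade filter names plus
#'   `"eligible"`
#' @param overlap if TRUE every violating market is additionally flagged
#'   OTC, so each still fails first at its own filter (tests first-failure
#'   attribution)
#' @return list with `products`, `monographs`, `sales` data.frames and the
#'   `plan`
#' @export
make_attrition_fixture <- function(plan = c(pre_1982 = 3, no_sales_match = 2,
                                            otc_or_discontinued = 1,
                                            eligible = 4),
                                   overlap = FALSE) {
  known <- c("pre_1982", "pre_loe", "monograph_before_nda", "under_patent",
             "no_sales_match", "no_class", "otc_or_discontinued", "eligible")
  if (length(plan) && (is.null(names(plan)) ||
                       !all(names(plan) %in% known))) {
    ge_error("make_attrition_fixture: unknown plan entries",
             "genentry_config_error")
  }
  rows <- list()
  monos <- list()
  sales <- list()
  idx <- 0
  add <- function(kind) {
    idx <<- idx + 1
    ing <- sprintf("FIXDRUG%03d", idx)
    nda_date <- if (kind == "pre_1982") PRE1982_SENTINEL else "2000-06-15"
    anda_date <- if (kind == "pre_loe") "1997-03-01" else "2005-03-01"
    otc <- kind == "otc_or_discontinued" || (overlap && kind != "eligible")
    rows[[length(rows) + 1]] <<- data.frame(
      ingredient = ing, route = "ORAL", dosage_form = "FORM",
      trade_name = ing, applicant = "ORIGINATOR",
      application_type = "NDA", application_number = sprintf("N%06d", idx),
      approval_date = nda_date, otc_flag = as.character(otc),
      discontinued_flag = "FALSE",
      therapeutic_class = if (kind == "no_class") "" else "CFIX",
      loe_date = "", patent_flag = as.character(kind == "under_patent"),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <<- data.frame(
      ingredient = ing, route = "ORAL", dosage_form = "FORM",
      trade_name = "", applicant = paste0("GEN-", idx),
      application_type = "ANDA", application_number = sprintf("A%06d", idx),
      approval_date = anda_date, otc_flag = "FALSE",
      discontinued_flag = "FALSE",
      therapeutic_class = if (kind == "no_class") "" else "CFIX",
      loe_date = "", patent_flag = "FALSE", stringsAsFactors = FALSE)
    if (kind == "monograph_before_nda") {
      monos[[length(monos) + 1]] <<- data.frame(
        ingredient = ing, route = "ORAL", monograph_type = "product",
        official_date = "1995-01-01", stringsAsFactors = FALSE)
    }
    if (kind != "no_sales_match") {
      sales[[length(sales) + 1]] <<- data.frame(
        ingredient = ing, route = "ORAL", year = 2004L,
        dollars = 1e6, volume = 1e4, stringsAsFactors = FALSE)
    }
  }
  for (kind in names(plan)) {
    for (j in seq_len(plan[[kind]])) add(kind)
  }
  empty_prod <- data.frame(
    ingredient = character(), route = character(), dosage_form = character(),
    trade_name = character(), applicant = character(),
    application_type = character(), application_number = character(),
    approval_date = character(), otc_flag = character(),
    discontinued_flag = character(), therapeutic_class = character(),
    loe_date = character(), patent_flag = character(),
    stringsAsFactors = FALSE)
  list(products = if (length(rows)) do.call(rbind, rows) else empty_prod,
       monographs = if (length(monos)) do.call(rbind, monos) else
         data.frame(ingredient = character(), route = character(),
                    monograph_type = character(),
                    official_date = character(), stringsAsFactors = FALSE),
       sales = if (length(sales)) do.call(rbind, sales) else
         data.frame(ingredient = character(), route = character(),
                    year = integer(), dollars = numeric(), volume = numeric(),
                    stringsAsFactors = FALSE),
       plan = plan)
}
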