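#' Normalize an ingredient-route market key
#'
#' Markets are defined at the ingredient-route level (e.g. the
#' furosemide-intravenous market). The canonical key form is upper-cased,
#' trimmed, with internal whitespace collapsed to single spaces; the
#' operation is idempotent.
#'
#' @param ingredient,route character vectors of equal length
#' @return data.frame with columns `ingredient_norm`, `route_norm`
#' @export
normalize_key <- function(ingredient, route) {
  ing <- toupper(trim(ingredient))
  rt <- toupper(trim(route))
  if (any(is.na(ing) | ing == "") || any(is.na(rt) | rt == "")) {
    ge_error("normalize_key: empty ingredient or route",
             "genentry_validation_error")
  }
  data.frame(ingredient_norm = ing, route_norm = rt, stringsAsFactors = FALSE)
}

market_id <- function(ingredient_norm, route_norm) {
  paste(ingredient_norm, route_norm, sep = " \r ")
}

#' Attach monograph official dates to markets
#'
#' Product monographs describe a finished dosage form and are matched on the
#' full (ingredient, route) key; substance monographs describe the active
#' ingredient only and are matched on ingredient alone, whatever the route.
#' When several monographs of the same type match a market, the earliest
#' official date wins. Monographs that match no market are reported via the
#' `unmatched_monographs` attribute, not an error.
#'
#' @param markets data.frame with `ingredient_norm`, `route_norm` columns
#' @param monographs a monograph table (see [read_monographs()]); keys are
#'   normalized internally
#' @return `markets` with `product_monograph_date` and
#'   `substance_monograph_date` columns (NA when absent)
#' @export
attach_monographs <- function(markets, monographs) {
  mono <- as.data.frame(monographs)
  if (nrow(mono) && !inherits(mono$official_date, "Date")) {
    mono$official_date <- parse_ob_date(as.character(mono$official_date))
  }
  markets$product_monograph_date <- as.Date(NA)
  markets$substance_monograph_date <- as.Date(NA)
  matched <- logical(nrow(mono))
  if (nrow(mono)) {
    ing <- toupper(trim(mono$ingredient))
    rt <- toupper(trim(mono$route))
    is_prod <- mono$monograph_type == "product"

    pk <- market_id(ing[is_prod], rt[is_prod])
    mk <- market_id(markets$ingredient_norm, markets$route_norm)
    pd <- tapply(as.numeric(mono$official_date[is_prod]), pk, min)
    idx <- match(mk, names(pd))
    markets$product_monograph_date <- as.Date(
      as.vector(pd[idx]), origin = "1970-01-01")
    matched[is_prod] <- pk %in% mk[!is.na(idx)]

    sd_ <- tapply(as.numeric(mono$official_date[!is_prod]), ing[!is_prod], min)
    idx2 <- match(markets$ingredient_norm, names(sd_))
    markets$substance_monograph_date <- as.Date(
      as.vector(sd_[idx2]), origin = "1970-01-01")
    matched[!is_prod] <- ing[!is_prod] %in% markets$ingredient_norm
  }
  attr(markets, "unmatched_monographs") <- mono[!matched, , drop = FALSE]
  markets
}

# Filter predicates for the eligibility cascade, in flow-diagram order. Each
# returns TRUE where the market must be REMOVED. A market is attributed to the
# first filter it fails, as in a study-derivation flow diagram.
cascade_filters <- function(cfg) {
  pre_cut <- as.Date(sprintf("%d-01-01", cfg$pre_approval_cut_year))
  loe_cut <- as.Date(sprintf("%d-01-01", cfg$loe_cut_year))
  list(
    pre_1982 = function(m) {
      m$nda_pre1982 | (!is.na(m$nda_approval_date) &
                         m$nda_approval_date < pre_cut)
    },
    pre_loe = function(m) {
      first_gen <- m$first_generic_date
      (!is.na(first_gen) & first_gen < loe_cut) |
        (!is.na(m$loss_of_exclusivity_date) &
           m$loss_of_exclusivity_date < loe_cut)
    },
    monograph_before_nda = function(m) {
      !is.na(m$product_monograph_date) & !is.na(m$nda_approval_date) &
        m$product_monograph_date < m$nda_approval_date
    },
    under_patent = function(m) m$patent_flag %in% TRUE,
    no_sales_match = function(m) !(m$sales_match %in% TRUE),
    no_class = function(m) is.na(m$therapeutic_class) |
      m$therapeutic_class == "",
    otc_or_discontinued = function(m) (m$otc_flag %in% TRUE) |
      (m$discontinued_flag %in% TRUE)
  )
}

#' Default eligibility-cascade configuration
#'
#' The cut years default to the study design: exact approval dates are only
#' available from 1982 onward, and sales data only from 1998 onward (markets
#' already genericized, or off exclusivity, before 1998 have no usable
#' pre-entry market size).
#'
#' @param pre_approval_cut_year approvals before Jan 1 of this year are
#'   excluded (default 1982)
#' @param loe_cut_year markets with a first generic or loss of exclusivity
#'   before Jan 1 of this year are excluded (default 1998)
#' @param order character vector naming the filters in application order
#' @return list config
#' @export
cascade_config <- function(pre_approval_cut_year = 1982,
                           loe_cut_year = 1998,
                           order = c("pre_1982", "pre_loe",
                                     "monograph_before_nda", "under_patent",
                                     "no_sales_match", "no_class",
                                     "otc_or_discontinued")) {
  list(pre_approval_cut_year = pre_approval_cut_year,
       loe_cut_year = loe_cut_year, order = order)
}

#' Apply the eligibility cascade to candidate markets
#'
#' Filters are applied sequentially in the configured order; a market is
#' removed at (and counted against) the first filter it fails, so the ledger
#' telescopes: remaining after step k = remaining after step k-1 minus removed
#' at step k, and the final remaining count is the cohort size.
#'
#' @param markets market table carrying `nda_approval_date`, `nda_pre1982`,
#'   `first_generic_date`, `loss_of_exclusivity_date`,
#'   `product_monograph_date`, `patent_flag`, `sales_match`,
#'   `therapeutic_class`, `otc_flag`, `discontinued_flag`
#' @param config see [cascade_config()]
#' @return list with `cohort` (the surviving markets) and `ledger`
#'   (data.frame filter_name, n_removed, n_remaining)
#' @export
apply_eligibility_cascade <- function(markets, config = cascade_config()) {
  filters <- cascade_filters(config)
  unknown <- setdiff(config$order, names(filters))
  if (length(unknown)) {
    ge_error(sprintf("cascade config references unknown filter(s): %s",
                     paste(unknown, collapse = ", ")),
             "genentry_config_error")
  }
  alive <- rep(TRUE, nrow(markets))
  removed_by <- rep(NA_character_, nrow(markets))
  steps <- data.frame(filter_name = character(), n_removed = integer(),
                      n_remaining = integer(), stringsAsFactors = FALSE)
  for (nm in config$order) {
    fails <- alive & filters[[nm]](markets)
    removed_by[fails] <- nm
    alive <- alive & !fails
    steps <- rbind(steps, data.frame(filter_name = nm,
                                     n_removed = sum(fails),
                                     n_remaining = sum(alive),
                                     stringsAsFactors = FALSE))
  }
  cohort <- markets[alive, , drop = FALSE]
  rownames(cohort) <- NULL
  markets$removed_by <- removed_by
  list(cohort = cohort, ledger = steps, markets = markets)
}
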