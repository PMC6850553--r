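#' Map an administration route to its analysis group
#'
#' Models use five route groups: inhalation, intravenous, oral, topical and
#' other. Injectable routes are pooled with intravenous.
#'
#' @param route_norm normalized route strings
#' @return character vector of group labels
#' @export
route_group <- function(route_norm) {
  r <- toupper(route_norm)
  out <- rep("other", length(r))
  out[grepl("ORAL", r) & !grepl("TOPICAL", r)] <- "oral"
  out[grepl("INTRAVEN|INJECT|IV \\(|^IV$", r)] <- "intravenous"
  out[grepl("INHALA|RESPIRATORY", r)] <- "inhalation"
  out[grepl("TOPICAL|DERMAL|OPHTHALMIC$", r)] <- "topical"
  out[grepl("^TOPICAL", r)] <- "topical"
  out
}

#' Collapse product records into one market per ingredient-route
#'
#' The originator (NDA) application with the earliest approval date defines
#' the market's NDA approval; generic entrants are *distinct ANDA applicants*
#' (the outcome of interest is the number of generic manufacturers, not
#' approvals), each timed at its first ANDA approval in the market. Markets
#' with no NDA record are dropped with a warning, since drug age is undefined
#' for them.
#'
#' @param products a product table (see [read_products()])
#' @param sales optional sales table; used only to set the `sales_match` flag
#' @param study_end end of the observation window (Date); generic approvals
#'   after this date are not counted
#' @return market table, one row per ingredient-route, with the entrant
#'   timeline in attribute `timelines` (a list of Date vectors, one per row)
#' @export
build_markets <- function(products, sales = NULL,
                          study_end = STUDY_END_DEFAULT) {
  p <- as.data.frame(products)
  key <- normalize_key(p$ingredient, p$route)
  p$mid <- market_id(key$ingredient_norm, key$route_norm)
  p$ingredient_norm <- key$ingredient_norm
  p$route_norm <- key$route_norm

  is_nda <- p$application_type == "NDA"
  mids <- unique(p$mid)

  has_nda <- mids %in% p$mid[is_nda]
  if (any(!has_nda)) {
    warning(sprintf("%d market(s) without an NDA record excluded (drug age undefined)",
                    sum(!has_nda)), call. = FALSE)
    mids <- mids[has_nda]
  }

  nda <- p[is_nda & p$mid %in% mids, , drop = FALSE]
  # earliest NDA defines the market; pre-1982 sentinel rows sort last so a
  # dated NDA wins when both exist
  ord <- order(nda$mid, nda$pre1982_flag, nda$approval_date)
  nda <- nda[ord, , drop = FALSE]
  nda <- nda[!duplicated(nda$mid), , drop = FALSE]
  nda <- nda[match(mids, nda$mid), , drop = FALSE]

  anda <- p[!is_nda & p$mid %in% mids & !p$pre1982_flag &
              !is.na(p$approval_date) & p$approval_date <= study_end, ,
            drop = FALSE]
  # one entrant per distinct applicant, at its first approval
  akey <- paste(anda$mid, toupper(anda$applicant), sep = "\r")
  ord <- order(akey, anda$approval_date)
  anda <- anda[ord, , drop = FALSE]
  anda <- anda[!duplicated(akey[ord]), , drop = FALSE]

  anda <- anda[order(anda$approval_date), , drop = FALSE]
  timelines <- split(anda$approval_date,
                     factor(anda$mid, levels = mids))
  timelines <- unname(timelines)

  m <- data.frame(
    ingredient_norm = nda$ingredient_norm,
    route_norm = nda$route_norm,
    nda_approval_date = nda$approval_date,
    nda_pre1982 = nda$pre1982_flag,
    therapeutic_class = nda$therapeutic_class,
    route_group = route_group(nda$route_norm),
    otc_flag = nda$otc_flag,
    discontinued_flag = nda$discontinued_flag,
    patent_flag = nda$patent_flag,
    loss_of_exclusivity_date = nda$loe_date,
    n_generics = vapply(timelines, length, 0L),
    first_generic_date = as.Date(vapply(timelines, function(tl) {
      if (length(tl)) as.numeric(tl[1]) else NA_real_
    }, 0), origin = "1970-01-01"),
    stringsAsFactors = FALSE)
  m$age_years <- as.numeric(study_end - m$nda_approval_date) / 365.25

  if (!is.null(sales)) {
    s <- as.data.frame(sales)
    skey <- market_id(toupper(trim(s$ingredient)), toupper(trim(s$route)))
    m$sales_match <- market_id(m$ingredient_norm, m$route_norm) %in% skey
  } else {
    m$sales_match <- FALSE
  }
  attr(m, "timelines") <- timelines
  attr(m, "study_end") <- study_end
  class(m) <- c("market_table", "data.frame")
  m
}

#' Extract the k-th generic approval date of each market
#'
#' @param markets a market table from [build_markets()]
#' @param k entrant index (1-based)
#' @return Date vector, NA where fewer than k entrants exist
#' @export
generic_date <- function(markets, k) {
  tl <- attr(markets, "timelines")
  as.Date(vapply(tl, function(x) {
    if (length(x) >= k) as.numeric(x[k]) else NA_real_
  }, 0), origin = "1970-01-01")
}

#' Assign vintage ranks within therapeutic classes
#'
#' Vintage is the order in which a drug was approved relative to the other
#' drugs of its class: the earliest NDA in a class has vintage 1. Ties share
#' the lower rank and the next rank is skipped (competition ranking).
#'
#' @param markets a market table with `therapeutic_class` and
#'   `nda_approval_date`
#' @return `markets` with a `vintage` column
#' @export
compute_vintage <- function(markets) {
  v <- rep(NA_integer_, nrow(markets))
  for (cl in unique(markets$therapeutic_class)) {
    i <- which(markets$therapeutic_class %in% cl)
    d <- as.numeric(markets$nda_approval_date[i])
    v[i] <- as.integer(rank(d, ties.method = "min"))
  }
  markets$vintage <- v
  markets
}

#' Compute pre-entry market size
#'
#' Market size is the drug's total sales in the calendar year before the
#' reference event: the first generic approval, or (for markets without a
#' generic) the loss of exclusivity. Markets whose reference year is missing
#' from the panel, or that have no reference event at all, get NA and a
#' `market_size_flag`.
#'
#' @param markets market table with `first_generic_date` and
#'   `loss_of_exclusivity_date`
#' @param sales sales table
#' @return `markets` with `market_size_usd` and `market_size_flag` columns
#' @export
compute_market_size <- function(markets, sales) {
  s <- as.data.frame(sales)
  skey <- paste(market_id(toupper(trim(s$ingredient)), toupper(trim(s$route))),
                s$year, sep = "\r")
  ref_date <- markets$first_generic_date
  use_loe <- is.na(ref_date)
  ref_date[use_loe] <- markets$loss_of_exclusivity_date[use_loe]
  ref_year <- as.integer(format(ref_date, "%Y")) - 1L
  want <- paste(market_id(markets$ingredient_norm, markets$route_norm),
                ref_year, sep = "\r")
  idx <- match(want, skey)
  markets$market_size_usd <- s$dollars[idx]
  markets$market_size_flag <- is.na(markets$market_size_usd)
  markets
}

#' Monograph exposure at a given timing
#'
#' The exposure of interest is a product monograph established before the
#' k-th generic entrant: the official date must strictly precede the k-th
#' generic's approval date, or -- for a market with fewer than k entrants --
#' the end of the study. `"ever"` means official by the end of the study.
#' Exposure is monotone in timing: before_first implies before_second implies
#' before_third implies ever.
#'
#' @param markets market table with a `product_monograph_date` column
#' @param timing one of `"before_first"`, `"before_second"`,
#'   `"before_third"`, `"ever"`
#' @param study_end end of study (defaults to the table's recorded window)
#' @return logical vector
#' @export
compute_exposure <- function(markets,
                             timing = c("before_first", "before_second",
                                        "before_third", "ever"),
                             study_end = NULL) {
  timing <- match.arg(timing)
  if (is.null(study_end)) {
    study_end <- attr(markets, "study_end")
    if (is.null(study_end)) study_end <- STUDY_END_DEFAULT
  }
  k <- switch(timing, before_first = 1L, before_second = 2L,
              before_third = 3L, ever = NA_integer_)
  mono <- markets$product_monograph_date
  if (is.na(k)) return(!is.na(mono) & mono < study_end)
  cutoff <- generic_date(markets, k)
  cutoff[is.na(cutoff)] <- study_end
  !is.na(mono) & mono < cutoff
}
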