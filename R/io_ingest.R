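# Sentinel text used by the Orange Book products file for applications whose
# exact approval date is unknown (pre-1982 approvals).
PRE1982_SENTINEL <- "Approved Prior to Jan 1, 1982"

# End of the study observation window: entrant timelines and exposure
# definitions for markets with too few entrants are evaluated against this date.
STUDY_END_DEFAULT <- as.Date("2018-04-03")

ge_error <- function(msg, class) {
  stop(structure(class = c(class, "genentry_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

trim <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Parse Orange Book style dates
#'
#' Dates in the Orange Book products file are printed as "Mon DD, YYYY"
#' (e.g. "Apr 3, 2018") in the C locale. Returns NA for unparseable input.
#' @param x character vector
#' @return Date vector
#' @keywords internal
parse_ob_date <- function(x) {
  old <- Sys.getlocale("LC_TIME")
  on.exit(suppressWarnings(Sys.setlocale("LC_TIME", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_TIME", "C"))
  out <- as.Date(x, format = "%b %d, %Y")
  iso <- as.Date(x, format = "%Y-%m-%d")
  out[is.na(out)] <- iso[is.na(out)]
  out
}

read_delim_table <- function(path, sep) {
  if (!file.exists(path)) {
    ge_error(sprintf("input file not found: %s", path), "genentry_input_error")
  }
  utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    colClasses = "character", check.names = FALSE,
                    fileEncoding = "UTF-8", na.strings = NULL)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    ge_error(sprintf("file %s is missing mandatory column(s): %s",
                     path, paste(missing, collapse = ", ")),
             "genentry_schema_error")
  }
}

finish_table <- function(accepted, rejects, n_input, subclass) {
  rownames(accepted) <- NULL
  structure(accepted,
            rejects = rejects,
            n_input = n_input,
            class = c(subclass, "data.frame"))
}

#' Rejected rows of an ingested table
#'
#' Every reader collects rows whose mandatory fields fail to parse into a
#' rejects table instead of silently dropping them, so the cohort attrition
#' remains auditable: accepted rows + rejected rows always equals the number
#' of data rows in the input file.
#'
#' @param x a table returned by [read_products()], [read_monographs()] or
#'   [read_sales()]
#' @return data.frame with columns `row` (1-based data-row index in the input
#'   file) and `reason`
#' @export
rejects <- function(x) attr(x, "rejects")

reject_df <- function(row = integer(), reason = character()) {
  data.frame(row = as.integer(row), reason = as.character(reason),
             stringsAsFactors = FALSE)
}

# Column maps for the two supported product dialects. The Orange Book products
# file is tilde-delimited with a header row; dosage form and route share one
# "DF;Route" column. Patent/LOE/class columns are not part of the historical
# file format; they are accepted when present (the synthetic generator emits
# them) and NA otherwise.
OB_PRODUCT_COLS <- c(ingredient = "Ingredient", df_route = "DF;Route",
                     trade_name = "Trade_Name", applicant = "Applicant",
                     application_type = "Appl_Type",
                     application_number = "Appl_No",
                     approval_date = "Approval_Date", type = "Type")
CSV_PRODUCT_COLS <- c(ingredient = "ingredient", route = "route",
                      dosage_form = "dosage_form", trade_name = "trade_name",
                      applicant = "applicant",
                      application_type = "application_type",
                      application_number = "application_number",
                      approval_date = "approval_date", otc_flag = "otc_flag",
                      discontinued_flag = "discontinued_flag")

#' Read a drug product approval table
#'
#' Reads product approval records either in the FDA Orange Book "products"
#' dialect (tilde-delimited text, header row, dates as "Mon DD, YYYY",
#' application type coded "N"/"A", marketing type "RX"/"OTC"/"DISCN") or as a
#' plain CSV with one column per field. Rows whose mandatory fields cannot be
#' parsed are collected in the rejects attribute (see [rejects()]); the
#' literal approval date \code{"Approved Prior to Jan 1, 1982"} is accepted
#' and mapped to an NA date with `pre1982_flag = TRUE` (such products are
#' excluded later by the eligibility cascade, which needs exact dates).
#'
#' Optional columns `Therap_Class`/`therapeutic_class`, `LOE_Date`/`loe_date`
#' and `Patent_Flag`/`patent_flag` are read when present.
#'
#' @param path file path
#' @param dialect `"orange_book"` (default) or `"csv"`
#' @return data.frame of typed product records with attribute `rejects`
#' @export
read_products <- function(path, dialect = c("orange_book", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "orange_book") "~" else ","
  raw <- read_delim_table(path, sep)
  cols <- if (dialect == "orange_book") OB_PRODUCT_COLS else CSV_PRODUCT_COLS
  require_columns(raw, unname(cols), path)
  n <- nrow(raw)
  if (n == 0L) {
    empty <- data.frame(ingredient = character(), route = character(),
                        dosage_form = character(), trade_name = character(),
                        applicant = character(), application_type = character(),
                        application_number = character(),
                        approval_date = as.Date(character()),
                        pre1982_flag = logical(), otc_flag = logical(),
                        discontinued_flag = logical(),
                        therapeutic_class = character(),
                        loe_date = as.Date(character()),
                        patent_flag = logical(), stringsAsFactors = FALSE)
    return(finish_table(empty, reject_df(), 0L, "product_table"))
  }

  opt <- function(nms) {
    hit <- intersect(nms, names(raw))
    if (length(hit)) trim(raw[[hit[1]]]) else rep(NA_character_, n)
  }

  if (dialect == "orange_book") {
    dfr <- trim(raw[[cols[["df_route"]]]])
    parts <- strsplit(dfr, ";", fixed = TRUE)
    dosage_form <- trim(vapply(parts, function(p) if (length(p) >= 1) p[1] else "", ""))
    route <- trim(vapply(parts, function(p) if (length(p) >= 2) p[2] else "", ""))
    type_raw <- toupper(trim(raw[[cols[["type"]]]]))
    otc <- type_raw == "OTC"
    discn <- type_raw == "DISCN"
    app_type_raw <- toupper(trim(raw[[cols[["application_type"]]]]))
    app_type <- ifelse(app_type_raw %in% c("N", "NDA"), "NDA",
                ifelse(app_type_raw %in% c("A", "ANDA"), "ANDA", NA_character_))
    date_raw <- trim(raw[[cols[["approval_date"]]]])
  } else {
    dosage_form <- trim(raw[[cols[["dosage_form"]]]])
    route <- trim(raw[[cols[["route"]]]])
    otc <- toupper(trim(raw[[cols[["otc_flag"]]]])) %in% c("TRUE", "T", "1", "YES")
    discn <- toupper(trim(raw[[cols[["discontinued_flag"]]]])) %in% c("TRUE", "T", "1", "YES")
    app_type_raw <- toupper(trim(raw[[cols[["application_type"]]]]))
    app_type <- ifelse(app_type_raw == "NDA", "NDA",
                ifelse(app_type_raw == "ANDA", "ANDA", NA_character_))
    date_raw <- trim(raw[[cols[["approval_date"]]]])
  }

  pre1982 <- date_raw == PRE1982_SENTINEL
  approval <- parse_ob_date(date_raw)
  ingredient <- trim(raw[[cols[["ingredient"]]]])
  applicant <- opt(c("Applicant", "applicant"))
  rec <- data.frame(
    ingredient = ingredient,
    route = route,
    dosage_form = dosage_form,
    trade_name = opt(c("Trade_Name", "trade_name")),
    applicant = applicant,
    application_type = app_type,
    application_number = opt(c("Appl_No", "application_number")),
    approval_date = approval,
    pre1982_flag = pre1982,
    otc_flag = otc,
    discontinued_flag = discn,
    therapeutic_class = opt(c("Therap_Class", "therapeutic_class")),
    loe_date = parse_ob_date(opt(c("LOE_Date", "loe_date"))),
    patent_flag = toupper(opt(c("Patent_Flag", "patent_flag"))) %in%
      c("TRUE", "T", "1", "YES"),
    stringsAsFactors = FALSE)
  rec$therapeutic_class[!is.na(rec$therapeutic_class) &
                          rec$therapeutic_class == ""] <- NA_character_

  bad_date <- is.na(rec$approval_date) & !pre1982
  bad_key <- rec$ingredient == "" | rec$route == ""
  bad_type <- is.na(rec$application_type)
  bad <- bad_date | bad_key | bad_type
  reason <- character(sum(bad))
  reason[bad_date[bad]] <- "unparseable approval_date"
  reason[bad_type[bad]] <- "unknown application_type"
  reason[bad_key[bad]] <- "empty ingredient or route"
  rej <- reject_df(which(bad), reason)
  finish_table(rec[!bad, , drop = FALSE], rej, n, "product_table")
}

#' Read a monograph directory table
#'
#' CSV with columns `ingredient`, `route`, `monograph_type`
#' (`"product"`/`"substance"`), `official_date` (ISO-8601). Substance
#' monographs describe the active ingredient rather than a finished dosage
#' form, so their `route` may be empty. Duplicate
#' (ingredient, route, monograph_type) rows are deduplicated keeping the
#' earliest official date, with a warning.
#'
#' @param path file path
#' @return data.frame of monograph records with attribute `rejects`
#' @export
read_monographs <- function(path) {
  raw <- read_delim_table(path, ",")
  require_columns(raw, c("ingredient", "route", "monograph_type",
                         "official_date"), path)
  n <- nrow(raw)
  type <- tolower(trim(raw$monograph_type))
  if (n > 0 && any(!type %in% c("product", "substance"))) {
    ge_error(sprintf("unknown monograph_type value(s): %s",
                     paste(unique(type[!type %in% c("product", "substance")]),
                           collapse = ", ")),
             "genentry_schema_error")
  }
  date <- parse_ob_date(trim(raw$official_date))
  rec <- data.frame(ingredient = trim(raw$ingredient), route = trim(raw$route),
                    monograph_type = type, official_date = date,
                    stringsAsFactors = FALSE)
  bad <- is.na(rec$official_date) | rec$ingredient == ""
  rej <- reject_df(which(bad),
                   ifelse(is.na(rec$official_date[bad]),
                          "unparseable official_date", "empty ingredient"))
  rec <- rec[!bad, , drop = FALSE]
  key <- paste(toupper(rec$ingredient), toupper(rec$route), rec$monograph_type,
               sep = "\r")
  if (anyDuplicated(key)) {
    warning(sprintf("%d duplicated monograph row(s) deduplicated keeping the earliest official date",
                    sum(duplicated(key))), call. = FALSE)
    ord <- order(key, rec$official_date)
    rec <- rec[ord, , drop = FALSE]
    rec <- rec[!duplicated(key[ord]), , drop = FALSE]
  }
  finish_table(rec, rej, n, "monograph_table")
}

#' Read a drug-year sales panel
#'
#' CSV with columns `ingredient`, `route`, `year`, `dollars`, `volume`
#' (prescriptions). Validation errors (negative values, duplicated
#' ingredient-route-year keys) are fatal: the savings engine divides dollars
#' by volume, and a silently corrupted panel would propagate into the
#' counterfactual totals.
#'
#' @param path file path
#' @return data.frame of sales observations with attribute `rejects`
#' @export
read_sales <- function(path) {
  raw <- read_delim_table(path, ",")
  require_columns(raw, c("ingredient", "route", "year", "dollars", "volume"),
                  path)
  n <- nrow(raw)
  rec <- data.frame(ingredient = trim(raw$ingredient), route = trim(raw$route),
                    year = suppressWarnings(as.integer(trim(raw$year))),
                    dollars = suppressWarnings(as.numeric(trim(raw$dollars))),
                    volume = suppressWarnings(as.numeric(trim(raw$volume))),
                    stringsAsFactors = FALSE)
  bad <- is.na(rec$year) | is.na(rec$dollars) | is.na(rec$volume) |
    rec$ingredient == "" | rec$route == ""
  rej <- reject_df(which(bad), rep("unparseable mandatory field", sum(bad)))
  rec <- rec[!bad, , drop = FALSE]
  if (nrow(rec) && any(rec$dollars < 0)) {
    ge_error("negative dollars in sales panel", "genentry_validation_error")
  }
  if (nrow(rec) && any(rec$volume < 0)) {
    ge_error("negative volume in sales panel", "genentry_validation_error")
  }
  key <- paste(toupper(rec$ingredient), toupper(rec$route), rec$year, sep = "\r")
  if (anyDuplicated(key)) {
    dupes <- unique(key[duplicated(key)])
    ge_error(sprintf("duplicate (ingredient, route, year) keys in sales panel: %s",
                     paste(gsub("\r", "/", dupes), collapse = "; ")),
             "genentry_validation_error")
  }
  finish_table(rec, rej, n, "sales_table")
}

#' Coerce a data.frame to the typed product-table schema
#'
#' Applies the same typing rules as the CSV reader (date parsing, the
#' pre-1982 sentinel, flag coercion, empty class to NA) to an in-memory
#' data.frame, e.g. one produced by the synthetic generator. Tables already
#' typed pass through unchanged.
#'
#' @param df data.frame in the CSV product dialect
#' @return a typed `product_table`
#' @export
as_product_table <- function(df) {
  if (inherits(df, "product_table")) return(df)
  p <- as.data.frame(df)
  date_raw <- trim(as.character(p$approval_date))
  p$pre1982_flag <- date_raw == PRE1982_SENTINEL
  p$approval_date <- parse_ob_date(date_raw)
  p$loe_date <- if ("loe_date" %in% names(p)) {
    parse_ob_date(trim(as.character(p$loe_date)))
  } else as.Date(NA)
  to_flag <- function(x) toupper(trim(as.character(x))) %in%
    c("TRUE", "T", "1", "YES")
  p$otc_flag <- if ("otc_flag" %in% names(p)) to_flag(p$otc_flag) else FALSE
  p$discontinued_flag <- if ("discontinued_flag" %in% names(p)) {
    to_flag(p$discontinued_flag)
  } else FALSE
  p$patent_flag <- if ("patent_flag" %in% names(p)) {
    to_flag(p$patent_flag)
  } else FALSE
  if (!"therapeutic_class" %in% names(p)) p$therapeutic_class <- NA_character_
  p$therapeutic_class <- trim(as.character(p$therapeutic_class))
  p$therapeutic_class[!is.na(p$therapeutic_class) &
                        p$therapeutic_class == ""] <- NA_character_
  bad <- (is.na(p$approval_date) & !p$pre1982_flag) |
    trim(p$ingredient) == "" | trim(p$route) == ""
  finish_table(p[!bad, , drop = FALSE],
               reject_df(which(bad), rep("unparseable mandatory field",
                                         sum(bad))),
               nrow(p), "product_table")
}

#' Write a pipeline table as CSV
#'
#' All pipeline outputs are flat CSV files; dates are written ISO-8601.
#' `write_table()` followed by the corresponding reader round-trips the typed
#' records.
#'
#' @param x data.frame
#' @param path output path
#' @export
write_table <- function(x, path) {
  out <- as.data.frame(x)
  for (j in seq_along(out)) {
    if (inherits(out[[j]], "Date")) out[[j]] <- format(out[[j]], "%Y-%m-%d")
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write the rejects sidecar of an ingested table
#'
#' @param x a table with a rejects attribute
#' @param path output path
#' @export
write_rejects <- function(x, path) {
  write_table(rejects(x), path)
}
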