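# Shared fixture builders. Everything is generated in code at test time.

ob_header <- paste("Ingredient", "DF;Route", "Trade_Name", "Applicant",
                   "Appl_Type", "Appl_No", "Approval_Date", "Type",
                   sep = "~")

write_ob_fixture <- function(rows, path = tempfile(fileext = ".txt")) {
  writeLines(c(ob_header, rows), path)
  path
}

ob_row <- function(ingredient = "FUROSEMIDE", route = "INTRAVENOUS",
                   form = "SOLUTION", trade = "BRAND", applicant = "ACME",
                   type = "N", no = "N012345", date = "Jun 30, 1986",
                   mkt = "RX") {
  paste(ingredient, paste0(form, ";", route), trade, applicant, type, no,
        date, mkt, sep = "~")
}

# a small hand-built product table (CSV dialect, in-memory)
csv_product_row <- function(ingredient, route, applicant, application_type,
                            approval_date, therapeutic_class = "C1",
                            otc_flag = "FALSE", discontinued_flag = "FALSE",
                            loe_date = "", patent_flag = "FALSE") {
  data.frame(ingredient = ingredient, route = route, dosage_form = "FORM",
             trade_name = "", applicant = applicant,
             application_type = application_type,
             approval_date = approval_date, otc_flag = otc_flag,
             discontinued_flag = discontinued_flag,
             therapeutic_class = therapeutic_class, loe_date = loe_date,
             patent_flag = patent_flag, stringsAsFactors = FALSE)
}

# markets with controlled entrant timelines and monograph dates, via the
# real construction path
toy_markets <- function(spec) {
  prods <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    s <- spec[i, ]
    rows <- csv_product_row(s$ingredient, "ORAL", "ORIG", "NDA", s$nda,
                            therapeutic_class = s$class)
    gen_dates <- strsplit(s$generics, ";")[[1]]
    gen_dates <- gen_dates[nzchar(gen_dates)]
    if (length(gen_dates)) {
      rows <- rbind(rows, do.call(rbind, lapply(seq_along(gen_dates),
        function(k) {
          csv_product_row(s$ingredient, "ORAL", paste0("GEN", i, "_", k),
                          "ANDA", gen_dates[k], therapeutic_class = s$class)
        })))
    }
    rows
  }))
  monos <- spec[nzchar(spec$mono_date), c("ingredient", "mono_date")]
  monographs <- if (nrow(monos)) {
    data.frame(ingredient = monos$ingredient, route = "ORAL",
               monograph_type = "product", official_date = monos$mono_date,
               stringsAsFactors = FALSE)
  } else {
    data.frame(ingredient = character(), route = character(),
               monograph_type = character(), official_date = character(),
               stringsAsFactors = FALSE)
  }
  m <- build_markets(as_product_table(prods))
  attach_monographs(m, monographs)
}

# small simulated cohort, cached per session
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_cohort(simulation_config(n_drugs = 600L,
                                               n_classes = 15L, seed = 42L))
      asm <- assemble_cohort(sim$products, sim$monographs, sim$sales)
      cache <<- list(sim = sim, markets = asm$markets, ledger = asm$ledger)
    }
    cache
  }
})
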