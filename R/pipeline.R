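PIPELINE_STAGES <- c("simulate", "cohort", "fit", "savings", "sensitivity",
                     "report")

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      ge_error(sprintf("config file not found: %s", config),
               "genentry_input_error")
    }
    cfg <- yaml::read_yaml(config)
    attr(cfg, "path") <- config
  } else {
    cfg <- config
  }
  known <- c("seed", "stages", "inputs", "simulate", "cascade", "savings",
             "study_end")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    ge_error(sprintf("unknown config key(s): %s",
                     paste(unknown, collapse = ", ")),
             "genentry_config_error")
  }
  cfg
}

log_line <- function(con, ...) {
  msg <- sprintf(...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full analysis pipeline
#'
#' Orchestrates ingestion, cohort construction, the three estimands, the
#' counterfactual savings engine and the sensitivity analyses, writing every
#' report as CSV plus a plain-text summary and a run log (config hash, input
#' hashes, seed, package version). Fully deterministic given inputs and
#' seed.
#'
#' When no input files are configured, the `simulate` stage generates a
#' synthetic cohort into `out_dir/simulated/` and the later stages consume
#' it.
#'
#' @param config path to a YAML config file, or an equivalent list
#' @param out_dir output directory
#' @param seed overrides the config seed
#' @param stages subset of `c("simulate", "cohort", "fit", "savings",
#'   "sensitivity", "report")`
#' @param keep_going continue past fit errors (recorded in the log) instead
#'   of failing
#' @return invisibly, a list of the in-memory results
#' @export
run_pipeline <- function(config, out_dir, seed = NULL,
                         stages = PIPELINE_STAGES, keep_going = FALSE) {
  cfg <- read_pipeline_config(config)
  bad_stage <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad_stage)) {
    ge_error(sprintf("unknown stage(s): %s",
                     paste(bad_stage, collapse = ", ")),
             "genentry_config_error")
  }
  if (is.null(seed)) seed <- cfg$seed %||% 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(out_dir, "run_log.txt"), "w")
  on.exit(close(logf), add = TRUE)
  log_line(logf, "genentry %s | seed %d | stages: %s",
           as.character(utils::packageVersion("genentry")), as.integer(seed),
           paste(stages, collapse = ","))
  cfg_path <- attr(cfg, "path")
  if (!is.null(cfg_path)) {
    log_line(logf, "config %s md5 %s", cfg_path,
             unname(tools::md5sum(cfg_path)))
  }

  results <- list()
  inputs <- cfg$inputs

  if ("simulate" %in% stages) {
    sim_args <- cfg$simulate %||% list()
    sim_args$seed <- as.integer(seed)
    scfg <- do.call(simulation_config, sim_args)
    sim <- simulate_cohort(scfg)
    paths <- write_cohort(sim, file.path(out_dir, "simulated"))
    log_line(logf, "simulated cohort: %d drugs, %d exposed",
             scfg$n_drugs, sum(sim$truth$exposure))
    if (is.null(inputs)) {
      inputs <- list(products = unname(paths["products"]),
                     products_dialect = "csv",
                     monographs = unname(paths["monographs"]),
                     sales = unname(paths["sales"]))
    }
    results$sim <- sim
  }

  need_data <- any(c("cohort", "fit", "savings", "sensitivity") %in% stages)
  if (need_data) {
    for (key in c("products", "monographs", "sales")) {
      if (is.null(inputs[[key]])) {
        ge_error(sprintf("config inputs missing required key: %s", key),
                 "genentry_config_error")
      }
      if (!file.exists(inputs[[key]])) {
        ge_error(sprintf("input file not found: %s", inputs[[key]]),
                 "genentry_input_error")
      }
      log_line(logf, "input %s %s md5 %s", key, inputs[[key]],
               unname(tools::md5sum(inputs[[key]])))
    }
    products <- read_products(inputs$products,
                              inputs$products_dialect %||% "csv")
    monographs <- read_monographs(inputs$monographs)
    sales <- read_sales(inputs$sales)
    write_rejects(products, file.path(out_dir, "rejects_products.csv"))
    casc_args <- cfg$cascade %||% list()
    study_end <- as.Date(cfg$study_end %||% STUDY_END_DEFAULT)
    asm <- assemble_cohort(products, monographs, sales,
                           do.call(cascade_config, casc_args), study_end)
    markets <- asm$markets
    results$ledger <- asm$ledger
    results$markets <- markets
    if ("cohort" %in% stages) {
      write_table(asm$ledger, file.path(out_dir, "attrition_ledger.csv"))
      out_m <- as.data.frame(markets)
      out_m$generic_approval_dates <- vapply(
        attr(markets, "timelines"),
        function(tl) paste(format(tl, "%Y-%m-%d"), collapse = ";"), "")
      write_table(out_m, file.path(out_dir, "markets.csv"))
      log_line(logf, "cohort: %d of %d markets eligible", nrow(markets),
               nrow(asm$all_markets))
    }
  }

  run_or_log <- function(label, expr) {
    if (keep_going) {
      tryCatch(expr, genentry_error = function(e) {
        log_line(logf, "fit error in %s: %s", label, conditionMessage(e))
        NULL
      })
    } else expr
  }

  if ("fit" %in% stages) {
    results$table2 <- run_or_log("main fits", fit_main_table(markets))
    if (!is.null(results$table2)) {
      write_table(results$table2, file.path(out_dir, "table2.csv"))
    }
    at_risk <- markets$n_generics >= 2
    if (any(markets$n_generics >= 3 & at_risk)) {
      m2 <- subset_markets(markets, at_risk)
      d2 <- generic_date(m2, 2L)
      d3 <- generic_date(m2, 3L)
      ev <- !is.na(d3)
      tm <- ifelse(ev, as.numeric(d3 - d2),
                   as.numeric(study_end - d2))
      grp <- compute_exposure(m2, "before_second")
      km <- lapply(split(seq_along(tm), grp), function(ii) {
        km_summary(tm[ii], as.numeric(ev[ii]))
      })
      curve_df <- do.call(rbind, lapply(names(km), function(g) {
        cbind(exposed = g, km[[g]]$curve)
      }))
      write_table(curve_df, file.path(out_dir, "km_curve.csv"))
      results$km <- km
    }
  }

  if ("savings" %in% stages) {
    sv_cfg <- cfg$savings %||% list()
    curve <- if (!is.null(inputs$price_curve)) {
      read_price_curve(inputs$price_curve)
    } else default_price_curve()
    irr <- results$table2$estimate[results$table2$estimand == "count_IRR" &
                                     results$table2$adjusted][1] %||% NULL
    if (is.null(irr) || length(irr) == 0 || is.na(irr)) {
      cf <- run_or_log("count fit for savings", fit_count(markets))
      irr <- if (is.null(cf)) NA_real_ else cf$estimate_ratio
    }
    sv <- run_or_log("savings", compute_savings(
      markets, sales, irr, curve,
      years = as.integer(sv_cfg$years %||% c(2015L, 2016L)),
      exposure = sv_cfg$exposure %||% "before_first"))
    if (!is.null(sv)) {
      write_table(sv$rows, file.path(out_dir, "savings_rows.csv"))
      write_table(sv$totals, file.path(out_dir, "savings_totals.csv"))
      results$savings <- sv
      log_line(logf, "savings totals: %s",
               paste(sprintf("%d: $%.0f", sv$totals$year,
                             sv$totals$total_savings), collapse = "; "))
    }
  }

  if ("sensitivity" %in% stages) {
    t3 <- run_or_log("sensitivity", sensitivity_table(markets))
    if (!is.null(t3)) write_table(t3, file.path(out_dir, "table3.csv"))
    g12 <- run_or_log("gap12", run_gap12(markets))
    if (!is.null(g12)) {
      write_table(fit_row(g12, "gap 1st to 2nd generic"),
                  file.path(out_dir, "table4.csv"))
    }
    results$table3 <- t3
    results$gap12 <- g12
  }

  if ("report" %in% stages) {
    sm <- file.path(out_dir, "summary.txt")
    con <- file(sm, "w")
    writeLines(sprintf("genentry pipeline summary (seed %d)",
                       as.integer(seed)), con)
    if (!is.null(results$ledger)) {
      writeLines("\nAttrition:", con)
      writeLines(sprintf("  %-22s removed %5d  remaining %5d",
                         results$ledger$filter_name,
                         results$ledger$n_removed,
                         results$ledger$n_remaining), con)
    }
    if (!is.null(results$table2)) {
      writeLines("\nMain estimands:", con)
      writeLines(sprintf("  %-14s %s  %5.2f (%.2f-%.2f)",
                         results$table2$estimand,
                         ifelse(results$table2$adjusted, "adj  ", "crude"),
                         results$table2$estimate, results$table2$ci_low,
                         results$table2$ci_high), con)
    }
    if (!is.null(results$savings)) {
      writeLines("\nCounterfactual savings:", con)
      writeLines(sprintf("  %d: $%.0f (%d additional manufacturers)",
                         results$savings$totals$year,
                         results$savings$totals$total_savings,
                         results$savings$totals$additional_manufacturers),
                 con)
    }
    close(con)
    log_line(logf, "summary written to %s", sm)
  }
  invisible(results)
}
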