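# Descriptive case characteristics and end-to-end pipeline orchestration.

block_df <- function(stratum, n) {
  data.frame(stratum = stratum, n = as.integer(n),
             proportion = as.integer(n) / sum(n),
             stringsAsFactors = FALSE)
}

#' Descriptive characteristics of a case set
#'
#' Counts and proportions per block: sex, age strata (`<18`, `[18,65)`,
#' `[65,85)`, `>=85`, unspecified), weight strata (`<50`, `50-100`,
#' `>100` kg), reporter type, reporting country (US / non-US), FDA receipt
#' year, and outcome codes. Each block's proportions are taken over the
#' block's own total: for single-valued blocks that equals the case count,
#' while the outcome block counts each case once per distinct outcome code
#' (plus an unspecified row for cases with none), so its counts may exceed
#' the number of cases.
#'
#' @param cs a deduplicated `faers_case_set`.
#' @return object of class `faers_descriptives`: named list of data.frames
#'   (`stratum`, `n`, `proportion`) plus `n_cases`.
#' @export
describe_cases <- function(cs) {
  stopifnot(inherits(cs, "faers_case_set"))
  demo <- cs$demo
  if (nrow(demo) == 0) stop("cannot describe an empty case set")

  sex <- block_df(c("Female", "Male", "Not specified"),
                  c(sum(demo$sex == "F"), sum(demo$sex == "M"),
                    sum(!demo$sex %in% c("F", "M"))))

  ag <- demo$age_years
  age <- block_df(
    c("<18", "18-65", "65-85", ">=85", "Not specified"),
    c(sum(!is.na(ag) & ag < 18),
      sum(!is.na(ag) & ag >= 18 & ag < 65),
      sum(!is.na(ag) & ag >= 65 & ag < 85),
      sum(!is.na(ag) & ag >= 85),
      sum(is.na(ag))))

  w <- demo$weight_kg
  weight <- block_df(
    c("<50 kg", "50-100 kg", ">100 kg", "Not specified"),
    c(sum(!is.na(w) & w < 50),
      sum(!is.na(w) & w >= 50 & w <= 100),
      sum(!is.na(w) & w > 100),
      sum(is.na(w))))

  reporter <- block_df(
    c("Health-professional", "Consumer", "Not specified"),
    c(sum(demo$reporter == "health-professional"),
      sum(demo$reporter == "consumer"),
      sum(demo$reporter == "unknown")))

  ctry <- trimws(demo$occr_country)
  country <- block_df(
    c("US", "Non-US", "Not specified"),
    c(sum(ctry == "US"), sum(nzchar(ctry) & ctry != "US"),
      sum(!nzchar(ctry))))

  yrs <- sort(unique(demo$year[!is.na(demo$year)]))
  year <- block_df(as.character(yrs),
                   vapply(yrs, function(y) {
                     sum(!is.na(demo$year) & demo$year == y)
                   }, 1L))

  # one count per distinct outcome code per case; cases without any
  # outcome row appear as Not specified
  oc <- unique(cs$outc[, c("caseid", "outc_cod")])
  codes <- c("CA", "DE", "DS", "HO", "LT", "OT", "RI")
  n_codes <- vapply(codes, function(k) sum(oc$outc_cod == k), 1L)
  n_none <- sum(!demo$caseid %in% oc$caseid)
  outcome <- block_df(c(codes, "Not specified"), c(n_codes, n_none))

  structure(list(n_cases = nrow(demo), sex = sex, age = age,
                 weight = weight, reporter = reporter, country = country,
                 year = year, outcome = outcome),
            class = "faers_descriptives")
}

#' @export
print.faers_descriptives <- function(x, ...) {
  cat(sprintf("Case characteristics (n = %d)\n", x$n_cases))
  for (blk in c("sex", "age", "weight", "reporter", "country", "year",
                "outcome")) {
    cat(sprintf("-- %s\n", blk))
    print(x[[blk]], row.names = FALSE)
  }
  invisible(x)
}

descriptives_to_table <- function(desc) {
  blocks <- c("sex", "age", "weight", "reporter", "country", "year",
              "outcome")
  do.call(rbind, lapply(blocks, function(b) {
    cbind(data.frame(block = b, stringsAsFactors = FALSE), desc[[b]])
  }))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full signal-detection pipeline
#'
#' Orchestrates ingest, deduplication, target selection, descriptives, the
#' SOC- and PT-level disproportionality sweeps, the age subgroup sweeps and
#' the time-to-onset Weibull analysis, writing one TSV per stage plus a run
#' log with the audit counts. Every number in the exported tables is
#' reproducible by calling the corresponding function directly; re-running
#' with identical inputs is byte-identical (stage timings go to the
#' console, never into the outputs).
#'
#' @param input_dir directory of quarterly FAERS-style files.
#' @param dictionary a `meddra_dictionary` or path to a dictionary file.
#' @param drug_names target drug names (generic + brands).
#' @param out_dir output directory, created if needed.
#' @param roles qualifying drug role codes.
#' @param min_cases_pt minimum target records for the PT sweep.
#' @param min_cases_soc minimum target records for the SOC sweep.
#' @param subgroup_age_max upper age bound (exclusive, years) of the
#'   pediatric subgroup.
#' @param min_cases_pt_subgroup minimum target records for the subgroup PT
#'   sweep.
#' @return invisibly, a list with all stage results (`case_set`, `target`,
#'   `descriptives`, `soc`, `pt`, `subgroup_soc`, `subgroup_pt`, `tto`,
#'   `weibull`, `outputs`).
#' @export
run_pipeline <- function(input_dir, dictionary, drug_names, out_dir,
                         roles = "PS", min_cases_pt = 100,
                         min_cases_soc = 1, subgroup_age_max = 18,
                         min_cases_pt_subgroup = 3) {
  outputs <- character(0)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      # remove partial outputs so a failed run leaves nothing half-written
      unlink(outputs)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    message(sprintf("[pvsignal] %-16s %6.2fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }
  if (!dir.exists(input_dir)) {
    stop("input directory not found: ", input_dir)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(dictionary)) dictionary <- read_meddra(dictionary)

  raw <- stage("ingest", read_faers_data(input_dir))
  cs <- stage("case_set", case_set(raw))
  target <- stage("target", select_target_cases(cs, drug_names, roles))
  desc <- stage("descriptives", describe_cases(cs))
  records <- stage("records", build_event_records(cs, target, dictionary))
  soc <- stage("soc_sweep",
               analyze_all(records, "SOC", min_cases = min_cases_soc))
  pt <- stage("pt_sweep",
              analyze_all(records, "PT", min_cases = min_cases_pt))

  sub_cs <- stage("subgroup", filter_subgroup(cs, function(d) {
    !is.na(d$age_years) & d$age_years < subgroup_age_max
  }))
  sub_soc <- sub_pt <- NULL
  sub_target <- select_target_cases(sub_cs, drug_names, roles)
  if (sub_target$n_target > 0 && nrow(sub_cs$reac) > 0) {
    # the stratum can lack target event records entirely; that is a valid
    # (empty) subgroup result, not a pipeline failure
    sub_records <- tryCatch(
      build_event_records(sub_cs, sub_target, dictionary),
      error = function(e) NULL)
    if (!is.null(sub_records)) {
      sub_soc <- analyze_all(sub_records, "SOC", min_cases = 1)
      sub_pt <- analyze_all(sub_records, "PT",
                            min_cases = min_cases_pt_subgroup)
    }
  }

  tto <- stage("tto", compute_tto(cs, target))
  tto_sum <- NULL
  wfit <- NULL
  if (nrow(tto$records) >= 10) {
    tto_sum <- summarize_tto(tto$records$days)
    wfit <- fit_weibull(tto$records$days)
  }

  out <- function(name) file.path(out_dir, name)
  outputs <- c(
    write_tsv(descriptives_to_table(desc), out("descriptives.tsv")),
    write_tsv(format_signal_table(soc), out("signals_soc.tsv")),
    write_tsv(format_signal_table(pt), out("signals_pt.tsv")),
    write_tsv(if (!is.null(sub_soc)) format_signal_table(sub_soc) else
      data.frame(note = "no subgroup target cases"),
      out("subgroup_signals_soc.tsv")),
    write_tsv(if (!is.null(sub_pt)) format_signal_table(sub_pt) else
      data.frame(note = "no subgroup target cases"),
      out("subgroup_signals_pt.tsv")),
    write_tsv(if (!is.null(tto_sum)) {
      cbind(tto_sum$bins,
            data.frame(n = tto_sum$n, median = tto_sum$median,
                       q1 = tto_sum$q1, q3 = tto_sum$q3))
    } else data.frame(note = "fewer than 10 usable onset intervals"),
    out("tto_summary.tsv")),
    write_tsv(if (!is.null(wfit)) {
      data.frame(alpha = wfit$alpha, alpha_low = wfit$alpha_ci[1],
                 alpha_high = wfit$alpha_ci[2], beta = wfit$beta,
                 beta_low = wfit$beta_ci[1], beta_high = wfit$beta_ci[2],
                 n = wfit$n, loglik = wfit$loglik,
                 failure_type = wfit$failure_type)
    } else data.frame(note = "fewer than 10 usable onset intervals"),
    out("weibull_fit.tsv"))
  )

  log_lines <- c(
    sprintf("pvsignal %s", as.character(utils::packageVersion("pvsignal"))),
    sprintf("input_dir: %s", input_dir),
    sprintf("drug_names: %s", paste(drug_names, collapse = ", ")),
    sprintf("roles: %s", paste(roles, collapse = ", ")),
    sprintf("quarters: %s", paste(cs$quarters, collapse = ", ")),
    sprintf("audit.%s: %s", names(cs$audit),
            vapply(cs$audit, function(v) paste(v, collapse = ","), "")),
    sprintf("target_cases: %d", target$n_target),
    sprintf("tto.%s: %d", names(tto$audit), as.integer(tto$audit))
  )
  writeLines(log_lines, out("run_log.txt"))
  outputs <- c(outputs, out("run_log.txt"))

  invisible(list(case_set = cs, target = target, descriptives = desc,
                 soc = soc, pt = pt, subgroup_soc = sub_soc,
                 subgroup_pt = sub_pt, tto = tto, tto_summary = tto_sum,
                 weibull = wfit, outputs = outputs))
}
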