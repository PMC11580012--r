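# Synthetic FAERS-style quarterly file sets with known planted drug-event
# associations, duplicate case versions, partial dates and Weibull
# time-to-onset intervals, so the whole pipeline is testable without any
# database download.

target_name_variants <- c("MEPOLIZUMAB", "NUCALA", "NUCALA 100MG",
                          "Mepolizumab.", "mepolizumab")

background_drug_pool <- c(
  "ADALIMUMAB", "IBUPROFEN", "PARACETAMOL", "OMALIZUMAB", "PREDNISONE",
  "SALBUTAMOL", "METFORMIN", "ATORVASTATIN", "LISINOPRIL", "AMOXICILLIN",
  "OMEPRAZOLE", "SERTRALINE", "LEVOTHYROXINE", "FLUTICASONE PROPIONATE",
  "MONTELUKAST", "AZITHROMYCIN", "GABAPENTIN", "WARFARIN",
  "INSULIN GLARGINE", "DUPILUMAB", "BENRALIZUMAB", "TIOTROPIUM")

target_indications <- c("Asthma", "Eosinophilic asthma",
                        "Eosinophilic granulomatosis with polyangiitis",
                        "Hypereosinophilic syndrome", "Nasal polyps")
background_indications <- c("Hypertension", "Pain", "Diabetes mellitus",
                            "Depression", "Infection prophylaxis",
                            "Product used for unknown indication")

# Default per-PT baseline reporting rates: proportional to the comparator
# counts of the bundled PT-level reference table, scaled so a background
# case reports about two PTs on average. This keeps rare terms rare
# (asthmatic crisis) and common terms common (dyspnoea) in proportion to a
# real reporting universe.
default_pt_profile <- function(mean_pts_per_case = 2) {
  tab <- utils::read.delim(system.file("extdata", "table3_pt.tsv",
                                       package = "pvsignal",
                                       mustWork = TRUE))
  data.frame(pt = tab$pt, soc = tab$soc,
             rate = tab$c / sum(tab$c) * mean_pts_per_case,
             stringsAsFactors = FALSE)
}

#' Configuration for the synthetic report generator
#'
#' Defaults emulate the reporting universe of a mepolizumab
#' pharmacovigilance study at desk scale: demographics follow the published
#' marginal distributions (46.1% female, 71.1% age unspecified, 67.28%
#' health-professional reporters, 55.8% US), onset intervals are Weibull
#' with shape 0.70 and scale 415.47 days, roughly 60% of dates are missing
#' or partial (so that about 16% of cases have two usable dates, matching
#' the published usable-onset fraction), and a handful of respiratory and
#' infection terms carry planted risk multipliers.
#'
#' @param seed integer RNG seed; the same seed yields byte-identical files.
#' @param n_target_cases number of target-drug cases.
#' @param n_background_cases number of other-drug cases.
#' @param pt_dictionary data.frame with columns `pt`, `soc`: the event
#'   vocabulary.
#' @param background_pt_rates named numeric in `[0,1]`, per-PT baseline
#'   report probability; names must match `pt_dictionary$pt`.
#' @param planted_signals named numeric (>= 0): risk multipliers applied to
#'   the per-PT rate in target-drug cases; every name must be in the
#'   dictionary. A multiplier of 1 is a planted null.
#' @param duplicate_rate fraction in `[0,1)` of cases emitted as two caseid
#'   versions (distinct primaryid, perturbed report date, identical drugs
#'   and events).
#' @param bad_date_rate fraction in `[0,1)` of therapy/event dates emitted
#'   blank or truncated to `YYYYMM`/`YYYY`.
#' @param negative_interval_rate fraction of cases whose event date is
#'   (erroneously) before therapy start, emulating data-entry errors.
#' @param tto_shape,tto_scale Weibull shape (beta) and scale (alpha, days)
#'   of the therapy-start-to-event interval.
#' @param n_deleted number of caseids listed in the deleted-case file.
#' @param demographics list of marginal distributions; see defaults.
#' @param quarters character vector of quarter labels like `"23Q1"`.
#' @return validated list of class `faers_sim_config`.
#' @export
faers_sim_config <- function(
    seed = 1L,
    n_target_cases = 2000L,
    n_background_cases = 200000L,
    pt_dictionary = NULL,
    background_pt_rates = NULL,
    planted_signals = c("Asthmatic crisis" = 100, "Wheezing" = 16,
                        "Coronavirus infection" = 7, "Pneumonia" = 5,
                        "Headache" = 1.4),
    duplicate_rate = 0.10,
    bad_date_rate = 0.60,
    negative_interval_rate = 0.02,
    tto_shape = 0.70,
    tto_scale = 415.47,
    n_deleted = 0L,
    demographics = list(
      sex = c(F = 0.461, M = 0.214, unknown = 0.325),
      age_known = 0.289, age_child = 0.023,
      weight_known = 0.052,
      country_us = 0.558, country_unknown = 0.001,
      reporter = c(hp = 0.6728, consumer = 0.3145, unknown = 0.0126),
      outcome_none = 0.391,
      outcome = c(CA = 13, DE = 1379, DS = 119, HO = 6034, LT = 179,
                  OT = 9784, RI = 16)),
    quarters = c("22Q1", "22Q2", "22Q3", "22Q4",
                 "23Q1", "23Q2", "23Q3", "23Q4")) {
  if (is.null(pt_dictionary)) {
    prof <- default_pt_profile()
    pt_dictionary <- prof[, c("pt", "soc")]
    if (is.null(background_pt_rates)) {
      background_pt_rates <- stats::setNames(prof$rate, prof$pt)
    }
  }
  if (is.null(background_pt_rates)) {
    bad_field("background_pt_rates",
              "must be supplied when pt_dictionary is custom")
  }
  cfg <- list(seed = as.integer(seed),
              n_target_cases = as.integer(n_target_cases),
              n_background_cases = as.integer(n_background_cases),
              pt_dictionary = pt_dictionary,
              background_pt_rates = background_pt_rates,
              planted_signals = planted_signals,
              duplicate_rate = duplicate_rate,
              bad_date_rate = bad_date_rate,
              negative_interval_rate = negative_interval_rate,
              tto_shape = tto_shape, tto_scale = tto_scale,
              n_deleted = as.integer(n_deleted),
              demographics = demographics,
              quarters = quarters)
  validate_sim_config(cfg)
  structure(cfg, class = "faers_sim_config")
}

validate_sim_config <- function(cfg) {
  if (is.na(cfg$seed)) bad_field("seed", "must be an integer")
  if (cfg$n_target_cases < 1) bad_field("n_target_cases", "must be >= 1")
  if (cfg$n_background_cases < 1) {
    bad_field("n_background_cases", "must be >= 1")
  }
  if (!all(c("pt", "soc") %in% names(cfg$pt_dictionary))) {
    bad_field("pt_dictionary", "needs columns 'pt' and 'soc'")
  }
  r <- cfg$background_pt_rates
  if (is.null(names(r)) || !all(names(r) %in% cfg$pt_dictionary$pt)) {
    bad_field("background_pt_rates",
              "must be named by PTs present in pt_dictionary")
  }
  if (any(r < 0 | r > 1)) {
    bad_field("background_pt_rates", "probabilities must lie in [0,1]")
  }
  ps <- cfg$planted_signals
  if (length(ps) > 0) {
    missing_pt <- setdiff(names(ps), cfg$pt_dictionary$pt)
    if (length(missing_pt) > 0) {
      bad_field("planted_signals", paste0("PT not in pt_dictionary: ",
                                          paste(missing_pt, collapse = ", ")))
    }
    if (any(ps < 0)) bad_field("planted_signals", "multipliers must be >= 0")
  }
  for (f in c("duplicate_rate", "bad_date_rate", "negative_interval_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] >= 1) bad_field(f, "must lie in [0,1)")
  }
  if (cfg$tto_shape <= 0) bad_field("tto_shape", "must be > 0")
  if (cfg$tto_scale <= 0) bad_field("tto_scale", "must be > 0")
  if (cfg$n_deleted < 0 ||
      cfg$n_deleted >= cfg$n_target_cases + cfg$n_background_cases) {
    bad_field("n_deleted", "must be in [0, total cases)")
  }
  if (length(cfg$quarters) < 1 ||
      !all(grepl("^[0-9]{2}Q[1-4]$", cfg$quarters))) {
    bad_field("quarters", "labels must look like '23Q1'")
  }
  invisible(cfg)
}

#' Draw a rounded Weibull time-to-onset sample
#'
#' `n` nonnegative whole-day intervals from a Weibull distribution with the
#' given shape (beta) and scale (alpha, days), rounded to whole days.
#'
#' @param n sample size (>= 1).
#' @param shape Weibull shape beta (> 0).
#' @param scale Weibull scale alpha in days (> 0).
#' @param seed optional integer seed for reproducibility.
#' @return integer vector of length `n`.
#' @export
generate_tto_sample <- function(n, shape, scale, seed = NULL) {
  if (length(n) != 1 || is.na(n) || n < 1) stop("n must be >= 1")
  if (shape <= 0 || scale <= 0) {
    stop("Weibull shape and scale must be positive")
  }
  if (!is.null(seed)) set.seed(seed)
  as.integer(round(stats::rweibull(n, shape = shape, scale = scale)))
}

fmt_date <- function(d) format(d, "%Y%m%d")

# Corrupt a vector of YYYYMMDD strings: blank / YYYYMM / YYYY at the
# configured rate. Returns the corrupted strings.
corrupt_dates <- function(x, rate) {
  n <- length(x)
  bad <- stats::runif(n) < rate
  kind <- sample(c("blank", "ym", "y"), n, replace = TRUE,
                 prob = c(0.5, 0.3, 0.2))
  x[bad & kind == "blank"] <- ""
  x[bad & kind == "ym"] <- substr(x[bad & kind == "ym"], 1, 6)
  x[bad & kind == "y"] <- substr(x[bad & kind == "y"], 1, 4)
  x
}

#' Simulate a FAERS-like report universe in memory
#'
#' The workhorse behind [generate_faers()]: draws the full set of cases and
#' returns the six FAERS tables plus the deleted-case list and a truth
#' manifest, without touching the file system. Useful for fast replicate
#' studies.
#'
#' @param config a [faers_sim_config()].
#' @return list with data.frames `demo`, `drug`, `reac`, `ther`, `indi`,
#'   `outc`, character `deleted`, and `manifest` (true planted parameters
#'   and intended counts, the oracle for downstream tests).
#' @export
simulate_faers_tables <- function(config) {
  stopifnot(inherits(config, "faers_sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  dem <- config$demographics
  n_t <- config$n_target_cases
  n_b <- config$n_background_cases
  n <- n_t + n_b
  is_target <- c(rep(TRUE, n_t), rep(FALSE, n_b))
  caseid <- sprintf("%d", 100000000 + seq_len(n))

  ## -- case-level demography ------------------------------------------
  quarter <- sample(config$quarters, n, replace = TRUE)
  q_year <- 2000L + as.integer(substr(quarter, 1, 2))
  q_no <- as.integer(substr(quarter, 4, 4))
  fda_dt <- as.Date(sprintf("%d-%02d-%02d", q_year,
                            3L * (q_no - 1L) + sample(1:3, n, replace = TRUE),
                            sample(1:28, n, replace = TRUE)))
  sex <- sample(c("F", "M", ""), n, replace = TRUE, prob = dem$sex)
  age_known <- stats::runif(n) < dem$age_known
  child <- age_known & stats::runif(n) < dem$age_child
  age_years <- rep(NA_real_, n)
  age_years[child] <- stats::runif(sum(child), 0.2, 17.9)
  adult <- age_known & !child
  age_years[adult] <- pmin(pmax(stats::rnorm(sum(adult), 52, 18), 18), 95)
  age_val <- rep("", n); age_cod <- rep("", n)
  unit_pick <- stats::runif(n)
  yr <- age_known & (unit_pick < 0.90 | child)
  age_val[yr] <- sprintf("%d", round(age_years[yr]))
  age_cod[yr] <- "YR"
  infant <- child & age_years < 2
  age_val[infant] <- sprintf("%d", pmax(1, round(age_years[infant] * 12)))
  age_cod[infant] <- "MON"
  dec <- age_known & !child & unit_pick >= 0.90
  age_val[dec] <- sprintf("%d", round(age_years[dec] / 10))
  age_cod[dec] <- "DEC"
  wt_known <- stats::runif(n) < dem$weight_known
  wt <- rep("", n)
  wt[wt_known] <- sprintf("%.1f",
                          pmin(pmax(stats::rnorm(sum(wt_known), 75, 18),
                                    30), 160))
  wt_cod <- ifelse(wt_known, "KG", "")
  cpick <- stats::runif(n)
  country <- ifelse(cpick < dem$country_us, "US",
                    ifelse(cpick < 1 - dem$country_unknown,
                           sample(c("GB", "DE", "FR", "JP", "CA", "AU",
                                    "IT", "ES", "NL", "BR"),
                                  n, replace = TRUE), ""))
  rpick <- stats::runif(n)
  occp <- ifelse(rpick < dem$reporter["hp"],
                 sample(c("MD", "PH", "OT"), n, replace = TRUE,
                        prob = c(0.5, 0.2, 0.3)),
                 ifelse(rpick < dem$reporter["hp"] + dem$reporter["consumer"],
                        "CN", ""))

  ## -- therapy and event dates ----------------------------------------
  tto <- round(stats::rweibull(n, config$tto_shape, config$tto_scale))
  report_lag <- sample(0:90, n, replace = TRUE)
  event_date <- fda_dt - report_lag
  start_date <- event_date - tto
  neg <- stats::runif(n) < config$negative_interval_rate
  event_date[neg] <- start_date[neg] - sample(1:200, sum(neg), replace = TRUE)
  event_dt <- corrupt_dates(fmt_date(event_date), config$bad_date_rate)
  start_dt <- corrupt_dates(fmt_date(start_date), config$bad_date_rate)

  ## -- events: Bernoulli per PT, unique PTs per case by construction --
  rates <- config$background_pt_rates
  mult <- rep(1, length(rates))
  names(mult) <- names(rates)
  mult[names(config$planted_signals)] <- config$planted_signals
  # independent Bernoulli per (case, PT): marginal reporting rates are
  # exactly rate * multiplier, so record-level odds ratios recover the
  # planted multipliers. A case may draw no in-vocabulary event at all --
  # it then contributes demographics but no (case, PT) record.
  ev_case <- integer(0); ev_pt <- character(0)
  for (j in seq_along(rates)) {
    p_t <- min(rates[j] * mult[j], 0.95)
    p_b <- rates[j]
    hit <- c(stats::runif(n_t) < p_t, stats::runif(n_b) < p_b)
    idx <- which(hit)
    ev_case <- c(ev_case, idx)
    ev_pt <- c(ev_pt, rep(names(rates)[j], length(idx)))
  }
  ord <- order(ev_case, ev_pt)
  ev_case <- ev_case[ord]; ev_pt <- ev_pt[ord]

  ## -- drugs ------------------------------------------------------------
  drug_rows <- function(i) {
    if (is_target[i]) {
      n_conc <- stats::rpois(1, 0.8)
      name <- c(sample(target_name_variants, 1),
                if (n_conc > 0) sample(background_drug_pool, n_conc))
      role <- c("PS", if (n_conc > 0)
        sample(c("C", "SS", "I"), n_conc, replace = TRUE,
               prob = c(0.6, 0.3, 0.1)))
    } else {
      n_drug <- 1 + stats::rpois(1, 0.8)
      name <- sample(background_drug_pool, min(n_drug,
                                               length(background_drug_pool)))
      role <- c("PS", if (length(name) > 1)
        sample(c("C", "SS", "I"), length(name) - 1, replace = TRUE,
               prob = c(0.6, 0.3, 0.1)))
    }
    list(name = name, role = role)
  }
  dr <- lapply(seq_len(n), drug_rows)
  n_drugs <- vapply(dr, function(x) length(x$name), 1L)
  drug_case <- rep(seq_len(n), n_drugs)
  drug_seq <- unlist(lapply(n_drugs, seq_len), use.names = FALSE)
  drug_name <- unlist(lapply(dr, `[[`, "name"), use.names = FALSE)
  drug_role <- unlist(lapply(dr, `[[`, "role"), use.names = FALSE)

  indi_pt <- ifelse(is_target,
                    sample(target_indications, n, replace = TRUE),
                    sample(background_indications, n, replace = TRUE))

  ## -- outcomes ----------------------------------------------------------
  has_outc <- stats::runif(n) >= dem$outcome_none
  n_outc <- ifelse(has_outc, 1L + (stats::runif(n) < 0.15), 0L)
  oc_case <- rep(seq_len(n), n_outc)
  oc_cod <- unlist(lapply(which(n_outc > 0), function(i) {
    sample(names(dem$outcome), n_outc[i], replace = FALSE,
           prob = dem$outcome)
  }), use.names = FALSE)

  ## -- duplicate versions ------------------------------------------------
  dup <- stats::runif(n) < config$duplicate_rate
  n_version <- ifelse(dup, 2L, 1L)
  ver_case <- rep(seq_len(n), n_version)
  ver_no <- unlist(lapply(n_version, seq_len), use.names = FALSE)
  primaryid <- paste0(caseid[ver_case], ver_no)
  # duplicate versions perturb only the report date, never drugs or events
  ver_fda <- fda_dt[ver_case] + ifelse(ver_no == 2,
                                       sample(1:45, length(ver_no),
                                              replace = TRUE), 0)
  ver_quarter <- quarter[ver_case]

  demo <- data.frame(
    primaryid = primaryid,
    caseid = caseid[ver_case],
    caseversion = ver_no,
    fda_dt = fmt_date(ver_fda),
    event_dt = event_dt[ver_case],
    age = age_val[ver_case],
    age_cod = age_cod[ver_case],
    sex = sex[ver_case],
    wt = wt[ver_case],
    wt_cod = wt_cod[ver_case],
    occp_cod = occp[ver_case],
    occr_country = country[ver_case],
    quarter = ver_quarter,
    stringsAsFactors = FALSE
  )

  expand <- function(case_idx, ...) {
    # repeat child rows once per emitted version of their case
    reps <- n_version[case_idx]
    keep <- rep(seq_along(case_idx), reps)
    ver <- unlist(lapply(reps, seq_len), use.names = FALSE)
    cols <- lapply(list(...), function(x) x[keep])
    data.frame(primaryid = paste0(caseid[case_idx][keep], ver),
               caseid = caseid[case_idx][keep],
               cols, quarter = quarter[case_idx][keep],
               stringsAsFactors = FALSE)
  }
  drug <- expand(drug_case, drug_seq = drug_seq, role_cod = drug_role,
                 drugname = drug_name)
  reac <- expand(ev_case, pt = ev_pt)
  ps_seq <- rep(1L, n)  # PS drug is always drug_seq 1 by construction
  ther <- expand(seq_len(n), dsg_drug_seq = ps_seq, start_dt = start_dt,
                 end_dt = rep("", n))
  indi <- expand(seq_len(n), indi_drug_seq = ps_seq, indi_pt = indi_pt)
  outc <- expand(oc_case, outc_cod = oc_cod)

  deleted <- character(0)
  if (config$n_deleted > 0) {
    deleted <- sort(sample(caseid, config$n_deleted))
  }
  kept <- !(caseid %in% deleted)
  manifest <- list(
    seed = config$seed,
    n_cases_drawn = n,
    n_unique_cases = sum(kept),
    n_target_unique = sum(kept & is_target),
    n_demo_rows = nrow(demo),
    n_duplicate_cases = sum(dup),
    n_deleted = length(deleted),
    planted_signals = config$planted_signals,
    tto_shape = config$tto_shape,
    tto_scale = config$tto_scale,
    quarters = config$quarters
  )
  list(demo = demo, drug = drug, reac = reac, ther = ther, indi = indi,
       outc = outc, deleted = deleted, manifest = manifest)
}

write_faers_table <- function(df, path) {
  df <- df[, setdiff(names(df), "quarter"), drop = FALSE]
  body <- do.call(paste, c(unname(as.list(df)), sep = "$"))
  writeLines(c(paste(names(df), collapse = "$"), body), path)
}

#' Generate a FAERS-like quarterly file set on disk
#'
#' Writes one `$`-delimited DEMO/DRUG/REAC/THER/INDI/OUTC file per quarter
#' (named like `DEMO23Q1.txt`), a deleted-case list (`DELETED.txt`, one
#' caseid per line), the PT-to-SOC dictionary used (`meddra_dict.tsv`) and
#' a tab-separated truth manifest (`manifest.tsv`). Each case appears in
#' DEMO exactly once per emitted version; duplicate versions share a caseid
#' but have distinct primaryids. The same config (and seed) always produces
#' byte-identical files.
#'
#' @param config a [faers_sim_config()].
#' @param out_dir output directory, created if needed.
#' @return the truth manifest, invisibly (with `$dir` and `$files` added).
#' @export
generate_faers <- function(config, out_dir) {
  stopifnot(inherits(config, "faers_sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  sim <- simulate_faers_tables(config)
  files <- character(0)
  tables <- c("demo", "drug", "reac", "ther", "indi", "outc")
  for (q in config$quarters) {
    for (tb in tables) {
      df <- sim[[tb]]
      path <- file.path(out_dir, sprintf("%s%s.txt", toupper(tb), q))
      write_faers_table(df[df$quarter == q, , drop = FALSE], path)
      files <- c(files, path)
    }
  }
  writeLines(c("caseid", sim$deleted), file.path(out_dir, "DELETED.txt"))
  dict <- structure(list(version = "26.0-toy",
                         entries = config$pt_dictionary[, c("pt", "soc")],
                         soc_list = sort(unique(config$pt_dictionary$soc))),
                    class = "meddra_dictionary")
  write_meddra(dict, file.path(out_dir, "meddra_dict.tsv"))
  man <- sim$manifest
  man_lines <- c(
    "key\tvalue",
    sprintf("seed\t%d", man$seed),
    sprintf("n_cases_drawn\t%d", man$n_cases_drawn),
    sprintf("n_unique_cases\t%d", man$n_unique_cases),
    sprintf("n_target_unique\t%d", man$n_target_unique),
    sprintf("n_demo_rows\t%d", man$n_demo_rows),
    sprintf("n_duplicate_cases\t%d", man$n_duplicate_cases),
    sprintf("n_deleted\t%d", man$n_deleted),
    sprintf("tto_shape\t%g", man$tto_shape),
    sprintf("tto_scale\t%g", man$tto_scale),
    sprintf("planted:%s\t%g", names(man$planted_signals),
            man$planted_signals)
  )
  writeLines(man_lines, file.path(out_dir, "manifest.tsv"))
  man$dir <- out_dir
  man$files <- c(files, file.path(out_dir, c("DELETED.txt",
                                             "meddra_dict.tsv",
                                             "manifest.tsv")))
  invisible(man)
}
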