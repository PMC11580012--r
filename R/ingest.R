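# Reading "$"-delimited FAERS quarterly files, case deduplication by the
# highest-primaryid rule, deleted-case removal, target-drug selection and
# subgroup filtering. Nothing is dropped silently: every removal lands in
# an audit count.

#' Read one "$"-delimited FAERS table
#'
#' The dialect is a header row plus one record per line with `$` as the
#' field separator (no quoting or escaping: the dialect guarantees `$`
#' never occurs inside a field). Data rows whose field count does not match
#' the header are quarantined -- returned in the `quarantined` attribute
#' with their line numbers, and counted -- never silently dropped.
#'
#' @param path path to the file.
#' @return data.frame of character columns with attribute `quarantined`
#'   (data.frame `line`, `content`).
#' @export
read_faers_table <- function(path) {
  if (!file.exists(path)) stop("FAERS table file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0 || !nzchar(trimws(lines[1]))) {
    stop("missing header row in ", path)
  }
  header <- strsplit(lines[1], "$", fixed = TRUE)[[1]]
  body <- lines[-1]
  parts <- strsplit(body, "$", fixed = TRUE)
  # field count = separators + 1; strsplit drops trailing empty fields, so
  # count separators directly
  counted <- nchar(body) - nchar(gsub("$", "", body, fixed = TRUE)) + 1L
  counted[!nzchar(body)] <- 0L
  ok <- counted == length(header)
  quarantined <- data.frame(line = which(!ok) + 1L,
                            content = body[!ok],
                            stringsAsFactors = FALSE)
  parts <- parts[ok]
  cols <- lapply(seq_along(header), function(j) {
    vapply(parts, function(p) if (j <= length(p)) p[j] else "", "")
  })
  names(cols) <- header
  df <- as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
  attr(df, "quarantined") <- quarantined
  df
}

#' Read a quarterly FAERS file set
#'
#' @param dir directory holding `<TABLE><quarter>.txt` files.
#' @param quarter quarter label like `"23Q1"`.
#' @return named list of raw data.frames (`demo`, `drug`, `reac`, `ther`,
#'   `indi`, `outc`).
#' @export
read_faers_quarter <- function(dir, quarter) {
  tables <- c("demo", "drug", "reac", "ther", "indi", "outc")
  out <- lapply(tables, function(tb) {
    path <- file.path(dir, sprintf("%s%s.txt", toupper(tb), quarter))
    df <- read_faers_table(path)
    df$quarter <- rep(quarter, nrow(df))
    df
  })
  names(out) <- tables
  out
}

#' Read all quarters of a FAERS-style directory
#'
#' Quarters are discovered from the `DEMO<quarter>.txt` files unless given
#' explicitly. The deleted-case list (`DELETED.txt`, one caseid per line
#' under a header) is read if present.
#'
#' @param dir input directory.
#' @param quarters quarter labels to read, or `NULL` to discover.
#' @return list with the six row-bound raw tables, `deleted` (character
#'   caseids), `quarters`, and `audit` (quarantined row counts per table).
#' @export
read_faers_data <- function(dir, quarters = NULL) {
  if (!dir.exists(dir)) stop("input directory not found: ", dir)
  if (is.null(quarters)) {
    demo_files <- list.files(dir, pattern = "^DEMO[0-9]{2}Q[1-4]\\.txt$")
    quarters <- sort(sub("^DEMO(.*)\\.txt$", "\\1", demo_files))
  }
  if (length(quarters) == 0) {
    stop("no DEMO<quarter>.txt files found in ", dir)
  }
  per_q <- lapply(quarters, function(q) read_faers_quarter(dir, q))
  tables <- c("demo", "drug", "reac", "ther", "indi", "outc")
  out <- lapply(tables, function(tb) {
    do.call(rbind, lapply(per_q, `[[`, tb))
  })
  names(out) <- tables
  quarantined <- vapply(tables, function(tb) {
    sum(vapply(per_q, function(q) nrow(attr(q[[tb]], "quarantined")), 1L))
  }, 1L)
  deleted <- character(0)
  del_path <- file.path(dir, "DELETED.txt")
  if (file.exists(del_path)) {
    dl <- readLines(del_path)
    deleted <- trimws(dl[-1][nzchar(trimws(dl[-1]))])
  }
  out$deleted <- deleted
  out$quarters <- quarters
  out$audit <- list(quarantined_parse = quarantined)
  out
}

#' Deduplicate demographic records by the highest-primaryid rule
#'
#' FAERS cases accumulate versions: several primaryids share one caseid.
#' Exactly one record per caseid is retained -- the one with the
#' numerically largest primaryid; exact primaryid ties are broken in favour
#' of the last-read record and counted. Rows whose primaryid does not parse
#' as a number are quarantined, not dropped silently.
#'
#' @param demo raw DEMO data.frame with `primaryid` and `caseid` columns.
#' @return list with `demo` (deduplicated, sorted by caseid), `removed`
#'   (version rows dropped), `quarantined` (unparseable-primaryid rows),
#'   `ties` (tie-broken caseids).
#' @export
deduplicate_cases <- function(demo) {
  pid <- suppressWarnings(as.numeric(demo$primaryid))
  bad <- is.na(pid)
  quarantined <- demo[bad, , drop = FALSE]
  demo <- demo[!bad, , drop = FALSE]
  pid <- pid[!bad]
  # stable order by pid: for equal pids the later-read row wins
  ord <- order(pid)
  demo <- demo[ord, , drop = FALSE]
  pid <- pid[ord]
  keep <- !duplicated(demo$caseid, fromLast = TRUE)
  n_ties <- sum(vapply(split(pid, demo$caseid),
                       function(p) sum(p == max(p)) > 1, TRUE))
  out <- demo[keep, , drop = FALSE]
  out <- out[order(out$caseid), , drop = FALSE]
  rownames(out) <- NULL
  list(demo = out,
       removed = sum(!keep),
       quarantined = nrow(quarantined),
       quarantined_rows = quarantined,
       ties = n_ties)
}

restrict_children <- function(cs, keep_primaryid) {
  for (tb in c("drug", "reac", "ther", "indi", "outc")) {
    cs[[tb]] <- cs[[tb]][cs[[tb]]$primaryid %in% keep_primaryid, ,
                         drop = FALSE]
    rownames(cs[[tb]]) <- NULL
  }
  cs
}

#' Assemble a deduplicated case set from raw tables
#'
#' Applies [deduplicate_cases()] to DEMO, removes cases on the deleted
#' list, restricts the drug/reaction/therapy/indication/outcome tables to
#' the retained primaryids (referential integrity: no orphan child rows)
#' and derives typed demographic fields: `age_years` via [convert_age()],
#' `year` from the FDA receipt date, a normalised `sex` and a `reporter`
#' category from the occupation code.
#'
#' @param raw list from [read_faers_data()] (or the same shape built in
#'   memory).
#' @param deleted caseids to remove; defaults to `raw$deleted`.
#' @return object of class `faers_case_set`: list of tables plus an
#'   `audit` satisfying
#'   `rows_in = retained + removed_dedup + removed_deleted + quarantined`.
#' @export
case_set <- function(raw, deleted = raw$deleted %||% character(0)) {
  demo <- raw$demo
  for (col in c("fda_dt", "event_dt", "age", "age_cod", "sex", "wt",
                "occp_cod", "occr_country")) {
    if (is.null(demo[[col]])) demo[[col]] <- rep("", nrow(demo))
  }
  child_cols <- list(drug = c("drug_seq", "role_cod", "drugname"),
                     reac = "pt",
                     ther = c("dsg_drug_seq", "start_dt"),
                     indi = c("indi_drug_seq", "indi_pt"),
                     outc = "outc_cod")
  for (tb in names(child_cols)) {
    if (is.null(raw[[tb]])) {
      raw[[tb]] <- data.frame(primaryid = character(0), caseid = character(0),
                              stringsAsFactors = FALSE)
    }
    for (col in child_cols[[tb]]) {
      if (is.null(raw[[tb]][[col]])) {
        raw[[tb]][[col]] <- rep("", nrow(raw[[tb]]))
      }
    }
  }
  rows_in <- nrow(demo)
  dd <- deduplicate_cases(demo)
  demo <- dd$demo
  n_deleted <- sum(demo$caseid %in% deleted)
  demo <- demo[!(demo$caseid %in% deleted), , drop = FALSE]
  rownames(demo) <- NULL

  demo$age_years <- convert_age(demo$age, demo$age_cod)
  demo$year <- ifelse(grepl("^[0-9]{4}", demo$fda_dt),
                      as.integer(substr(demo$fda_dt, 1, 4)), NA_integer_)
  demo$sex <- ifelse(demo$sex %in% c("F", "M"), demo$sex, "unknown")
  demo$reporter <- ifelse(demo$occp_cod %in% c("MD", "PH", "OT", "HP"),
                          "health-professional",
                          ifelse(demo$occp_cod == "CN", "consumer",
                                 "unknown"))
  demo$weight_kg <- suppressWarnings(as.numeric(demo$wt))

  cs <- structure(
    list(demo = demo, drug = raw$drug, reac = raw$reac, ther = raw$ther,
         indi = raw$indi, outc = raw$outc,
         quarters = raw$quarters %||% unique(demo$quarter),
         audit = list(rows_in = rows_in,
                      retained = nrow(demo),
                      removed_dedup = dd$removed,
                      removed_deleted = n_deleted,
                      quarantined = dd$quarantined,
                      ties = dd$ties,
                      quarantined_parse = raw$audit$quarantined_parse %||%
                        NULL)),
    class = "faers_case_set")
  restrict_children(cs, demo$primaryid)
}

#' @export
print.faers_case_set <- function(x, ...) {
  a <- x$audit
  cat(sprintf(
    paste0("FAERS case set: %d cases (%d DEMO rows in; %d duplicate",
           " versions removed, %d deleted, %d quarantined)\n",
           "  drug rows: %d  event rows: %d  therapy rows: %d\n"),
    nrow(x$demo), a$rows_in, a$removed_dedup, a$removed_deleted,
    a$quarantined, nrow(x$drug), nrow(x$reac), nrow(x$ther)))
  invisible(x)
}

#' Remove cases on a deleted-case list
#'
#' Drops the listed caseids (and their drug/event/therapy rows) from an
#' assembled case set; the audit is updated. An empty list is valid and
#' leaves the set unchanged.
#'
#' @param cs a `faers_case_set`.
#' @param deleted_ids character caseids.
#' @return the filtered `faers_case_set`.
#' @export
remove_deleted <- function(cs, deleted_ids) {
  stopifnot(inherits(cs, "faers_case_set"))
  hit <- cs$demo$caseid %in% deleted_ids
  cs$demo <- cs$demo[!hit, , drop = FALSE]
  rownames(cs$demo) <- NULL
  cs$audit$removed_deleted <- cs$audit$removed_deleted + sum(hit)
  cs$audit$retained <- nrow(cs$demo)
  restrict_children(cs, cs$demo$primaryid)
}

#' Partition cases into target-drug and comparator arms
#'
#' A case is a target case iff at least one of its drug entries matches any
#' of the given names -- case-insensitively, whitespace-trimmed, as a
#' substring of the verbatim drug name (FAERS names carry dose and
#' formulation suffixes, so exact matching would silently lose cases) --
#' AND that entry's role is in `roles`. A case with several matching
#' entries counts once.
#'
#' @param cs a `faers_case_set`.
#' @param names nonempty character vector of drug names (generic + brands).
#' @param roles drug role codes that qualify; default primary suspect only.
#' @return object of class `faers_target`: list with `caseids`,
#'   `primaryids`, `matches` (primaryid, caseid, drug_seq of every
#'   qualifying drug entry) and `n_target`.
#' @export
select_target_cases <- function(cs, names, roles = "PS") {
  stopifnot(inherits(cs, "faers_case_set"))
  if (length(names) == 0 || all(!nzchar(trimws(names)))) {
    stop("target drug name list must be nonempty")
  }
  stopifnot(all(roles %in% c("PS", "SS", "C", "I")))
  dn <- tolower(trimws(cs$drug$drugname))
  hit <- rep(FALSE, length(dn))
  for (nm in tolower(trimws(names))) {
    hit <- hit | grepl(nm, dn, fixed = TRUE)
  }
  hit <- hit & cs$drug$role_cod %in% roles
  matches <- cs$drug[hit, c("primaryid", "caseid", "drug_seq"), drop = FALSE]
  rownames(matches) <- NULL
  caseids <- unique(matches$caseid)
  structure(list(caseids = caseids,
                 primaryids = unique(matches$primaryid),
                 matches = matches,
                 n_target = length(caseids)),
            class = "faers_target")
}

#' @export
print.faers_target <- function(x, ...) {
  cat(sprintf("target partition: %d cases (%d matching drug entries)\n",
              x$n_target, nrow(x$matches)))
  invisible(x)
}

#' Convert FAERS age value/unit pairs to years
#'
#' Unit codes: `DEC` decades, `YR` years, `MON` months, `WK` weeks
#' (52.1775 per year), `DY` days (365.25 per year), `HR` hours (8766 per
#' year). Unparseable values, unknown units, negative results and
#' implausible ages (> 120 years) all yield `NA`.
#'
#' @param age_value numeric or character vector of age values.
#' @param age_unit character vector of unit codes.
#' @return numeric vector of ages in years (`NA` where unusable).
#' @export
convert_age <- function(age_value, age_unit) {
  v <- suppressWarnings(as.numeric(age_value))
  u <- toupper(trimws(as.character(age_unit)))
  factor_per_unit <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1775,
                       DY = 1 / 365.25, HR = 1 / 8766)
  f <- factor_per_unit[u]
  years <- v * as.numeric(f)
  years[is.na(f) | is.na(v) | years < 0 | years > 120] <- NA_real_
  as.numeric(years)
}

#' Restrict a case set to a subgroup
#'
#' Retains the cases for which `predicate` (a function of the demographic
#' data.frame returning one logical per row; `NA` counts as `FALSE`) holds,
#' together with their drug/event/therapy rows. Downstream 2x2 tables built
#' from the filtered set use the filtered universe as reference: both the
#' target and the comparator arm are restricted to the stratum.
#'
#' @param cs a `faers_case_set`.
#' @param predicate function of the demo data.frame.
#' @return the filtered `faers_case_set` (audit field `subgroup_removed`
#'   added).
#' @export
filter_subgroup <- function(cs, predicate) {
  stopifnot(inherits(cs, "faers_case_set"), is.function(predicate))
  keep <- predicate(cs$demo)
  keep[is.na(keep)] <- FALSE
  removed <- sum(!keep)
  cs$demo <- cs$demo[keep, , drop = FALSE]
  rownames(cs$demo) <- NULL
  cs$audit$subgroup_removed <- removed
  cs$audit$retained <- nrow(cs$demo)
  restrict_children(cs, cs$demo$primaryid)
}
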