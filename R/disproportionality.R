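# Disproportionality statistics on drug x event 2x2 tables.
#
# The counting unit throughout is the unique (case, PT) pair: for one term
# at PT or SOC level,
#   a = target-drug records with the term,   b = target records without it,
#   c = comparator records with the term,    d = comparator records without.
# The target margin a + b is therefore constant across all terms of a run,
# which is the convention the bundled reference tables follow.

zcrit_ror <- 1.96   # two-sided 95% Woolf interval
zcrit_ebgm <- 1.64  # one-sided lower bound convention of the reference tables

#' Build the (case, PT) record set for a disproportionality run
#'
#' Collapses the event table of a deduplicated case set to unique
#' (caseid, PT) pairs, splits them into the target-drug and comparator arms,
#' and annotates each record with its primary SOC. SOC-level counting is
#' record-level: a case contributes one count per (case, PT) record whose PT
#' maps to the SOC, which preserves the constant target margin across SOC
#' rows. Unmapped PTs are kept (with `NA` SOC) and tallied.
#'
#' @param case_set a deduplicated [case_set()].
#' @param target a target partition from [select_target_cases()].
#' @param dictionary a `meddra_dictionary`, or `NULL` to skip SOC
#'   annotation (PT-level analyses only).
#' @return an object of class `event_records`: data.frame with columns
#'   `caseid`, `pt`, `soc`, `target`, plus attributes `N` (total record
#'   count) and `n_unmapped`.
#' @export
build_event_records <- function(case_set, target, dictionary = NULL) {
  stopifnot(inherits(case_set, "faers_case_set"),
            inherits(target, "faers_target"))
  ev <- case_set$reac
  if (nrow(ev) == 0) stop("case set has no event records")
  caseid <- case_set$demo$caseid[match(ev$primaryid, case_set$demo$primaryid)]
  rec <- unique(data.frame(caseid = caseid,
                           pt = trimws(ev$pt),
                           stringsAsFactors = FALSE))
  rec <- rec[nzchar(rec$pt), , drop = FALSE]
  rec$target <- rec$caseid %in% target$caseids
  if (!any(rec$target)) {
    stop("empty target arm: no event records for the target drug")
  }
  n_unmapped <- 0L
  if (!is.null(dictionary)) {
    soc <- map_pt(dictionary, rec$pt)
    n_unmapped <- attr(soc, "n_unmapped")
    rec$soc <- as.character(soc)
  } else {
    rec$soc <- NA_character_
  }
  rec <- rec[order(rec$caseid, rec$pt), , drop = FALSE]
  rownames(rec) <- NULL
  structure(rec, N = nrow(rec), n_unmapped = n_unmapped,
            class = c("event_records", "data.frame"))
}

#' Construct a 2x2 contingency table from explicit counts
#'
#' @param a,b,c,d nonnegative counts; `a` and `c` are term-positive records
#'   in the target and comparator arm respectively.
#' @param term term label.
#' @param level `"PT"` or `"SOC"`.
#' @return an object of class `contingency_2x2`.
#' @export
contingency <- function(a, b, c, d, term = "", level = c("PT", "SOC")) {
  level <- match.arg(level)
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("contingency counts must be nonnegative")
  }
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 c = as.numeric(c), d = as.numeric(d),
                 term = term, level = level),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("2x2 table [%s] %s: a=%g b=%g c=%g d=%g (N=%g)\n",
              x$level, x$term, x$a, x$b, x$c, x$d, x$a + x$b + x$c + x$d))
  invisible(x)
}

#' Build the 2x2 table for one term
#'
#' @param records an `event_records` set.
#' @param term PT or SOC name (matched case-insensitively).
#' @param level `"PT"` or `"SOC"`.
#' @return a `contingency_2x2`.
#' @export
build_table <- function(records, term, level = c("PT", "SOC")) {
  level <- match.arg(level)
  stopifnot(inherits(records, "event_records"))
  col <- if (level == "PT") records$pt else records$soc
  hit <- !is.na(col) & tolower(col) == tolower(trimws(term))
  if (!any(hit)) {
    stop(sprintf("unknown %s-level term: '%s'", level, term))
  }
  tgt <- records$target
  contingency(a = sum(hit & tgt), b = sum(!hit & tgt),
              c = sum(hit & !tgt), d = sum(!hit & !tgt),
              term = term, level = level)
}

# Vectorised core: all statistics from parallel count vectors. Counts are
# coerced to double up front -- FAERS-scale products overflow 32-bit
# integers. Zero cells yield NA estimates unless the Haldane correction is
# requested.
signal_stats <- function(a, b, c, d, correction = c("none", "haldane")) {
  correction <- match.arg(correction)
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  defined <- a > 0 & b > 0 & c > 0 & d > 0
  if (correction == "haldane") {
    adj <- !defined
    a[adj] <- a[adj] + 0.5; b[adj] <- b[adj] + 0.5
    c[adj] <- c[adj] + 0.5; d[adj] <- d[adj] + 0.5
    defined <- rep(TRUE, length(a))
  }
  N <- a + b + c + d
  ror <- prr <- chi2 <- ebgm <- se <- rep(NA_real_, length(a))
  i <- defined
  ror[i] <- (a[i] * d[i]) / (b[i] * c[i])
  se[i] <- sqrt(1 / a[i] + 1 / b[i] + 1 / c[i] + 1 / d[i])
  prr[i] <- (a[i] / (a[i] + b[i])) / (c[i] / (c[i] + d[i]))
  chi2[i] <- N[i] * (a[i] * d[i] - b[i] * c[i])^2 /
    ((a[i] + b[i]) * (c[i] + d[i]) * (a[i] + c[i]) * (b[i] + d[i]))
  ebgm[i] <- a[i] * N[i] / ((a[i] + b[i]) * (a[i] + c[i]))
  data.frame(
    a = a, b = b, c = c, d = d,
    ror = ror,
    ror_low = exp(log(ror) - zcrit_ror * se),
    ror_high = exp(log(ror) + zcrit_ror * se),
    prr = prr,
    chi2 = chi2,
    ebgm = ebgm,
    ebgm05 = exp(log(ebgm) - zcrit_ebgm * se),
    defined = defined
  )
}

#' Reporting odds ratio with Woolf 95% interval
#'
#' ROR = (a d)/(b c) with the Woolf log-scale interval
#' `exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. With any zero cell
#' the estimate is undefined and returned as `NA` with `defined = FALSE`;
#' no continuity correction is applied unless `correction = "haldane"`
#' (adds 0.5 to every cell of affected tables).
#'
#' @param table a `contingency_2x2`.
#' @param correction `"none"` (default) or `"haldane"`.
#' @return list with `est`, `low`, `high`, `defined`.
#' @export
ror <- function(table, correction = c("none", "haldane")) {
  stopifnot(inherits(table, "contingency_2x2"))
  s <- signal_stats(table$a, table$b, table$c, table$d, correction)
  list(est = s$ror, low = s$ror_low, high = s$ror_high, defined = s$defined)
}

#' Proportional reporting ratio with Pearson chi-squared
#'
#' PRR = `[a/(a+b)] / [c/(c+d)]`; the accompanying statistic is the Pearson
#' chi-squared without continuity correction,
#' `N (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`.
#'
#' @inheritParams ror
#' @return list with `prr`, `chi2`, `defined`.
#' @export
prr_chi2 <- function(table, correction = c("none", "haldane")) {
  stopifnot(inherits(table, "contingency_2x2"))
  s <- signal_stats(table$a, table$b, table$c, table$d, correction)
  list(prr = s$prr, chi2 = s$chi2, defined = s$defined)
}

#' Observed/expected (EBGM-style) ratio with lower bound
#'
#' The point estimate is the observed-to-expected reporting ratio
#' `a N / [(a+b)(a+c)]` -- the value a Gamma-Poisson shrinkage converges to
#' with negligible shrinkage at these cell sizes; a full DuMouchel MGPS fit
#' is deliberately not implemented (see the methods vignette). The lower
#' bound is the one-sided log-normal bound
#' `exp(ln EBGM - 1.64 sqrt(1/a + 1/b + 1/c + 1/d))`; the 1.64 multiplier
#' is the convention the bundled reference tables are computed under.
#'
#' @inheritParams ror
#' @return list with `ebgm`, `low`, `defined`.
#' @export
ebgm <- function(table, correction = c("none", "haldane")) {
  stopifnot(inherits(table, "contingency_2x2"))
  s <- signal_stats(table$a, table$b, table$c, table$d, correction)
  list(ebgm = s$ebgm, low = s$ebgm05, defined = s$defined)
}

#' Apply the signal criterion
#'
#' A term is a signal when it has at least `min_cases` target records and
#' the ROR 95% interval lower bound strictly exceeds 1. An undefined
#' estimate (zero cell without correction) is never a signal.
#'
#' @param result one row of an [analyze_all()] result, or any list/row with
#'   fields `a` and `ror_low`.
#' @param min_cases minimum target record count; conventional choices are
#'   100 for a full-database PT sweep and 3 for sparse subgroup sweeps.
#' @return logical.
#' @export
flag_signal <- function(result, min_cases = 1) {
  a <- result$a
  low <- result$ror_low
  !is.na(a) & a >= min_cases & !is.na(low) & low > 1
}

#' Sweep all terms at one MedDRA level
#'
#' Builds the 2x2 table of every PT (or SOC) present in the record set,
#' computes ROR/PRR/chi-squared/EBGM, applies the signal criterion and
#' returns terms with at least `min_cases` target records sorted by
#' descending ROR. All values are unrounded; presentation rounding belongs
#' to [format_signal_table()].
#'
#' @param records an `event_records` set.
#' @param level `"PT"` or `"SOC"`.
#' @param min_cases minimum target record count for inclusion.
#' @param correction zero-cell handling, see [ror()].
#' @param p_adjust multiple-testing adjustment for the chi-squared p-value
#'   column, passed to [stats::p.adjust()]; `"none"` (default) mirrors
#'   standard disproportionality practice.
#' @return data.frame of class `signal_results` with one row per term.
#' @export
analyze_all <- function(records, level = c("PT", "SOC"), min_cases = 1,
                        correction = c("none", "haldane"),
                        p_adjust = "none") {
  level <- match.arg(level)
  stopifnot(inherits(records, "event_records"))
  col <- if (level == "PT") records$pt else records$soc
  keep <- !is.na(col)
  if (!any(keep)) {
    out <- data.frame(term = character(0), level = character(0))
    class(out) <- c("signal_results", "data.frame")
    return(out)
  }
  col <- col[keep]
  tgt <- records$target[keep]
  n_target <- sum(records$target)
  n_comp <- sum(!records$target)
  counts_a <- tapply(tgt, col, sum)
  counts_c <- tapply(!tgt, col, sum)
  terms <- names(counts_a)
  a <- as.numeric(counts_a)
  c_ <- as.numeric(counts_c)
  s <- signal_stats(a, n_target - a, c_, n_comp - c_, correction)
  out <- cbind(data.frame(term = terms, level = level,
                          stringsAsFactors = FALSE), s)
  out$p <- stats::pchisq(out$chi2, df = 1, lower.tail = FALSE)
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  out$signal <- flag_signal(out, min_cases)
  out <- out[out$a >= min_cases, , drop = FALSE]
  out <- out[order(-out$ror, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("signal_results", "data.frame")
  out
}

#' Round a signal sweep for presentation
#'
#' Ratios and interval bounds to 2 decimals (half-up), chi-squared to 2
#' decimals with thousands separators, mirroring the layout of published
#' disproportionality tables. Only this function rounds; every analysis
#' function returns full precision.
#'
#' @param results a `signal_results` data.frame.
#' @return data.frame of formatted character columns.
#' @export
format_signal_table <- function(results) {
  stopifnot(inherits(results, "signal_results"))
  fmt2 <- function(x) sprintf("%.2f", round_half_up(x, 2))
  data.frame(
    term = results$term,
    a = results$a, b = results$b, c = results$c, d = results$d,
    `ROR (95% CI)` = sprintf("%s (%s-%s)", fmt2(results$ror),
                             fmt2(results$ror_low), fmt2(results$ror_high)),
    `PRR (chi2)` = sprintf("%s (%s)", fmt2(results$prr),
                           formatC(round_half_up(results$chi2, 2),
                                   format = "f", digits = 2, big.mark = ",")),
    `EBGM (lower bound)` = sprintf("%s (%s)", fmt2(results$ebgm),
                                   fmt2(results$ebgm05)),
    signal = results$signal,
    check.names = FALSE
  )
}
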