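# Closed-form expected values below were verified against the bundled
# reference tables (see test-acceptance.R for the full-table sweep).

test_that("ROR, PRR, chi2 and EBGM reproduce reference rows at printed precision", {
  # respiratory SOC row of the full-database sweep
  t1 <- contingency(16136, 66342, 1623032, 34149902, "resp", "SOC")
  r <- ror(t1)
  expect_equal(round_half_up(r$est, 2), 5.12)
  expect_equal(round_half_up(r$low, 2), 5.03)
  expect_equal(round_half_up(r$high, 2), 5.21)
  e <- ebgm(t1)
  expect_equal(round_half_up(e$ebgm, 2), 4.28)
  expect_equal(round_half_up(e$low, 2), 4.22)

  # strongest PT row (asthmatic crisis)
  t2 <- contingency(522, 81956, 2172, 35770762)
  expect_equal(round_half_up(ror(t2)$est, 2), 104.90)
  expect_equal(round_half_up(ror(t2)$low, 2), 95.31)
  expect_equal(round_half_up(ror(t2)$high, 2), 115.44)
  p <- prr_chi2(t2)
  expect_equal(round_half_up(p$prr, 2), 104.24)
  expect_equal(round_half_up(p$chi2, 2), 43034.77)
  e2 <- ebgm(t2)
  expect_equal(round_half_up(e2$ebgm, 2), 84.23)
  expect_equal(round_half_up(e2$low, 2), 77.75)
})

test_that("small tables match independent brute-force oracles to 1e-10", {
  set.seed(42)
  for (i in 1:200) {
    k <- sample(1:30, 4, replace = TRUE)
    a <- k[1]; b <- k[2]; c <- k[3]; d <- k[4]
    tab <- contingency(a, b, c, d)
    # oracles written independently of signal_stats()
    expect_equal(ror(tab)$est, (a / c) / (b / d), tolerance = 1e-10)
    expect_equal(prr_chi2(tab)$prr,
                 (a * (c + d)) / (c * (a + b)), tolerance = 1e-10)
    m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
    exp_counts <- outer(rowSums(m), colSums(m)) / sum(m)
    chi2_oracle <- sum((m - exp_counts)^2 / exp_counts)
    expect_equal(prr_chi2(tab)$chi2, chi2_oracle, tolerance = 1e-10)
    # and against the standard test statistic
    suppressWarnings(
      expect_equal(prr_chi2(tab)$chi2,
                   unname(stats::chisq.test(m, correct = FALSE)$statistic),
                   tolerance = 1e-10))
  }
})

test_that("ROR is invariant to (a<->d, b<->c); proportional rows null PRR and chi2", {
  tab <- contingency(12, 40, 300, 7000)
  swapped <- contingency(7000, 300, 40, 12)
  expect_equal(ror(tab)$est, ror(swapped)$est, tolerance = 1e-12)
  # row-proportional table: a/(a+b) == c/(c+d)
  null_tab <- contingency(10, 90, 50, 450)
  expect_equal(prr_chi2(null_tab)$prr, 1, tolerance = 1e-12)
  expect_equal(prr_chi2(null_tab)$chi2, 0, tolerance = 1e-9)
  expect_equal(ror(null_tab)$est, 1, tolerance = 1e-12)
})

test_that("EBGM satisfies the O/E identity ebgm * (a+c) * (a+b) = a * N", {
  set.seed(7)
  for (i in 1:50) {
    k <- sample(1:5000, 4, replace = TRUE)
    tab <- contingency(k[1], k[2], k[3], k[4])
    e <- ebgm(tab)$ebgm
    N <- sum(k)
    expect_equal(e * (k[1] + k[3]) * (k[1] + k[2]), k[1] * N,
                 tolerance = 1e-10)
  }
  # a equal to its expected count means O/E = 1
  tab <- contingency(10, 90, 100, 900)
  expect_equal(ebgm(tab)$ebgm, 1, tolerance = 1e-12)
})

test_that("zero cells yield flagged undefined estimates unless Haldane is requested", {
  tab <- contingency(0, 100, 50, 5000)
  r <- ror(tab)
  expect_false(r$defined)
  expect_true(is.na(r$est))
  rh <- ror(tab, correction = "haldane")
  expect_true(rh$defined)
  expect_true(is.finite(rh$est))
})

test_that("signal criterion: lower bound strictly above 1 with enough cases", {
  # SOC rows with published lower bounds either side of 1
  immune <- contingency(1136, 81342, 432311, 35340623)
  cardiac <- contingency(1222, 81256, 729526, 35043408)
  res_i <- c(list(a = 1136), ror(immune)[c("low")])
  names(res_i)[2] <- "ror_low"
  expect_true(flag_signal(res_i, min_cases = 1))
  res_c <- list(a = 1222, ror_low = ror(cardiac)$low)
  expect_false(flag_signal(res_c, min_cases = 1))
  # boundary: a lower bound of exactly 1 is not a signal
  expect_false(flag_signal(list(a = 500, ror_low = 1), min_cases = 1))
  # the case threshold gates otherwise-positive terms
  expect_false(flag_signal(list(a = 2, ror_low = 3), min_cases = 3))
})

test_that("event records count unique (case, PT) pairs against an enumeration oracle", {
  sim <- simulate_faers_tables(tiny_config(seed = 37, n_target = 150,
                                           n_background = 1200,
                                           duplicate_rate = 0.3))
  cs <- sim_case_set(sim)
  tg <- select_target_cases(cs, c("mepolizumab", "nucala"))
  rec <- build_event_records(cs, tg)
  brute <- unique(sim$reac[, c("caseid", "pt")])
  expect_equal(attr(rec, "N"), nrow(brute))
  # a repeated PT within one case contributes one record
  raw <- list(demo = data.frame(primaryid = "11", caseid = "1",
                                stringsAsFactors = FALSE),
              drug = data.frame(primaryid = "11", caseid = "1",
                                drug_seq = 1, role_cod = "PS",
                                drugname = "NUCALA",
                                stringsAsFactors = FALSE),
              reac = data.frame(primaryid = c("11", "11"),
                                caseid = c("1", "1"),
                                pt = c("Cough", "Cough"),
                                stringsAsFactors = FALSE))
  cs1 <- case_set(raw)
  tg1 <- select_target_cases(cs1, "nucala")
  expect_equal(attr(build_event_records(cs1, tg1), "N"), 1)
  # an empty target arm is an error
  tg_none <- select_target_cases(cs, "drug-that-does-not-exist")
  expect_error(build_event_records(cs, tg_none), "target arm")
})

test_that("per-term tables agree with the sweep and margins are conserved", {
  sim <- simulate_faers_tables(tiny_config(seed = 41, n_target = 120,
                                           n_background = 1000))
  cs <- sim_case_set(sim)
  tg <- select_target_cases(cs, c("mepolizumab", "nucala"))
  rec <- build_event_records(cs, tg)
  res <- analyze_all(rec, "PT", min_cases = 1)
  for (term in res$term) {
    tab <- build_table(rec, term, "PT")
    row <- res[res$term == term, ]
    expect_equal(c(tab$a, tab$b, tab$c, tab$d),
                 c(row$a, row$b, row$c, row$d))
    expect_equal(tab$a + tab$b + tab$c + tab$d, attr(rec, "N"))
  }
  # constant target margin across terms
  expect_true(all(res$a + res$b == sum(rec$target)))
  expect_error(build_table(rec, "Nonexistent term", "PT"), "unknown")
  # a term present only in the comparator arm has a = 0
  only_comp <- setdiff(unique(rec$pt[!rec$target]),
                       unique(rec$pt[rec$target]))
  if (length(only_comp) > 0) {
    expect_equal(build_table(rec, only_comp[1], "PT")$a, 0)
  }
  # min_cases above every a empties the sweep, sorting is by descending ROR
  expect_equal(nrow(analyze_all(rec, "PT", min_cases = 1e9)), 0)
  defined <- res[res$defined, ]
  expect_true(!is.unsorted(rev(defined$ror)))
})
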