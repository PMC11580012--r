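write_demo_file <- function(path, rows) {
  writeLines(c("primaryid$caseid$age$age_cod$sex", rows), path)
}

test_that("dollar-delimited parsing matches a naive line-split oracle", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "DEMO23Q1.txt")
  rows <- c("1001$10$45$YR$F", "1002$11$$YR$M", "1003$12$6$MON$",
            "broken$row", "1004$13$70$YR$F")
  write_demo_file(path, rows)
  df <- read_faers_table(path)
  expect_equal(nrow(df), 4)
  q <- attr(df, "quarantined")
  expect_equal(q$line, 5)   # 1-based file line of the malformed row
  expect_equal(q$content, "broken$row")
  # oracle: naive split on "$" (dialect guarantees no "$" inside fields),
  # padding the trailing empty fields strsplit drops
  split_pad <- lapply(strsplit(rows, "$", fixed = TRUE),
                      function(p) c(p, rep("", 5 - length(p))))
  nsep <- nchar(rows) - nchar(gsub("$", "", rows, fixed = TRUE))
  oracle <- do.call(rbind, split_pad[nsep == 4])
  for (j in 1:5) expect_equal(df[[j]], oracle[, j])
  expect_error(read_faers_table(file.path(dir, "nope.txt")), "not found")
})

test_that("trailing empty fields survive parsing", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "t.txt")
  writeLines(c("a$b$c", "1$$"), path)
  df <- read_faers_table(path)
  expect_equal(unname(unlist(df[1, ])), c("1", "", ""))
})

test_that("blank age fields propagate to missing age_years", {
  raw <- list(demo = data.frame(primaryid = c("11", "21"),
                                caseid = c("1", "2"),
                                age = c("", "45"), age_cod = c("", "YR"),
                                stringsAsFactors = FALSE))
  cs <- case_set(raw)
  expect_true(is.na(cs$demo$age_years[1]))
  expect_equal(cs$demo$age_years[2], 45)
})

test_that("deduplication keeps the numerically largest primaryid", {
  demo <- data.frame(primaryid = c("420001", "420002", "555"),
                     caseid = c("42", "42", "55"),
                     stringsAsFactors = FALSE)
  dd <- deduplicate_cases(demo)
  expect_equal(dd$demo$primaryid[dd$demo$caseid == "42"], "420002")
  expect_equal(dd$removed, 1)
  # idempotence
  dd2 <- deduplicate_cases(dd$demo)
  expect_identical(dd2$demo, dd$demo)
  expect_equal(dd2$removed, 0)
})

test_that("deduplication is order-independent and audits conserve rows", {
  sim <- simulate_faers_tables(tiny_config(seed = 9, n_target = 150,
                                           n_background = 1000,
                                           duplicate_rate = 0.3))
  demo <- sim$demo
  set.seed(1)
  shuffled <- demo[sample(nrow(demo)), ]
  a <- deduplicate_cases(demo)
  b <- deduplicate_cases(shuffled)
  expect_identical(a$demo, b$demo)

  cs <- sim_case_set(sim)
  au <- cs$audit
  expect_equal(au$rows_in,
               au$retained + au$removed_dedup + au$removed_deleted +
                 au$quarantined)
})

test_that("unparseable primaryids are quarantined, not dropped silently", {
  demo <- data.frame(primaryid = c("11", "xx", "21"),
                     caseid = c("1", "1", "2"), stringsAsFactors = FALSE)
  dd <- deduplicate_cases(demo)
  expect_equal(dd$quarantined, 1)
  expect_equal(nrow(dd$demo), 2)
})

test_that("deleted-case removal is exact set difference", {
  sim <- simulate_faers_tables(tiny_config(seed = 13, n_target = 100,
                                           n_background = 900))
  cs <- sim_case_set(sim)
  n0 <- nrow(cs$demo)
  expect_identical(remove_deleted(cs, character(0))$demo, cs$demo)

  planted <- sample(cs$demo$caseid, 50)
  cs2 <- remove_deleted(cs, planted)
  expect_equal(nrow(cs2$demo), n0 - 50)
  expect_false(any(cs2$demo$caseid %in% planted))
  # referential integrity: no orphan child rows
  for (tb in c("drug", "reac", "ther", "indi", "outc")) {
    expect_true(all(cs2[[tb]]$primaryid %in% cs2$demo$primaryid))
  }
  # degenerate: everything deleted is valid and flagged in the audit
  cs3 <- remove_deleted(cs, cs$demo$caseid)
  expect_equal(nrow(cs3$demo), 0)
  expect_equal(cs3$audit$removed_deleted, n0)
})

test_that("target selection is substring, case-folded and role-restricted", {
  raw <- list(
    demo = data.frame(primaryid = c("11", "21", "31"),
                      caseid = c("1", "2", "3"), stringsAsFactors = FALSE),
    drug = data.frame(primaryid = c("11", "21", "31", "31"),
                      caseid = c("1", "2", "3", "3"),
                      drug_seq = c(1, 1, 1, 2),
                      role_cod = c("PS", "C", "PS", "PS"),
                      drugname = c("NUCALA 100MG", "mepolizumab",
                                   "IBUPROFEN", "  Mepolizumab. "),
                      stringsAsFactors = FALSE))
  cs <- case_set(raw)
  tg <- select_target_cases(cs, c("mepolizumab", "nucala"))
  # case 1: brand substring + PS; case 2: name matches but role C;
  # case 3: one matching PS among several entries, counts once
  expect_setequal(tg$caseids, c("1", "3"))
  expect_equal(tg$n_target, 2)
  expect_error(select_target_cases(cs, character(0)), "nonempty")
})

test_that("age conversion follows FAERS unit codes with plausibility bounds", {
  expect_equal(convert_age(6, "MON"), 0.5)
  expect_equal(convert_age(7, "DEC"), 70)
  expect_equal(convert_age(2, "YR"), 2)
  expect_equal(convert_age(52.1775, "WK"), 1)
  expect_equal(convert_age(365.25, "DY"), 1)
  expect_equal(convert_age(8766, "HR"), 1)
  expect_true(is.na(convert_age(200, "YR")))   # implausible
  expect_true(is.na(convert_age(-5, "YR")))
  expect_true(is.na(convert_age("", "YR")))
  expect_true(is.na(convert_age(40, "")))
})

test_that("subgroup filtering matches a linear-scan oracle and keeps integrity", {
  sim <- simulate_faers_tables(tiny_config(seed = 17, n_target = 200,
                                           n_background = 1500))
  cs <- sim_case_set(sim)
  under18 <- function(d) !is.na(d$age_years) & d$age_years < 18
  sub <- filter_subgroup(cs, under18)
  oracle_n <- sum(vapply(seq_len(nrow(cs$demo)), function(i) {
    a <- cs$demo$age_years[i]
    !is.na(a) && a < 18
  }, TRUE))
  expect_equal(nrow(sub$demo), oracle_n)
  for (tb in c("drug", "reac", "ther")) {
    expect_true(all(sub[[tb]]$primaryid %in% sub$demo$primaryid))
  }
  expect_identical(filter_subgroup(cs, function(d) rep(TRUE, nrow(d)))$demo,
                   cs$demo)
  expect_equal(nrow(filter_subgroup(cs,
                                    function(d) rep(FALSE, nrow(d)))$demo),
               0)
})

test_that("quarter files read losslessly end to end", {
  cfg <- tiny_config(seed = 29, n_target = 50, n_background = 400)
  dir <- withr::local_tempdir()
  man <- generate_faers(cfg, dir)
  raw <- read_faers_data(dir)
  expect_equal(nrow(raw$demo), man$n_demo_rows)
  expect_setequal(raw$quarters, cfg$quarters)
  expect_error(read_faers_data(file.path(dir, "missing")), "not found")
})
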