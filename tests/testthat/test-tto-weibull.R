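make_tto_raw <- function(start, event) {
  n <- length(start)
  id <- as.character(seq_len(n) * 10 + 1)
  list(
    demo = data.frame(primaryid = id, caseid = as.character(seq_len(n)),
                      event_dt = event, stringsAsFactors = FALSE),
    drug = data.frame(primaryid = id, caseid = as.character(seq_len(n)),
                      drug_seq = 1, role_cod = "PS", drugname = "NUCALA",
                      stringsAsFactors = FALSE),
    ther = data.frame(primaryid = id, caseid = as.character(seq_len(n)),
                      dsg_drug_seq = 1, start_dt = start,
                      stringsAsFactors = FALSE))
}

tto_from <- function(start, event) {
  raw <- make_tto_raw(start, event)
  cs <- case_set(raw)
  tg <- select_target_cases(cs, "nucala")
  compute_tto(cs, tg)
}

test_that("onset days are calendar differences with audited exclusions", {
  res <- tto_from(
    start = c("20230101", "20230101", "202301", "", "20230601"),
    event = c("20230131", "20221201", "20230301", "20230301", ""))
  expect_equal(res$records$days, 30)
  au <- res$audit
  expect_equal(unname(au["candidates"]), 5)
  expect_equal(unname(au["usable"]), 1)
  expect_equal(unname(au["negative_interval"]), 1)
  expect_equal(unname(au["partial_date"]), 1)
  expect_equal(unname(au["missing_start"]), 1)
  expect_equal(unname(au["missing_event"]), 1)
  # conservation: candidates = usable + sum of exclusions
  expect_equal(unname(au["candidates"]),
               unname(au["usable"] + sum(au[c("missing_event",
                                              "partial_date",
                                              "missing_start",
                                              "negative_interval")])))
})

test_that("several therapy rows use the earliest full-precision start date", {
  raw <- make_tto_raw("20230301", "20230310")
  raw$ther <- rbind(raw$ther,
                    data.frame(primaryid = "11", caseid = "1",
                               dsg_drug_seq = 1, start_dt = "20230201",
                               stringsAsFactors = FALSE),
                    data.frame(primaryid = "11", caseid = "1",
                               dsg_drug_seq = 1, start_dt = "202301",
                               stringsAsFactors = FALSE))
  cs <- case_set(raw)
  tg <- select_target_cases(cs, "nucala")
  res <- compute_tto(cs, tg)
  expect_equal(res$records$days, as.integer(as.Date("2023-03-10") -
                                              as.Date("2023-02-01")))
})

test_that("non-target therapy rows do not contribute start dates", {
  raw <- make_tto_raw("20230101", "20230131")
  raw$drug <- rbind(raw$drug,
                    data.frame(primaryid = "11", caseid = "1",
                               drug_seq = 2, role_cod = "C",
                               drugname = "IBUPROFEN",
                               stringsAsFactors = FALSE))
  raw$ther <- rbind(raw$ther,
                    data.frame(primaryid = "11", caseid = "1",
                               dsg_drug_seq = 2, start_dt = "20220101",
                               stringsAsFactors = FALSE))
  cs <- case_set(raw)
  tg <- select_target_cases(cs, "nucala")
  expect_equal(compute_tto(cs, tg)$records$days, 30)
})

test_that("binning is closed on printed edges and matches brute force", {
  bins <- reference_tto_bins()
  days <- rep(c(0, 31, 61, 91, 181, 361), times = bins$count)
  s <- summarize_tto(days)
  expect_equal(s$bins$count, bins$count)
  expect_equal(round_half_up(s$bins$proportion[1], 3), 0.185)
  # edge membership: both ends inclusive, >360 means >= 361
  s2 <- summarize_tto(c(0, 30, 31, 60, 360, 361))
  expect_equal(s2$bins$count, c(2L, 2L, 0L, 0L, 1L, 1L))
  # all records at day zero land in the first bin
  s3 <- summarize_tto(rep(0, 5))
  expect_equal(s3$bins$proportion[1], 1)
  # uniform sample against a linear scan
  set.seed(3)
  u <- sample(0:400, 500, replace = TRUE)
  s4 <- summarize_tto(u)
  expect_equal(s4$bins$count[1], sum(u >= 0 & u <= 30))
  expect_equal(s4$bins$count[6], sum(u >= 361))
  expect_equal(sum(s4$bins$count), 500)
  expect_equal(s4$median, unname(stats::quantile(u, 0.5, type = 7)))
  expect_error(summarize_tto(integer(0)), "no time-to-onset")
})

test_that("Weibull MLE agrees with an independent fitter and is scale-equivariant", {
  x <- generate_tto_sample(2000, shape = 1.3, scale = 120, seed = 5)
  x[x == 0] <- 0.5
  f <- fit_weibull(x)
  g <- fitdistrplus::fitdist(as.numeric(x), "weibull")
  expect_equal(f$beta, unname(g$estimate["shape"]), tolerance = 1e-3)
  expect_equal(f$alpha, unname(g$estimate["scale"]), tolerance = 1e-3)
  # rescaling the sample by k scales alpha by k and leaves beta unchanged
  f3 <- fit_weibull(x * 3)
  expect_equal(f3$alpha, f$alpha * 3, tolerance = 1e-6)
  expect_equal(f3$beta, f$beta, tolerance = 1e-6)
  expect_error(fit_weibull(1:5), "at least 10")
})

test_that("exponential data give a shape interval covering 1", {
  x <- generate_tto_sample(2000, shape = 1, scale = 100, seed = 8)
  f <- fit_weibull(x)
  expect_true(f$beta_ci[1] < 1 && f$beta_ci[2] > 1)
  expect_equal(classify_failure(f), "random")
})

test_that("fitted point is a local likelihood maximum", {
  x <- generate_tto_sample(500, shape = 0.8, scale = 200, seed = 12)
  f <- fit_weibull(x)
  loglik_at <- function(alpha, beta) {
    sum(stats::dweibull(pmax(x, 0.5), shape = beta, scale = alpha,
                        log = TRUE))
  }
  set.seed(99)
  for (i in 1:100) {
    a <- f$alpha * exp(stats::rnorm(1, 0, 0.05))
    b <- f$beta * exp(stats::rnorm(1, 0, 0.05))
    expect_lte(loglik_at(a, b), f$loglik + 1e-8)
  }
})

test_that("shape estimates are nearly unbiased with calibrated interval coverage", {
  for (beta in c(0.5, 1, 2)) {
    est <- numeric(50)
    cover <- logical(50)
    for (k in 1:50) {
      # continuous draws isolate the estimator from day-rounding effects
      set.seed(7000 + 100 * beta + k)
      x <- stats::rweibull(2000, shape = beta, scale = 300)
      f <- fit_weibull(x)
      est[k] <- f$beta
      cover[k] <- f$beta_ci[1] <= beta && beta <= f$beta_ci[2]
    }
    expect_lt(abs(mean(est) - beta) / beta, 0.02)
    expect_gte(mean(cover), 0.90)
    expect_lte(mean(cover), 0.99)
  }
})

test_that("failure classification follows the shape-interval rule table", {
  fit <- function(beta, lo, hi) {
    structure(list(beta = beta, beta_ci = c(lo, hi)),
              class = "weibull_fit")
  }
  expect_equal(classify_failure(fit(0.70, 0.68, 0.72)), "early")
  expect_equal(classify_failure(fit(1.00, 0.90, 1.10)), "random")
  expect_equal(classify_failure(fit(1.40, 1.20, 1.60)), "wear-out")
  expect_equal(classify_failure(fit(1.60, 0.90, 2.80)), "indeterminate")
})
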