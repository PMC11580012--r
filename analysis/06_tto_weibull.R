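#!/usr/bin/env Rscript
# Stage 6: time to onset. Intervals run from the earliest full-precision
# therapy start of the target drug to the event date; partial dates,
# missing dates and negative intervals are excluded with audited reasons.
# The usable intervals are binned (0-30 ... >360 days) and fitted with a
# maximum-likelihood Weibull whose shape parameter classifies the hazard.

library(pvsignal)

dir <- file.path("results", "synthetic_faers")
cs <- case_set(read_faers_data(dir))
tg <- select_target_cases(cs, c("mepolizumab", "nucala"))

tto <- compute_tto(cs, tg)
cat("Exclusion audit:\n")
print(tto$audit)

s <- summarize_tto(tto$records$days)
print(s)
write.table(cbind(s$bins, n = s$n, median = s$median, q1 = s$q1,
                  q3 = s$q3),
            file.path("results", "tto_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

fit <- fit_weibull(tto$records$days)
print(fit)
write.table(data.frame(alpha = fit$alpha, alpha_low = fit$alpha_ci[1],
                       alpha_high = fit$alpha_ci[2], beta = fit$beta,
                       beta_low = fit$beta_ci[1],
                       beta_high = fit$beta_ci[2], n = fit$n,
                       failure_type = fit$failure_type),
            file.path("results", "weibull_fit.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(
  "\nThe generator drew onsets from Weibull(shape 0.70, scale 415.47 d);\n"))
cat(sprintf(
  "the fit recovers shape %.2f (%.2f-%.2f) -> '%s' hazard, falling with\n",
  fit$beta, fit$beta_ci[1], fit$beta_ci[2], fit$failure_type))
cat("time since treatment start, i.e. events cluster early in therapy.\n")
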