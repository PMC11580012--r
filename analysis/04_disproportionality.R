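#!/usr/bin/env Rscript
# Stage 4: disproportionality sweeps. Every unique (case, PT) record of the
# deduplicated universe enters a 2x2 table per term; ROR with Woolf 95% CI,
# PRR with Pearson chi-squared and the O/E (EBGM-style) ratio are computed
# at SOC level (unthresholded) and PT level (a >= 100, the main-analysis
# inclusion threshold).

library(pvsignal)

dir <- file.path("results", "synthetic_faers")
cs <- case_set(read_faers_data(dir))
tg <- select_target_cases(cs, c("mepolizumab", "nucala"))
dict <- read_meddra(file.path(dir, "meddra_dict.tsv"))
rec <- build_event_records(cs, tg, dict)
cat(sprintf("%d unique (case, PT) records (%d target, %d comparator)\n",
            attr(rec, "N"), sum(rec$target), sum(!rec$target)))

soc <- analyze_all(rec, "SOC", min_cases = 1)
pt <- analyze_all(rec, "PT", min_cases = 100)

write.table(format_signal_table(soc),
            file.path("results", "signals_soc.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(format_signal_table(pt),
            file.path("results", "signals_pt.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("\nSOC sweep: %d terms, %d signals\n", nrow(soc),
            sum(soc$signal)))
cat(sprintf("PT sweep (a >= 100): %d terms, %d signals\n", nrow(pt),
            sum(pt$signal)))
cat("\nTop PT signals (descending ROR):\n")
print(head(format_signal_table(pt[pt$signal, ]), 8), row.names = FALSE)
cat("\nThe planted respiratory/infection multipliers surface at the top;",
    "\nunplanted terms hover near ROR 1, as expected under independence.\n")
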