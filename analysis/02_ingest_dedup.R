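#!/usr/bin/env Rscript
# Stage 2: ingest the quarterly files, deduplicate by the
# highest-primaryid rule, drop deleted cases and select target-drug cases
# (generic or brand name substring, primary-suspect role only).

library(pvsignal)

dir <- file.path("results", "synthetic_faers")
raw <- read_faers_data(dir)
cs <- case_set(raw)
print(cs)

tg <- select_target_cases(cs, c("mepolizumab", "nucala"), roles = "PS")
print(tg)

audit <- data.frame(measure = names(cs$audit)[1:6],
                    value = unlist(cs$audit[1:6], use.names = FALSE))
write.table(audit, file.path("results", "ingest_audit.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf(
  "Audit conservation: %d rows in = %d retained + %d dedup + %d deleted + %d quarantined\n",
  cs$audit$rows_in, cs$audit$retained, cs$audit$removed_dedup,
  cs$audit$removed_deleted, cs$audit$quarantined))
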