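#!/usr/bin/env Rscript
# Stage 1: simulate a FAERS-like reporting universe at desk scale.
#
# The generator's defaults emulate the conditions of the reference
# mepolizumab analysis: published demographic margins, Weibull(shape 0.70,
# scale 415.47 d) onset intervals, ~60% unusable dates, and planted
# respiratory/infection signals. We scale the universe to 2,000 target and
# 50,000 background cases over eight quarters so the whole workflow runs
# in seconds.

library(pvsignal)

cfg <- faers_sim_config(seed = 1234,
                        n_target_cases = 2000,
                        n_background_cases = 50000,
                        duplicate_rate = 0.10,
                        n_deleted = 150)
dir <- file.path("results", "synthetic_faers")
man <- generate_faers(cfg, dir)

cat(sprintf("Simulated %d cases (%d target) across %d quarters into %s\n",
            man$n_cases_drawn, man$n_target_unique,
            length(cfg$quarters), dir))
cat(sprintf("DEMO rows emitted: %d (%d cases carry a duplicate version;",
            man$n_demo_rows, man$n_duplicate_cases),
    sprintf(" %d caseids on the deleted list)\n", man$n_deleted))
cat("Planted risk multipliers:\n")
print(man$planted_signals)
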