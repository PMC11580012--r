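---
title: "Methods: disproportionality, time-to-onset and the synthetic reporting universe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality, time-to-onset and the synthetic reporting universe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its statistical methods:
the models and the assumptions behind them, the parameters that matter,
the numerical choices, and what the synthetic data generator does and
does not emulate. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The counting unit

Everything downstream of ingest operates on **unique (case, PT) pairs**.
A case reporting the same preferred term twice contributes one record;
a case reporting four distinct terms contributes four. With this unit the
target margin `a + b` -- the total number of target-drug records -- is
constant across all rows of a sweep, at PT and SOC level alike, which is
the convention the bundled reference tables follow (their printed margins
are constant across rows). At SOC level a case contributes one count per
(case, PT) record whose PT maps to the SOC (*record-level* counting), so
SOC counts are exact sums of their PT counts. The alternative --
deduplicating per (case, SOC) -- would shrink SOC counts where one case
reports several PTs of the same class; the choice is isolated in
`build_event_records()` so it can be swapped without touching the
statistics.

## Disproportionality statistics

For a 2×2 table (a, b, c, d) with `N = a+b+c+d`:

* `ROR = ad/bc` with the Woolf interval
  `exp(ln ROR ± 1.96·se)`, `se = sqrt(1/a + 1/b + 1/c + 1/d)`;
* `PRR = [a/(a+b)]/[c/(c+d)]` with Pearson's
  `χ² = N(ad−bc)²/[(a+b)(c+d)(a+c)(b+d)]`, **without** Yates
  continuity correction -- the corrected variant does not reproduce the
  reference tables, the uncorrected one reproduces every cell;
* `EBGM = aN/[(a+b)(a+c)]`, the observed-to-expected reporting ratio,
  with the one-sided lower bound `exp(ln EBGM − 1.64·se)`.

Two conventions deserve comment.

**The 1.64 multiplier.** The usual one-sided 95% normal quantile is
1.645. Recomputing all 910 cells of the bundled reference tables shows
that 1.645 misses 17 of the 130 printed lower bounds by one unit in the
second decimal, always on the low side, while `z = 1.64` reproduces every
cell exactly at printed precision under half-up rounding. The package
therefore uses 1.64 as the convention of record for this bound. The
difference is confined to the third decimal of the bound and has no
effect on any signal decision.

**"EBGM" without shrinkage.** A full DuMouchel Gamma-Poisson (MGPS) fit
shrinks observed/expected ratios toward the prior, noticeably so for
small counts. The reference values are numerically the *unshrunk* O/E
ratios, so that is what the package implements, under the name the field
uses for this column. The divergence matters below roughly a = 10, where
a true MGPS estimate would be visibly smaller; users needing shrinkage
should treat `ebgm` here as the raw O/E statistic it is.

**Zero cells.** With any empty cell the estimates are undefined and
returned as `NA` with `defined = FALSE`; no continuity correction is
applied by default because the reference tables contain none. An optional
Haldane mode (`correction = "haldane"`, +0.5 to every cell of affected
tables) exists for exploratory use.

**Signal criterion and thresholds.** A term is flagged when its ROR
interval lower bound strictly exceeds 1 (a bound of exactly 1 is not a
signal) and it reaches the inclusion threshold on `a`: 100 for the
full-database PT sweep, 3 for the pediatric PT sweep, none for SOC
sweeps. No multiple-testing adjustment is applied by default, mirroring
standard disproportionality practice; `analyze_all(p_adjust =
"bonferroni")` adjusts the χ² p-value column for users who want it.

**Rounding.** Analysis functions return full precision; only
`format_signal_table()` rounds, to 2 decimals half-away-from-zero
(`round_half_up()`), because that is the convention under which published
tables of this kind are printed and compared.

## Ingest rules

* **Deduplication** keeps, per caseid, the record with the numerically
  largest primaryid. Exact ties are broken in favour of the last-read
  record and counted in the audit -- ties cannot occur in well-formed
  extracts, but a rule must exist. Unparseable primaryids are
  quarantined, not dropped. The audit satisfies
  `rows_in = retained + removed_dedup + removed_deleted + quarantined`.
* **Target selection** matches drug names case-insensitively as
  substrings of the verbatim `drugname` (FAERS names carry dose and
  formulation suffixes; exact matching silently loses cases), restricted
  to the primary-suspect role by default.
* **Partial dates** (`YYYYMM`, `YYYY`) are treated as missing for all
  interval arithmetic but are distinguished from blanks in exclusion
  audits. Calendar tabulation of report years uses the FDA receipt date,
  which is always full-precision.
* **Subgroups** rebuild the reference universe inside the stratum: both
  the target and the comparator arm are restricted, so subgroup margins
  are stratum totals, not inherited from the full database.
* **Age** conversion uses DEC×10, YR×1, MON÷12, WK÷52.1775, DY÷365.25,
  HR÷8766, with results below 0 or above 120 years set to missing.
  Weight is taken as kilograms as reported.

## Time-to-onset and the Weibull fit

Onset is the day count from the **earliest full-precision start date**
of a matching target-drug therapy row to the case's event date. Cases are
excluded with exactly one audited reason, checked in a fixed order:
missing event date, partial date (event or all starts), no start date,
negative interval. The six bins are closed on both printed ends (0-30
means 0 ≤ d ≤ 30; >360 means d ≥ 361); quartiles use the
linear-interpolation convention (`quantile(type = 7)`).

The Weibull log-likelihood
`Σ[ln β − β ln α + (β−1) ln t − (t/α)^β]` is maximised by damped Newton
iteration on `(ln α, ln β)` with analytic gradient and Hessian, started
from the Gumbel moment estimator of the log-transformed sample, to a
gradient norm below 1e-8. The line search accepts a step when the
likelihood does not decrease beyond `1e-10·(1+|loglik|)`; an absolute
tolerance there would sit below floating-point noise for samples in the
thousands and stall the final micro-steps. Confidence intervals are Wald
intervals from the observed Fisher information on the log scale,
transformed back -- they respect positivity and match the symmetric
intervals conventionally reported for this analysis; profile-likelihood
intervals were not needed at these sample sizes.

**Same-day events** are kept and offset to 0.5 days so the continuous
likelihood is defined; excluding them would bias the shape upward,
and the first onset bin clearly includes day 0. Note that day-rounding
itself (a generator property) mildly inflates fitted shapes when the
scale is small relative to one day; the estimator-correctness tests
therefore use continuous draws, while recovery tests at the reference
scale (hundreds of days) are unaffected.

**Failure classification** from the shape interval: `early` when the
upper bound is below 1, `wear-out` when the lower bound is above 1,
`random` when the interval contains 1 and the point estimate lies in
[0.8, 1.25] (a symmetric band on the log scale), `indeterminate` when
the interval contains 1 but the estimate is far from it -- a wide,
uninformative fit should not be read as "constant hazard".

## The synthetic reporting universe

`faers_sim_config()` defaults emulate the study conditions of the
reference mepolizumab analysis at desk scale:

* demographic margins follow the published distribution (46.1% female,
  71.1% age unspecified, 2.3% of known ages under 18, 67.28%
  health-professional reporters, 55.8% US, outcome mix dominated by
  hospitalisation and "other");
* onset intervals are Weibull with shape 0.70 and scale 415.47 days;
* 60% of therapy/event dates are emitted unusable (blank, `YYYYMM`, or
  `YYYY` -- the real FAERS partial-date dialects), chosen so that about
  `0.4² ≈ 16%` of cases carry two usable dates, matching the published
  usable-onset fraction (3,827 of 24,156 cases);
* 10% of cases are emitted as two caseid versions that differ only in
  primaryid and report date, making the highest-primaryid rule
  observable but harmless;
* per-PT baseline rates are proportional to the comparator counts of the
  bundled PT-level reference table, scaled to two records per background
  case on average, so rare terms stay rare in realistic proportion;
* planted risk multipliers (defaults: asthmatic crisis ×100, wheezing
  ×16, coronavirus infection ×7, pneumonia ×5, headache ×1.4) multiply
  the per-PT rate in target cases.

Events are independent Bernoulli draws per (case, PT), so marginal
reporting rates are exactly `rate × multiplier` and record-level odds
ratios recover the planted multipliers; a case may draw no in-vocabulary
event at all, in which case it contributes demographics but no analysis
record (interpretable as a case whose events fall outside the toy
vocabulary). An earlier design that forced at least one PT per case was
rejected: conditioning on non-emptiness inflates every rate by the
inverse acceptance probability and distorts planted effects whenever the
vocabulary is small.

What the generator does **not** emulate -- and hence what passing tests
do not show about real data: correlation between events within a case
(real PTs co-occur in syndromes), reporting-rate drift across quarters,
indication-driven channeling (target cases receive asthma indications
but events are drawn independently of them), verbatim-to-PT coding noise,
and narrative text. The toy dictionary covers 68 PTs in 13 SOCs, not a
licensed MedDRA release; real analyses plug in their own dictionary file.

Problem sizes: the analysis workflow simulates 2,000 target and 50,000
background cases over eight quarters; test replicate studies use a few
hundred to a few thousand cases per replicate with a six-term
vocabulary, and the null-coverage property uses 100 seeded end-to-end
replicates. These sizes give Monte-Carlo errors comfortably inside the
asserted tolerances while keeping the workflow interactive.

## Known limitations

* Disproportionality measures reporting association, not incidence or
  causation; no exposure denominators exist in spontaneous data.
* The EBGM column is the unshrunk O/E ratio (above); small-count rows
  are not shrunk toward 1.
* The per-(case, PT) record-level SOC counting is a convention, not a
  discovery; the alternative per-(case, SOC) deduplication is a
  one-function change.
* The deleted-case list removes whole cases only; linkage of follow-up
  versions beyond the max-primaryid rule, E2B XML ingestion and
  indication-based filtering are out of scope (the INDI table is read
  and carried, not analysed).
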