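# pvsignal

Disproportionality-based adverse event signal detection for spontaneous
reporting data shaped like the FDA Adverse Event Reporting System (FAERS),
built around the post-marketing safety profile of mepolizumab (an
anti-IL-5 monoclonal antibody for severe eosinophilic asthma). The package
is for pharmacovigilance analysts who work with FAERS-style quarterly
ASCII extracts and want a tested, reproducible path from raw files to
signal tables, plus a synthetic report generator so every stage can be
validated without downloading the real database.

## What it computes

For a target drug against all other drugs in the same database, each
MedDRA term (preferred term PT, or system organ class SOC) gets a 2×2
table over unique (case, PT) records:

|                | term present | term absent |
|----------------|--------------|-------------|
| target drug    | a            | b           |
| all other drugs| c            | d           |

* **ROR** (reporting odds ratio) = `ad / bc`, with the Woolf 95% interval
  `exp(ln ROR ± 1.96 √(1/a + 1/b + 1/c + 1/d))`. A term is a **signal**
  when the interval's lower bound strictly exceeds 1 and the term has at
  least a minimum number of target records (100 for the full-database PT
  sweep, 3 for the sparse pediatric sweep).
* **PRR** (proportional reporting ratio) = `[a/(a+b)] / [c/(c+d)]`, with
  the Pearson χ² statistic `N(ad−bc)² / [(a+b)(c+d)(a+c)(b+d)]` (no
  continuity correction).
* **EBGM-style ratio** = observed/expected `aN / [(a+b)(a+c)]`, with the
  one-sided lower bound `exp(ln EBGM − 1.64 √(1/a + 1/b + 1/c + 1/d))`
  (see the methods vignette for why 1.64).

Time-to-onset analysis takes the days from the earliest full-precision
therapy start date (THER.START_DT) to the event date (DEMO.EVENT_DT),
tabulates the conventional six bins (0–30 … >360 days), and fits a
Weibull distribution by maximum likelihood. A shape parameter β whose 95%
interval lies below 1 indicates an *early failure* hazard: adverse events
cluster soon after treatment start.

Ingest handles the FAERS realities along the way: `$`-delimited quarterly
files, duplicate case versions resolved by the highest primaryid, the
FDA deleted-case list, partial (`YYYYMM`/`YYYY`) dates, free-text drug
names matched by substring, and age unit codes (DEC/YR/MON/WK/DY/HR).

## Worked example

The `analysis/` directory is a numbered workflow over the package. Stage 1
simulates a desk-scale reporting universe (2,000 target and 50,000
background cases, planted risk multipliers on five terms); stages 2–6
ingest, describe, sweep and fit it; stage 7 validates the closed forms
against the bundled reference tables.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/04_disproportionality.R
```

prints (abridged):

```
Simulated 52000 cases (1992 target) across 8 quarters into results/synthetic_faers
...
Top PT signals (descending ROR):
             term   a    b    c     d         ROR (95% CI)       PRR (chi2)  EBGM (lower bound) signal
 Asthmatic crisis 203 5261   51 99933 75.61 (55.55-102.91) 72.84 (2,894.79)       15.42 (11.92)   TRUE
         Wheezing 495 4969  700 99284  14.13 (12.55-15.91) 12.94 (3,231.10)         7.99 (7.24)   TRUE
        Pneumonia 855 4609 4209 95775     4.22 (3.90-4.57)  3.72 (1,482.64)         3.26 (3.05)   TRUE
```

The planted multipliers (100, 16, 5 for these three terms) surface in
rank order; the ROR estimates sit within Monte-Carlo error of the
record-level odds ratios implied by the planted rates, while unplanted
terms hover near 1. Stage 6 refits the onset model:

```
Weibull fit (n=279): scale 433.70 (95% CI 365.55-514.55), shape 0.72 (95% CI 0.66-0.79)
failure type: early
```

recovering the generating parameters (shape 0.70, scale 415.47 days) and
classifying the hazard as early failure. Stage 7 reports
`910 / 910 published cells reproduced at printed precision` and lists the
six SOCs flagged by the signal criterion.

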