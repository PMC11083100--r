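# cepa — Censored Event Precedence Analysis

`cepa` answers a question that comes up whenever a cohort records several
time-to-event outcomes per subject under right censoring: **in what order
do the events tend to occur?** Its motivating use case is neonatal
claims data — first diagnoses of disease groups over a subject's first
year, where an event unobserved within the window is censored — but the
machinery applies to any small set of censored event times on a common
clock. Naive answers (drop censored subjects, or compare observed times
as if censoring times were event times) are both biased; `cepa` instead
estimates the full joint density of each event-time pair, censored
observations included, and derives precedence from it.

## The model

For each pair of events, the joint density of $(T_1, T_2)$ is estimated
with an **optional Pólya tree** (OPT): the sample space is recursively
bisected, and the marginal likelihood of a region $A$ obeys

```
Phi(A) = 1/2 Phi0(A) + 1/4 * sum_{i=1,2} B'(N(A_i1), N(A_i2)) Phi(A_i1) Phi(A_i2)
```

with `Phi0(A) = area(A)^-N(A)` the uniform ("stop") branch and
`B'(x, y) = B(x+1/2, y+1/2) / B(1/2, 1/2)` the Beta weight of a split
into halves with counts `x` and `y`. Censored observations cannot be
counted directly, so counts are *expected* counts under the current
density estimate, iterated EM-style to a fixed point: the E-step
allocates each censored sample over the tail it is known to lie in, the
M-step refits the posterior-mean piecewise density.

From the fitted densities:

* `Pr(T_i < T_j)` — integral of the pair's density below the diagonal
  (**precedence probability**);
* sequence likelihood — product of the pairwise probabilities an ordering
  implies, scored as `-log10 L` (lower = more probable), with "valid"
  sequences within 2% of the best score;
* a **precedence network** — directed edges along valid sequences, with a
  bidirectional edge when a pair's probability is within 5 points of
  50% (no practical priority);
* survival summaries — Kaplan–Meier and OPT marginal curves, overall vs
  observed median onset, and diagnosis-gap profiles after an anchor
  event.

## Worked example

A synthetic cohort stands in for the real claims data (which cannot be
redistributed): 1000 subjects, 7 events on a 1–52 week grid with
censoring sentinel 53 — an early anchor (`RESP`), dependent followers
(`SKIN`, `DIGE`, `EAR`), and independent events (`INFE`, `EYE`, `INJU`).

```r
library(cepa)
spec   <- cohort_spec(n_subjects = 1000, seed = 7)
tab    <- generate_cohort(spec)          # long format: subject, event, week, status
report <- run_cohort_analysis(tab)       # 21 pairwise fits + ranking + network

report$summary
#>   event censoring_rate median_overall median_observed
#> 1  DIGE          0.190             17              15
#> 2   EAR          0.164             17              16
#> 3   EYE          0.163             27              21
#> 4  INFE          0.048             11              10
#> 5  INJU          0.242             42              27
#> 6  RESP          0.011              6               6
#> 7  SKIN          0.072             10               9

head(report$ranking, 2)
#>                                                order log10_likelihood    score     rate
#> 1 RESP -> SKIN -> INFE -> DIGE -> EAR -> EYE -> INJU        -2.914578 2.914578 0.000000
#> 2 RESP -> SKIN -> INFE -> EAR -> DIGE -> EYE -> INJU        -2.986668 2.986668 2.473418

report$network
#> <precedence network: 7 nodes, 6 edges>
#>   RESP -> SKIN (p = 0.97)
#>   SKIN <-> INFE (p = 0.54)
#>   INFE -> DIGE (p = 0.64)
#>   DIGE <-> EAR (p = 0.54)
#>   EAR -> EYE (p = 0.58)
#>   EYE -> INJU (p = 0.59)

report$precedence["RESP", "INJU"]
#> [1] 0.8826461
```

Reading the output: the anchor event's overall and observed medians
coincide (censoring 1%), while heavily censored late events (`INJU`,
24%) show the overall median pushed far above the observed one. The
best-scoring sequence starts at the anchor; `SKIN` and `INFE` form a
bidirectional pair (54% — no practical priority), and a subject with a
`RESP` diagnosis has an 88% estimated chance of it preceding any
eventual `INJU` diagnosis. A report is serialised with
`write_cepa_report(report, "out/")` (CSV tables, GraphML/DOT network,
JSON metadata). A thin CLI over the same functions ships in
`inst/cli/cepa.R` (`simulate`, `cohort-synth`, `cohort-run`, `rank`).

The simulation benchmark compares CEPA against a censoring-blind
comparator on generated trivariate chains:

```r
b <- run_benchmark("uniform", n_samples = 500, n_reps = 20, seed = 101)
attr(b, "summary")
#>   method      mean       q25    median       q75
#> 1   cepa 0.7030341 0.6797644 0.7065336 0.7323647
#> 2  naive 0.6075000 0.5950000 0.6090000 0.6235000
```

The metric is the probability mass assigned to the true order
`T1 -> T2 -> T3`; CEPA's advantage comes entirely from handling the
~50% of coordinates that are censored.

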