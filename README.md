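# ccr5flux

Case-control association and monocyte calcium-flux analysis for the CCR5
promoter polymorphism **rs1799987 (-2459 A>G)** in Löfgren's syndrome — an
acute, usually self-remitting phenotype of sarcoidosis.

The package is aimed at researchers who want to reproduce, stress-test or
extend this kind of combined genetic + cytometric + functional study. It
implements three analysis stages behind one tidyverse-style API (data frames
in, tibbles out, `tidy()`/`glance()` on fitted results, `autoplot()` on
traces), plus a synthetic-data generator that emulates the study conditions
so everything is testable without patient data:

1. **Genetics** — allele/genotype/carriership tabulation, Hardy–Weinberg
   equilibrium, Pearson χ² association (no continuity correction), and odds
   ratios with Wald 95% CIs:
   `OR = ad/bc`, `CI = exp(log OR ± 1.96·√(1/a + 1/b + 1/c + 1/d))`.
2. **Flow gating / expression** — FSC/SSC → CD14 gating, isotype-anchored
   positivity threshold (default: 99.5th percentile of the matched isotype
   control), % CCR5⁺ and median fluorescence intensity (MFI) on gated
   monocytes, and classical/intermediate/non-classical subset labels.
3. **Calcium kinetics** — binned fluo-4 traces (per-bin median), frame
   summaries as time-normalised trapezoidal area under the curve
   (AUC/time), per-run baseline-net responses
   `net = AUC/time(response) − AUC/time(baseline)`, positive-control
   normalisation `relative = net(MIP-1α) / net(fMLP)`, responder
   classification (`net > k · robust SD` of baseline bins, k = 3), and the
   genotype × responder χ² test.

Group comparisons (Mann–Whitney U with exact tie-aware p-values,
Kruskal–Wallis, one-way ANOVA, Bonferroni post-hoc) are included as the
statistical layer used downstream of stages 2–3.

See `vignettes/methods.Rmd` for the full model description, parameter
defaults and design decisions.

## Worked example

The published genotype and responder count tables ship as plain-text
fixtures; every statistic printed alongside them is recomputed:

```r
library(ccr5flux)

rep <- reproduce_printed_tables()
rep$association$allele_or
#> OR = 1.680, 95% CI 1.22-2.32
rep$association$carrier_or
#> OR = 2.257, 95% CI 1.31-3.88
rep$responder_test
#> Pearson chi-square (no continuity correction)
#>   X-squared = 7.255, df = 2, p = 0.02659
hwe_test(92, 115, 50)     # control genotype counts
#> Hardy-Weinberg equilibrium chi-square (df = 1)
#>   X-squared = 1.665, df = 1, p = 0.1969
```

So: G-allele carriage is associated with the syndrome (allelic OR 1.68,
carriership OR 2.26, both CIs excluding 1), while the control genotypes are
consistent with Hardy–Weinberg equilibrium (p ≈ 0.20), and the calcium
responder distribution differs by genotype (χ² = 7.3, p = 0.027).

A fully synthetic end-to-end run — simulate a cohort at the study-anchored
defaults, then push it through every stage:

```r
scores <- kinetic_cohort_scores(rep(c("AA", "AG", "GG"), each = 7), seed = 99)
dplyr::summarise(scores,
                 med_net = median(net_mip),
                 med_rel = median(relative_response),
                 .by = genotype)
#>   genotype med_net  med_rel
#> 1 AA        23.9    0.387
#> 2 AG        16.4    0.240
#> 3 GG        -0.116 -0.00150
```

The AA and AG medians recover the generator's published-value anchors
(23.25 / 16.35 net; 0.38 / 0.24 relative); the GG median sits near zero
because only ~1 of 7 GG subjects responds, so the genotype median is a
non-responder — the responder *table*, not the median, carries the GG
signal. `run_pipeline(run_config(seed = ...), out_dir = ...)` wraps the
whole study (association report, expression summaries, kinetic scores,
responder test) and writes CSV/TSV/JSON outputs plus a YAML config echo;
`inst/cli/ccr5flux.R` exposes `simulate`, `genetics`, `run-all` and
`reproduce-printed` subcommands for shell use.

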