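# caosc — automated analysis of egg-activation calcium oscillations

Mammalian eggs respond to fertilization, or to parthenogenetic
activation by strontium, with hours of repeated cytoplasmic calcium
transients. These oscillations drive egg activation, and comparing
their pattern between two groups of eggs — for example eggs from
naturally cycling versus superovulated females — is a standard
experimental design in reproductive biology. The raw data are
per-egg ratiometric Fura-2 time series: a dimensionless F340/F380
ratio sampled every 7.5 s for ~110–120 min.

`caosc` is an R package for that analysis:

* **robust per-trace baseline and noise estimation** (pre-stimulus
  median/MAD when a quiet window exists; a bias-corrected windowed
  10th-percentile estimate otherwise);
* **transient detection** by a threshold of `k·σ` above baseline with
  a hysteresis-style offset at a fraction of peak height, gap-based
  merging and minimum-duration filtering — every knob explicit and
  recorded;
* **the per-egg metric panel**: time to the first transient, duration
  of the first transient, oscillation counts for 60 and 120 min from
  the first onset, oscillations per 10 min, area under the curve
  (AUC, ratio·s) over 60 min, and cessation/censoring for persistence;
* **two-group inference**: Mann–Whitney U tests — exact by full
  enumeration of group assignments for small tie-free samples,
  tie-corrected normal approximation otherwise — for the scalar
  metrics, and the Mantel–Cox log-rank test
  (χ² = (ΣO − ΣE)²/ΣV on the per-event-time hypergeometric tables)
  for oscillation persistence with censoring;
* **a seeded synthetic-trace generator** with per-egg ground truth
  (latency, transient times and durations, cessation, responder
  status), so detection, feature extraction and the statistics are all
  validated against known truth — including full type-I error and
  power studies of the entire pipeline.

## Worked example

Simulate the canonical engineered contrast — group B begins
oscillating slightly later (latency ×1.15) and has a 50% longer first
transient (duration ×1.5), all else identical — at realistic group
sizes, run the full pipeline, and print the six-panel comparison:

```r
library(caosc)
run <- run_pipeline(run_config(scenario = "sr_paper", seed = 17))
run
#> <caosc_run> scenario 'sr_paper' (seed 17) | config 48e4047a | caosc 0.1.0
#>   groups: NC (n=75, 75 responders), SOV (n=78, 78 responders)
#> Two-group comparison (alpha = 0.05)
#>            metric n_a n_b median_a median_b statistic          test   p_value
#>   time_to_first_s  75  78   127.50   150.00 1783.0000 mw_asymptotic 2.944e-05
#>  first_duration_s  75  78    30.00    45.00 1362.0000 mw_asymptotic 7.684e-09
#>    freq_per_10min  75  78     3.00     3.00 2708.0000 mw_asymptotic 4.115e-01
#>            auc_60  75  78   108.10   102.80 2817.0000 mw_asymptotic 6.948e-01
#>         n_osc_120  75  78    24.00    21.50 2521.0000 mw_asymptotic 1.399e-01
#>       persistence  75  78    84.38    82.62    0.4538       logrank 5.005e-01
#>  testable significant
#>      TRUE        TRUE
#>      TRUE        TRUE
#>      TRUE       FALSE
#>      TRUE       FALSE
#>      TRUE       FALSE
#>      TRUE       FALSE
```

Exactly the two altered metrics come out significant: the latency to
the first transient (median 127.5 s vs 150 s) and the duration of the
first transient (median 30 s vs 45 s, the engineered 1.5-fold
contrast), while frequency, AUC, the 120-min oscillation count and
persistence — none of which differ between the generating regimes —
stay non-significant. `plot(run)` draws the two groups' persistence
curves; `summary(run)` adds per-group feature medians.

Real data come in as plain TSV (long `egg_id/time_s/ratio` or wide
`time_s` + one column per egg, with a YAML metadata sidecar carrying
group, mode, replicate and stimulus time):

```r
ts  <- read_traceset("traces.tsv", format = "long")
run <- run_pipeline(run_config(input = "traces.tsv"))
```

A thin command-line wrapper over the same functions ships in
`inst/cli/caosc` (subcommands `simulate`, `detect`, `features`,
`run`).

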