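# sweeppower

Can a genome scan find a selective sweep in a population that just went
through a severe bottleneck? `sweeppower` is a simulation laboratory for
that question. It targets the situation faced by anyone scanning recently
colonized or domesticated populations — e.g. the Gulf Coast beach mice and
Nebraska Sand Hills deer mice whose pigmentation loci are textbook cases of
recent local adaptation — where the demographic history (a 99.6–99.9%
population-size reduction a few thousand generations ago) mimics the
genomic footprint of selection and starves the scan statistics of signal.

The package provides, in one coherent pipeline:

* **A coalescent simulator with hard sweeps** (`simulate_neutral_sample()`,
  `simulate_sweep_sample()`): a backward-in-time ancestral recombination
  graph under a piecewise-constant demography (ancestral size
  *N*<sub>anc</sub>, bottleneck to *f·N*<sub>anc</sub> at divergence time
  *d*, recovery to *c·N*<sub>anc</sub> at *t<sub>r</sub>*; times in
  2*N*<sub>anc</sub> generations), with a structured sweep phase driven by
  a Wright–Fisher allele-frequency trajectory conditioned on fixation at
  time τ (`simulate_trajectory()`). Infinite-sites mutations, continuous
  positions, Hudson `ms` text as the exchange format (`read_ms()`,
  `write_ms()`).
* **Two scan statistics.** A SweepFinder-style composite likelihood ratio
  (`clr_scan()`): at each test position *X* the background site frequency
  spectrum **b** is distorted by distance-dependent escape probabilities
  *p<sub>e</sub>* = 1 − e<sup>−α·d</sup>, and
  Λ(X) = 2[ln CL<sub>sweep</sub>(α̂) − ln CL<sub>background</sub>]
  is maximized over the sweep-intensity nuisance α. And the
  LD-based ω statistic (`omega_max_scan()`):
  ω = [avg r² within flanks] / [avg r² across the split], maximized over
  split windows — elevated by the flanking-LD / broken-cross-LD pattern a
  completed sweep leaves.
* **Calibration and power** (`calibrate_threshold()`,
  `run_power_study()`): neutral-null simulation with θ fitted to the
  scanned data, empirical 95th-percentile cutoffs, and per-replicate
  true/false-positive classification against a 10 kb window centred on the
  known selected site (a sweep of strength *s* is expected to span roughly
  0.01·*s*/*r* bp, `expected_sweep_width()`).

Results are tibbles; scan profiles, trajectories and power tables have
`autoplot()`, `tidy()` and `glance()` methods. A thin command-line front
end lives at `inst/cli/sweeppower` (subcommands `simulate`, `sumstats`,
`scan-sf`, `scan-omega`, `calibrate`, `evaluate`, `reproduce`).

## Worked example

Simulate one Florida-model (beach mouse) replicate with a sweep of
*s* = 0.01 fixing 0.1 × 2*N* generations ago, then scan it:

```r
library(sweeppower)
p <- preset_model("florida-table2")
h <- simulate_sweep_sample(p$demography, sweep_model(0.01, 0.1),
                           p$region, seed = 11)
h
#> Haplotype sample: 40 chromosomes, 52 segregating sites, 180000 bp region
replicate_sumstats(list(h))
#> # A tibble: 1 × 5
#>   replicate     S        pi   theta_w     D
#>       <int> <int>     <dbl>     <dbl> <dbl>
#> 1         1    52 0.0000335 0.0000679 -1.81
glance(clr_scan(h))
#> # A tibble: 1 × 4
#>   statistic max_value max_position n_grid
#>   <chr>         <dbl>        <dbl>  <int>
#> 1 clr            1.47       119000    181
```

The diversity is ~20-fold below the ancestral 4*N*μ, Tajima's D is
strongly negative — the bottleneck's doing, not the sweep's — and the
likelihood-ratio profile peaks at a modest 1.5, far from the true target
at 90 kb. A small power study makes that systematic:

```r
st <- study_config(n_replicates = 20, n_null_replicates = 50, seed = 42)
cells <- list("florida s=0.01 tau=0.1" =
  list(demography = p$demography, region = p$region,
       sweep = sweep_model(0.01, 0.1)))
run_power_study(cells, st)
#>                     cell statistic tp_pct fp_pct    cutoff
#> 1 florida s=0.01 tau=0.1       clr      0     10   3.57466
#> 2 florida s=0.01 tau=0.1     omega      0      0 761.00000
```

No replicate is significant inside the 10 kb target window (`tp_pct`),
and rejections elsewhere (`fp_pct`) sit at the calibrated false-positive
level: under this demography the sweep is undetectable, which is the
study's central result for small bottlenecked populations.

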