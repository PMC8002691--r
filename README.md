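# tracern2o

Estimation and source partitioning of nitrous oxide (N₂O) production
rates from ¹⁵N tracer incubations in low-oxygen seawater, with a
synthetic-study generator for end-to-end validation.

## The problem

In oceanic oxygen minimum zones, N₂O — a potent greenhouse gas — is
produced by several microbial pathways at once: bacterial
denitrification, nitrification, and (much less studied) fungal
denitrification, which terminates at N₂O. Disentangling these sources
from bottle incubations requires three pieces of arithmetic that this
package implements as tested, reusable components:

1. **Isotope bookkeeping.** An IRMS reports total N₂O (nmol N) and bulk
   δ¹⁵N. The labelled portion is

   ```
   ¹⁵N₂O = N₂O × ((δ/1000 + 1)·R_ref) / (1 + (δ/1000 + 1)·R_ref)
   ```

   and the volumetric production rate is the regression slope of ¹⁵N₂O
   against time, normalised by the pool labelling f¹⁵ and the incubated
   volume V:

   ```
   R_N2O = (d¹⁵N₂O/dt) / (f¹⁵ × V)        [nmol N L⁻¹ d⁻¹]
   ```

2. **Selective-inhibition partitioning.** Chloramphenicol blocks
   prokaryotic activity, so the rate in a ¹⁵NO₃⁻ + chloramphenicol
   bottle approximates (an upper limit of) fungal denitrification;
   total-minus-inhibited is attributed to bacteria, and the ¹⁵NH₄⁺
   treatment measures nitrification.

3. **Depth integration.** Trapezoidal integration of the fungal and
   total rates from the oxycline to the oxic–anoxic interface (located
   by interpolated O₂-threshold crossing) gives the water-column fungal
   fraction in percent.

A fourth component, `expected_gene_reads()`, quantifies whether a
single-copy fungal gene (e.g. the nitric oxide reductase P450nor) could
even be detected at a given metagenome sequencing depth, via Poisson
sampling: λ = reads × fungal fraction × gene/genome length.

Because real incubation campaigns are small and noisy, the package ships
a synthetic generator (`station_scenario()`, `generate_station()`) that
simulates whole two-station studies — sigmoidal oxyclines, exponentially
oxygen-inhibited pathway rates, 2‰ δ¹⁵N precision, detection-limit
censoring — so every stage can be verified against known truth.

## Worked example

Simulate the default deep station (three time points, 0/12/24 h), run
the full analysis, and integrate the fungal contribution:

```r
library(tracern2o)
cfg    <- default_config()
scen   <- default_scenarios()$S2
study  <- generate_station(scen, cfg, seed = 42)
series <- series_from_table(study$incubations, cfg, study$profile)
ana    <- analyze_station(series, study$profile, cfg, z_top_m = scen$z_top_m)

head(ana$rates, 3)
#>   station depth_m treatment rate_nmolN_L_d     slope_se n_points p_one_sided censored_points
#> 1      S2      90       NO3    -0.05499703 5.929088e-05        3  0.68759968               0
#> 2      S2      90   NO3_CAP     0.03840446 7.805936e-05        3  0.39151816               0
#> 3      S2      90       NH4     0.02125388 2.260205e-05        3  0.06846725               0

subset(ana$partition, depth_m >= 130 & depth_m <= 160,
       select = c(depth_m, o2_uM, total_no3_rate, fungal_rate, bacterial_rate))
#>   depth_m     o2_uM total_no3_rate fungal_rate bacterial_rate
#> 5     130 4.3657003      0.2091219   0.2932753       0.000000
#> 6     140 1.2716417      2.7038032   0.5377810       2.166022
#> 7     160 0.1050279      7.8840114   0.7375424       7.146469

ana$interface_m
#> [1] 144.6569
ana$integration
#> Integrated 90-144.7 m: fungal 8.958 / total 32.56 umol N/m2/d = 27.5% fungal
study$truth$fungal_fraction_percent
#> [1] 20.30994
```

Reading the output: at 90 m (O₂ ≈ 148 µM) production is indistinguishable
from zero — the NO3 rate is slightly negative and its one-sided p-value
is large. Rates rise steeply as O₂ falls: at 160 m the bacterial pathway
dominates (7.1 of 7.9 nmol N L⁻¹ d⁻¹). At 130 m the inhibited bottle
happened to out-produce the uninhibited one, so the bacterial rate was
clamped to zero and the depth flagged (`ana$partition$clamped`). The
oxic–anoxic interface (O₂ < 1 µM) interpolates to 144.7 m, and the
integrated fungal share over 90–144.7 m is 27.5% in this single noisy
realization, against a true 20.3% for this scenario — rate estimates at
individual depths are noisy, and the clamp/floor rules rectify some of
that noise upward, which is why the fungal share is interpreted as an
upper limit. The median over many seeds recovers the truth within a few
percentage points (see the test suite).

Gene detectability at a study-like sequencing depth:

```r
expected_gene_reads(1e7, 2e-4)
#> Gene detectability: 0.1 expected reads (lambda), P(>=1 read) = 0.09516
#>   (1e+07 reads, fungal fraction 0.0002, gene 1500 bp / genome 3e+07 bp)
```

A command-line front end wrapping the same functions is installed at
`inst/scripts/tracern2o.R`
(`simulate | fit-rates | partition | integrate | detectability | report`),
with exit codes 0 (success), 2 (validation error), 3 (estimation error).

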