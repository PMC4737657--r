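# synaptometry

Quantitative analysis of dendritic spine morphometry and the precision of
synaptic plasticity.

Spine head volume is a structural correlate of synaptic strength. Pairs of
spines on the same dendrite innervated by the same axon share their entire
pre- and postsynaptic activity history, so the similarity of such
"axon-coupled" pairs bounds the variability of activity-dependent
plasticity from above. `synaptometry` implements the statistical chain
that turns that observation into an information-capacity estimate, for
neuroscientists working with 3D reconstruction morphometry or modelling
synaptic precision:

- **Pair precision.** For each pair, CV = (|a−b|/√2) / ((a+b)/2); the
  population statistic is the median over same-dendrite axon-coupled
  pairs (empirical anchor: 0.083, versus ≈ 0.39 for random pairings).
  Disjoint random-pairing resampling nulls, two-sample KS comparisons and
  log–log regressions back the inference (`spine_pair_analysis()`).
- **Information capacity.** Constant-CV Gaussian strength levels tile the
  dynamic range with spacing ratio 1 + 2·CV·z, where
  z = √2·erf⁻¹(c) for discrimination probability c, giving
  N = ln(range)/ln(1 + 2·CV·z) distinguishable levels and log₂N bits per
  synapse (`discrimination_model()`).
- **Release averaging.** Reading a strength at precision CV through
  binomial vesicle release with probability p_r requires
  n = (1−p_r)/(p_r·CV²) spikes, i.e. a time window T = n/R at firing rate
  R (`release_table()`, `simulate_release()`).
- **Morphometry.** Convex-hull volumes and areas of tagged mesh regions,
  neck volume by subtraction, docked-vesicle counts by the 100-nm
  active-zone distance rule, PSD-centroid distances and
  repeated-measurement error (`region_hull_volume()`, `count_docked()`, …),
  with ASCII-PLY + JSON-sidecar mesh I/O.
- **Synthetic neuropil.** A calibrated generator for spine-record tables,
  coupled pairs, toy spine meshes and vesicle clouds with exact ground
  truth (`generate_population()`, `generate_coupled_pairs()`, …), so every
  stage is testable end to end.

## Worked example

```r
library(synaptometry)

report <- run_all(default_run_config(seed = 1))
report
#> Synaptic precision pipeline report
#>   population: 287 spines, median head volume 0.050 um^3, 28-fold range, area-volume r2 0.989
#>   pairs: 17 coupled, median CV 0.060 (null 0.361, empirical p 0.000999, KS p 1.57e-06)
#>   capacity: N = 26.3 levels (~26), 4.72 bits, 31% overlap at cv = 0.083
#>   release averaging: 3 release probabilities x 2 rates (cv 0.083)
```

Reading the report: the generator produced 287 spines whose head area
tracks head volume with r² ≈ 0.99 on the log scale; the 17 planted
axon-coupled pairs were recovered with a median per-pair CV near the 0.083
calibration target (any single 17-pair sample is noisy — the seed-ensemble
mean sits on 0.083), far below the ≈ 0.36 median of random pairings
(empirical p ≈ 0.001, the resampling resolution). At CV = 0.083 over a
60-fold range, 26 strength levels are distinguishable at the 69% threshold
— about 4.7 bits of storable information per synapse.

The component models are directly accessible:

```r
discrimination_model(cv = 0.083, range_factor = 60, confidence = 0.69)
#> Discriminable synaptic strength levels (signal-detection model)
#>   per-level CV:            0.083
#>   dynamic range (max/min): 60-fold
#>   discrimination:          69% (z = 1.0152, overlap 31%)
#>   spacing ratio:           1.1685 per level
#>   distinguishable levels:  N = 26.3 (~26)
#>   information:             4.72 bits per synapse

release_table()
#> Lower bounds on averaging time for binomial release to reach CV = 0.083
#>
#>  p_r spikes n T (R = 1 Hz) T (R = 25 Hz)
#>  0.1     1306     21.8 min        52.2 s
#>  0.2      581     9.68 min        23.2 s
#>  0.5      145     2.42 min         5.8 s
```

So a weak synapse (release probability 0.1) needs ~1300 presynaptic spikes
— 22 minutes at 1 Hz — before its postsynaptic partner could know its
strength to CV 0.083, while a reliable one (0.5) needs only 145.

A thin command-line wrapper over the same functions ships in
`inst/scripts/synaptometry-cli.R`
(`Rscript synaptometry-cli.R run --seed 1 --out results/`).

## Package layout

- `R/synthetic.R` – population/pair/mesh/vesicle generators and their
  calibration
- `R/mesh.R` – tagged meshes, convex hulls, distances, measurement error
- `R/pair_statistics.R` – pair CVs, resampling nulls, KS, regressions
- `R/capacity.R` – the discriminable-level model
- `R/release.R` – the binomial release-averaging model
- `R/pipeline.R` – configuration, orchestration, reporting
- `vignettes/synaptic-precision.Rmd` – the methods vignette: model
  assumptions, calibrations, numerical conventions and limitations
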