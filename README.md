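# isoN2O

Analysis toolkit for N2O isotopocule data from DNRA batch cultures
(dissimilatory nitrate reduction to ammonium). Nitrate-ammonifying bacteria
release a small amount of N2O from NO2− via NO, and that N2O carries an
exceptionally high **site preference**,

```
SP = δ15N_alpha − δ15N_beta        (central minus terminal N, ‰)
δ15N_beta = 2 δ15N_bulk − δ15N_alpha
```

which distinguishes it from denitrification-derived N2O (SP ≈ 0 ‰). The
package implements the full desk side of such experiments:

* **Isotopocule calculus** — complete and validate δ15Nα/δ15Nβ/δ15Nbulk/SP
  records, reference product deltas to the substrate (`complete_isotopocule`,
  `substrate_reference`).
* **Gas budgeting** — headspace-to-total N2O via the Bunsen coefficient
  (`total_n2o`, `dissolved_fraction`, default α = 0.544 at 25 °C, 20/30 mL).
* **Nitrogen budgets** — per-bottle amounts as N, conversion ratios,
  end-stage composition with honest `unrecovered`, and the N2O–nitrite
  association (`amounts_as_N`, `conversion_ratio`, `end_stage_composition`,
  `production_association`).
* **Source partitioning** — two-endmember SP mass balance
  `SP_mix = f·SP_a + (1−f)·SP_b` with closed-form inversion and Monte Carlo
  uncertainty (`solve_fraction`, `predict_mixture`, `mc_fraction`).
* **Dual-isotope classification** — endmember-zone membership in
  (SP, δ15N, δ18O) space and back-projection along the N2O-reduction vector
  (`classify_zones`, `apply_reduction`, `reachable_zones`, `dnra_zone`).
* **Cohort statistics** — group medians with one-decimal reporting,
  Mann–Whitney U and Kruskal–Wallis tests (`group_medians`, `mann_whitney`,
  `kruskal_wallis`).
* **Synthetic cultures** — a seeded generator of culture time series and
  replicate-level isotope tables with known ground truth
  (`culture_config`, `simulate_culture`, `simulate_isotopes`).

A reference dataset of strain-mean isotopocule signatures from nine
Geobacteraceae strains ships in `inst/extdata/` (`load_reference_isotopes()`),
together with an editable YAML endmember-zone library.

## Worked example

Partition 7-day N2O from a nitrate-fed culture between the DNRA pathway
(its own 3-day SP, 45.5 ± 0.7 ‰) and cNor-driven denitrification
(−5.9 ± 2.1 ‰), given a measured 7-day SP of 41.9 ± 0.9 ‰:

```r
library(isoN2O)

dnra <- point_endmember("DNRA_3d", 45.5, 0.7)
cnor <- point_endmember("cNor", -5.9, 2.1)
mc_fraction(41.9, 0.9, dnra, cnor, n_draws = 1e5, seed = 1)
#> <mixing_result> f = 0.9300 (closed form), MC mean 0.9300 +/- 0.0220, 95% CI [0.8871, 0.9732]
#>   n_draws = 100000, seed = 1, share outside [0,1] = 0.00086, resampled = 0
```

About 93 % of the late-culture N2O is attributable to the DNRA pathway,
with a 95 % interval of roughly 89–97 %; under a tenth of a percent of the
draws fall outside [0, 1].

Classify the same culture's 3-day observation against the shipped DNRA
signature zone and summarise the reference dataset:

```r
obs <- tibble::tibble(SP = 46.8, d15N_bulk = -23.7, d18O = 27.8,
                      referenced = TRUE)
classify_zones(obs)[[1]]
#> [1] "DN"

group_medians(sp_groups(load_reference_isotopes(), "substrate"))
#> # A tibble: 2 × 4
#>   group     n median_raw median_reported
#>   <chr> <int>      <dbl>           <dbl>
#> 1 NO2      10       46.2            46.2
#> 2 NO3      10       46.3            46.4
```

The substrate medians (46.2 ‰ vs 46.4 ‰, raw 46.35) are statistically
indistinguishable (`mann_whitney`, p = 0.94): the N2O production pathway is
shared across nitrate and nitrite feeding.

A command-line wrapper over the same functions is installed at
`inst/cli/isoN2O.R` (`simulate`, `isotopes`, `budget`, `mix`, `classify`,
`stats` subcommands), for use in shell pipelines.

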