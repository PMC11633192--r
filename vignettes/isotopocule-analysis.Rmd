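---
title: "N2O isotopocule analysis for DNRA cultures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{N2O isotopocule analysis for DNRA cultures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoN2O)
```

# The scientific problem

Dissimilatory nitrate reduction to ammonium (DNRA) is an anaerobic
respiration in which NO3&#8722; is reduced to NO2&#8722; and on to NH4+,
with nitrous oxide (N2O) formed as a minor byproduct from NO2&#8722; via
NO. N2O carries an intramolecular isotopic fingerprint: the two nitrogen
positions of the linear N&#8211;N&#8211;O molecule (central &alpha;,
terminal &beta;) can differ in their 15N content. The **site preference**

$$\mathrm{SP} = \delta^{15}\mathrm{N}^{\alpha} - \delta^{15}\mathrm{N}^{\beta}$$

depends on the enzymatic mechanism that formed the molecule and not on the
substrate's isotopic composition, which makes it a pathway tracer: N2O from
DNRA cultures carries very high SP (roughly 43&#8211;50&permil;), far above
bacterial denitrification (around 0&permil;). This package implements the
data analysis around that tracer for batch-culture experiments: isotopocule
calculus, gas budgeting, nitrogen budgets, two-endmember source
partitioning with Monte Carlo uncertainty, dual-isotope zone
classification, nonparametric group comparison, and a synthetic culture
generator so every stage can be tested without instrument data.

# Isotopocule calculus

All per-mil values are stored as plain numbers on the per-mil scale; every
relation used is linear in per-mil, so no ratio-space conversion is needed.
The four 15N observables obey two identities,

$$\delta^{15}\mathrm{N}^{\beta} = 2\,\delta^{15}\mathrm{N}^{bulk} -
\delta^{15}\mathrm{N}^{\alpha}, \qquad
\mathrm{SP} = \delta^{15}\mathrm{N}^{\alpha} - \delta^{15}\mathrm{N}^{\beta},$$

so any two determine the other two. `complete_isotopocule()` solves the
little linear system by least squares, fills missing fields, and measures
the misfit of over-determined rows. The consistency tolerance is
0.01&permil; &mdash; one decimal beyond the usual 0.1&permil; reporting
precision &mdash; and inconsistent rows either error (single-record use) or
are flagged and kept (table reading), never dropped silently.

```{r}
m <- isotope_measurement("example", d15N_bulk = -39.8, SP = 46.5)
complete_isotopocule(m)[, c("d15N_alpha", "d15N_beta", "d15N_bulk", "SP")]
```

`substrate_reference()` re-expresses product &delta;15N and &delta;18O as
product-minus-substrate differences (the shipped substrate compositions are
&delta;15N 2.4 &plusmn; 0.1 / &delta;18O 17.9 &plusmn; 0.3&permil; for
NO3&#8722; and &#8722;1.8 &plusmn; 0.3 / 3.7 &plusmn; 0.2&permil; for
NO2&#8722;). SP is a difference of two positions of the same molecule and
is therefore invariant under this frame shift; the API documents and tests
that invariance. &alpha; and &beta; are shifted along with the bulk value
so the identities keep holding after referencing.

# Gas partitioning

Sealed serum bottles hold N2O in both headspace and medium. At solubility
equilibrium the dissolved amount follows the Bunsen absorption coefficient
$\alpha$ (volume of gas per volume of liquid at unit partial pressure):

$$n_{total} = n_{headspace}\left(1 + \alpha\,\frac{V_{liq}}{V_{head}}\right).$$

The shipped default is 20 mL medium in a 50 mL bottle (30 mL headspace) at
25 &deg;C with $\alpha = 0.544$; one &micro;mol in the headspace implies
`r round(total_n2o(1), 4)` &micro;mol in the bottle. $\alpha$ is a
configured constant &mdash; no solubility&#8211;temperature correlation is
implemented, since incubations run isothermally. The GC mixing-ratio helper
assumes 1 atm total pressure (configurable); salinity corrections and
non-equilibrium dissolution are out of scope.

# Nitrogen budgets

`amounts_as_N()` converts to &micro;mol N (mM &times; liquid mL for ions;
N2O counts twice). `end_stage_composition()` divides each pool at the final
time by the initial substrate-N and reports the remainder as `unrecovered`
&mdash; negative if the pools over-close, never clipped, so the fractions
always sum to one. The "final reaction stage" defaults to the last sampled
time with a `t_end` override, since cultures stall at strain-specific
times. `conversion_ratio()` guards against zero consumption with an error
rather than returning 0 or NaN.

For the N2O&#8211;nitrite association, the regression variable for
"NO2&#8722; accumulation" is not uniquely defined once the transient starts
being consumed. The default is the max-to-date net NO2&#8722; increase
(monotone, so the regression is on cumulative quantities);
`x_mode = "instantaneous"` uses the raw net change instead. A caveat
matters here: for cultures that convert NO2&#8722; nearly completely, most
N2O forms *after* the NO2&#8722; peak, so the max-to-date predictor is flat
over the late points while cumulative N2O keeps growing, and r&sup2; of the
full-course regression settles near 0.5 regardless of rate constants. The
strong linear association (r&sup2; &ge; 0.7) is characteristic of cultures
in which NO2&#8722; accumulation persists &mdash; the weak-nitrite-reducer
phenotype, or the accumulation phase of any culture &mdash; and that is the
regime in which the property is asserted in the test suite.

# Two-endmember mixing

A measured SP that lies between two pathway endmembers is attributed by
linear mass balance:

$$\mathrm{SP}_{mix} = f\,\mathrm{SP}_{a} + (1-f)\,\mathrm{SP}_{b}
\quad\Longrightarrow\quad
f = \frac{\mathrm{SP}_{mix} - \mathrm{SP}_{b}}{\mathrm{SP}_{a} - \mathrm{SP}_{b}}.$$

The canonical use case partitions late-culture N2O between the DNRA
pathway (the culture's own 3-day SP) and cNor-driven denitrification
(SP = &#8722;5.9 &plusmn; 2.1&permil;). `mc_fraction()` propagates
uncertainty by drawing all three SP values from independent normal
distributions &mdash; the &plusmn; values are read as 1 SD; no
distributional form is stated by the underlying reports, and Gaussian is
the conventional reading. Design choices worth knowing:

* out-of-[0,1] draws are *retained* in the summary statistics and their
  share reported (`clipped_share`); silently truncating would bias $f$
  near the boundaries;
* draws with endmembers closer than 10^-6 &permil; are rejected and
  resampled, with the count reported;
* inversion with more than two endmembers on the single SP axis is refused
  as under-determined (only the forward mixture is exposed).

On the shipped reference strain means, the closed form gives
`r round(100 * solve_fraction(41.9, 45.5, -5.9), 1)`&#37; (strain Red69)
and `r round(100 * solve_fraction(41.1, 47.0, -5.9), 1)`&#37; (strain
Red111) DNRA contribution at 7 days. Published replicate-level analyses of
the same cultures quote about 94&#37; for both strains; that figure is not
reproducible from the strain means with the stated equation and presumably
reflects replicate-level averaging whose scheme is not recoverable. The
package computes from the data it is given and documents the discrepancy
rather than guessing.

# Dual-isotope zone classification

`classify_zones()` tests measurements against axis-aligned boxes in
(SP, &delta;15N, &delta;18O) space with closed intervals (boundary points
match). A zone may constrain any subset of axes; constraining an axis
absent from a measurement yields a warned non-match. The shipped library
contains only the DNRA zone (SP 43.0&#8211;49.9, &delta;15N
&#8722;39.9 to &#8722;5.8, &delta;18O 14.1&#8211;30.5&permil;,
substrate-referenced); the conventional zones for other processes
(bacterial/fungal/chemical denitrification, nitrification, nitrifier
denitrification) are cited to literature compilations and ship as an
editable YAML template rather than hard-coded numbers.

Partial N2O consumption by N2O reductase moves residual N2O along a known
direction; `apply_reduction()` displaces a point by &Delta; per-mil of
&delta;15N with SP and &delta;18O following at slopes 0.96 and 2.21, and
`reachable_zones()` inverts this: for each zone it solves the interval of
reduction extent for which the back-projected source lies inside, by
intersecting per-axis interval constraints. &delta;15N parameterises the
line; the independently reported SP/&delta;18O slope of 0.45 implies
0.96/0.45 &asymp; 2.13 for &delta;18O/&delta;15N versus the directly
reported 2.21 &mdash; a rounding-level inconsistency. The direct 2.21 is
the default for internal consistency and the 0.45-derived line is
selectable (`use_printed_sp_d18o = TRUE`).

# Group statistics

Medians are reported at one decimal with half-away-from-zero rounding
(so a raw 46.35 reports as 46.4, matching the conventional one-decimal
style); the raw value is always returned alongside. Two-group comparisons
use the Mann&#8211;Whitney U test (exact permutation distribution when the
smaller group has &le; 8 observations and no ties, otherwise the
tie-corrected normal approximation) and three or more groups use
Kruskal&#8211;Wallis, both delegated to the standard `stats`
implementations behind the module interface. Substrate comparisons exclude
the two nitrite-only strains by default because they have no nitrate arm;
an include flag is provided. The reference dataset's substrate medians are
46.2&permil; (NO2&#8722;) and 46.4&permil; (NO3&#8722;, raw 46.35) with no
significant difference &mdash; note that replicate-level data can yield
slightly different genus medians than strain means; both levels are
supported inputs and the analysis level should be stated when reporting.

# The synthetic culture generator

The generator exists so that every pipeline stage has a testable input with
known ground truth. It emulates the *statistical structure* of DNRA batch
experiments, not their biochemistry:

* **Kinetics** (`simulate_culture()`): logistic biomass (defaults r = 0.06
  h^-1, K = 0.20 OD600, inoculum 0.02), first-order substrate consumption
  scaled by biomass (k_consume = 0.5 h^-1 OD^-1), and first-order onward
  NO2&#8722; reduction (k_nitrite = 0.11 h^-1 OD^-1) partitioned into NH4+
  (y_nh4 = 0.65), N2O-N (y_n2o = 0.01 for nitrate runs, 0.02 for nitrite
  runs) and an unmeasured remainder. This is the simplest form that
  reproduces the observed shape: complete NO3&#8722; consumption, a
  transient NO2&#8722; peak with a residual in the 3&#8211;20&#37; band at
  one week, ammonium above 60&#37; of substrate-N, and N2O near 1&#37;.
  The rate law itself is this package's choice; the emulated experiments
  report dynamics, not kinetic constants.
* **Integration**: forward Euler at 0.05 h (&le; 0.1 h enforced), sampled
  every 12 h to 168 h. Any pool dipping below &#8722;10^-9 aborts with an
  instruction to reduce the step. The latent state (including the
  unmeasured pool) closes the nitrogen budget to machine precision at all
  times; measurement noise (2&#37; relative, optional) is applied only to
  sampled observations.
* **Isotopes** (`simulate_isotopes()`): per replicate and day, pathway SP
  values are drawn around the DNRA (46.2 &plusmn; 1.5&permil;) and cNor
  (&#8722;5.9 &plusmn; 2.1&permil;) endmembers and mixed linearly at
  f_DNRA; raw &delta;15N/&delta;18O are the substrate composition plus a
  drawn net offset (&#8722;24.6 &plusmn; 6.0 and 23.6 &plusmn;
  6.3&permil;). Instrument noise uses the stated precisions 0.1&permil;
  (bulk, &delta;18O) and, for SP, the propagated
  &radic;(0.2&sup2; + (2&middot;0.1)&sup2;) &asymp; 0.28&permil; (no SP
  precision is reported directly; this follows from
  &beta; = 2&middot;bulk &#8722; &alpha;). &alpha;/&beta; are then derived
  exactly, so generated tables satisfy the completion identities by
  construction.
* **Determinism**: every stochastic element is seeded; identical seeds give
  identical tables. A time-varying f_DNRA is *not* simulated &mdash; the
  7-day SP decreases seen in two reference strains are consistent with a
  step change in pathway mixture, but no schedule for it is documented, so
  the generator keeps f constant per run.

What passing tests on synthetic data do **not** show: real cultures have
autocorrelated sampling error, non-Gaussian isotope scatter, Rayleigh-type
drift of substrate isotopes in closed systems (deliberately not modelled;
the emulated experiments report fixed substrate compositions), and
strain-specific stall behaviour. Synthetic-data results validate the
*computations*, not instrument performance.

# Numerical and design notes

* Completion solves a 2-unknown least-squares system per row; with exactly
  two knowns the residual is zero by construction and any two of the four
  observables are mutually sufficient (no pair is collinear).
* `round_half_away()` guards against binary under-representation of exact
  halves (a mean of 46.3 and 46.4 is stored fractionally below 46.35) with
  a 10^-12 relative epsilon before flooring.
* The Kruskal&#8211;Wallis wrapper returns H = 0 when every observation is
  tied (the delegated implementation returns NaN there).
* Monte Carlo summaries use the 2.5&#8211;97.5 percentile interval;
  `f_point` is the closed form at the means and is reported alongside the
  draw statistics so bias from the nonlinear ratio is visible (negligible
  at the shipped endmember separation of ~52&permil;).
* Problem sizes used by the verification script: 10^5 mixing draws, 5
  replicate bottles, 15 sampled time points per culture, 5 replicate
  isotope tables per f value &mdash; chosen to hold Monte Carlo error well
  below the tolerances being checked.

# Known limitations

* Two-endmember, single-axis inversion only; joint Bayesian mixing over
  SP/&delta;15N/&delta;18O (MixSIAR-style) is out of scope.
* The zone library ships with numeric ranges for the DNRA zone only.
* Mass-spectrometer calibration, scrambling and ion corrections are
  upstream of this package: inputs are assumed calibrated.
* The max-to-date association statistic is informative only while
  NO2&#8722; accumulates (see above); for full-conversion cultures restrict
  the window or interpret r&sup2; accordingly.
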