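Package: isoN2O
Title: N2O Isotopocule Analysis for DNRA Culture Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing nitrous oxide (N2O) isotopocule data from
    anoxic batch cultures of nitrate-ammonifying bacteria (dissimilatory
    nitrate reduction to ammonium, DNRA). Provides isotopocule calculus for
    delta-15N-alpha/beta/bulk, delta-18O and site preference (SP); Bunsen
    solubility partitioning of headspace and dissolved N2O; per-bottle
    nitrogen budgets (conversion ratios, end-stage composition, N2O-nitrite
    association); two-endmember isotope mass-balance source partitioning with
    Monte Carlo uncertainty; dual-isotope endmember-zone classification with
    N2O-reduction vector back-projection; nonparametric group comparisons;
    and a seeded synthetic culture generator so the whole pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
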