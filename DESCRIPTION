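Package: no3apport
Title: Nitrate Source Apportionment from Nitrogen and Triple Oxygen Isotopes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Apportions nitrate in snow, inflow and lake waters among
    atmospheric and terrestrial sources using delta-15N and the
    mass-independent Delta-17O anomaly. Provides isotope data reduction
    (standard-based calibration, the delta-15N mass-overlap correction,
    a water-exchange correction for delta-18O), a Bayesian stable isotope
    mixing model with Dirichlet prior fitted by Markov chain Monte Carlo
    and summarised by modal probability estimates and highest density
    regions, a snowpack ammonium delta-15N mass balance, a tropospheric
    NOx budget scaler, and a synthetic sample generator emulating alpine
    catchment survey data for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
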