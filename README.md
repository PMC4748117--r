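# no3apport

Nitrate source apportionment for snow, inflow and lake waters from
nitrogen and triple-oxygen isotopes.

Alpine lakes are nitrogen-limited, so atmospheric deposition of reactive
nitrogen — fertiliser ammonium, fossil-fuel NOx — measurably changes them,
and managing that requires knowing *which* sources deliver the nitrate.
Two tracers do most of the work: δ¹⁵N separates fertiliser, soil and waste
nitrogen, while the mass-independent anomaly
Δ¹⁷O = δ¹⁷O − 0.52 × δ¹⁸O is a specific fingerprint of nitrate oxidised in
the atmosphere (AON), because terrestrial processes are mass-dependent and
leave Δ¹⁷O ≈ 0.

The package provides the full chain:

* **Data reduction** — standard-based linear calibration
  (`calibrate_linear()`, `reduce_run()`), the δ¹⁵N mass-overlap correction
  `δ¹⁵N − x_corr·Δ¹⁷O` (`correct_d15N_mass_overlap()`, with
  `estimate_xcorr()` from a standard of known anomaly), the water-exchange
  inversion for δ¹⁸O (`correct_d18O_water_exchange()`), and
  `delta17O_excess()`.
* **Bayesian stable isotope mixing model** — for sample *i*, tracer *j*
  and sources *k* with proportions **p** on the simplex:

  *X*ᵢⱼ ~ Normal( Σₖ pₖ(μⱼₖ + cⱼₖ),  Σₖ pₖ² ωⱼₖ² + σⱼ² )

  with Dirichlet prior on **p**, fitted by adaptive random-walk Metropolis
  on log-ratio coordinates (`fit_mixing_model()`), summarised as modal
  probability estimates (MPE, the posterior mode) and 50/75/95% highest
  density regions (`summarize_apportionment()`, `hdr()`).
* **Budget calculators** — the snowpack ammonium δ¹⁵N mass balance
  (`snow_ammonium_d15N()`), tropospheric NOx budget scaling
  (`nox_budget_apportionment()`), and the anthropogenic roll-up
  (`anthropogenic_share()`).
* **Synthetic survey generator** — `generate_survey()` emulates an alpine
  snow/inflow/lake survey (group means, spreads, and the Δ¹⁷O–δ¹⁸O
  correlation via a shared atmospheric-fraction latent);
  `generate_mixture_samples()` draws from the mixing model's own sampling
  distribution for parameter-recovery tests.
* **Pipeline and CLI** — `run_pipeline()` composes the stages and writes
  summary CSVs plus a provenance log; `inst/cli/no3apport.R` exposes
  `correct`, `simulate`, `fit`, `budget` and `run` subcommands.

See the vignette (`vignettes/nitrate-source-apportionment.Rmd`) for the
model, its assumptions, and the design choices.

## Worked example

```r
library(no3apport)

survey <- generate_survey(seed = 1)          # synthetic 41-sample survey
keep   <- filter_samples(survey)$kept        # >1.6 uM NO3-, has D17O
table(keep$group)
#> inflow   lake   snow
#>     16      9     12

src <- default_source_profiles()             # AON / fertiliser / soil / septic
fit <- fit_mixing_model(keep[keep$group == "inflow", ], src,
                        mixing_fit_config(iterations = 100000,
                                          burn_in = 10000, seed = 1))
summarize_apportionment(fit)
#> Source apportionment (%, MPE with 50/75/95% HDR bounds)
#>                      source MPE hdr50_low hdr50_high hdr75_low hdr75_high hdr95_low hdr95_high
#>                         AON  20        19         21        19         22        17         24
#>         Fertilizer+Rain NH4  68        64         71        61         73        57         77
#>                    Soil NO3   6         1         10         0         13         0         19
#>  Septic Effluent and Manure   0         0          3         0          6         0         10
```

The fitted AON share (MPE 20%, 95% HDR 17–24) recovers the fraction the
generator mixed in for inflows (atmospheric fraction 0.177 ± 0.05): the
Δ¹⁷O tracer pins AON tightly, while the terrestrial sources — separated
only by δ¹⁵N — get wider intervals, with fertiliser + rain NH₄⁺ dominant.

```r
snow   <- survey[survey$group == "snow", ]
inflow <- survey[survey$group == "inflow", ]
snow_ammonium_d15N(mean(inflow$d15N), mean(snow$d15N),
                   mean(snow$nh4_uM), mean(snow$no3_uM))
#> [1] -4.581809
```

A snow-ammonium δ¹⁵N near −4.6 ‰ falls in the fertiliser-ammonium range —
the isotopic argument that snowpack ammonium is largely fertiliser-derived.

```r
format_nox_budget(nox_budget_apportionment(default_nox_budget(), aon_mpe = 24))
#>                          name tg_per_year percent_of_nox contribution_to_lakes
#> 1                Fossil fuels        24.0           40.0                  10.0
#> 2                   Lightning        12.0           20.0                   5.0
#> 3              Soil emissions        12.0           20.0                   5.0
#> 4             Biomass burning         8.0           13.0                   3.0
#> 5               NH3 oxidation         3.0            5.0                   1.0
#> 6 Transport from stratosphere         0.4            0.7                   0.2
#> 7                    Aircraft         0.4            0.7                   0.2
#> 8                       Total        60.0          100.0                  24.0
```

With a lake AON MPE of 24%, fossil-fuel NOx (40% of the global budget)
accounts for ~10% of lake nitrate; `anthropogenic_share(62, 23, 0.40)`
rolls fertiliser plus fossil-fuel AON into 71.2% — the "at least 70%
anthropogenic" conclusion.

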