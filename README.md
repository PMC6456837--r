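# mangroveyield

Growth-and-yield analysis and direct-use economic valuation for even-aged
mangrove stands, built around a restored *Rhizophora apiculata* stand in
Balikpapan Bay, East Kalimantan. The package is aimed at forest
mensurationists and ecosystem-service analysts who work from stand tables
(stocking, mean diameter, height, form factor by age) and household income
surveys rather than from tree-level inventories.

## What it computes

**Stand growth.** Standing volume from the form-factor formula

    V = N · (π/4) · (D/100)² · H · F        [m³ ha⁻¹]

with stocking *N* (stems ha⁻¹), mean diameter *D* (cm), branch-free height
*H* (m) and form factor *F*. From a volume series the package derives the
mean annual increment MAI = V_t / t, the periodic annual increment
PAI = (V_t − V_{t−1}) / Δt over the actual measurement interval, and the
MAI culmination age — the biologically optimal rotation.

**Thinning.** Low thinning removes every tree whose diameter is more than
2 cm (configurable) below the stand mean; `thinning_contrast()` quantifies
the stems removed and the MAI response between a pre- and post-thinning
stand table.

**Economics.** Nominal rate of return i = (I_n / V_0)^(1/n) − 1 (monthly,
from annual net income and operating cost), Sturges income classing
(class count ≈ 1 + 3.332·log₁₀N), per-person-per-day income conversion in
IDR or US$, annual wood income (area × volume × stumpage price / rotation)
and the overfishing rate, the relative excess of fishing over wood income
per person per day.

**Synthetic data.** Chapman–Richards stand trajectories, truncated-normal
tree lists and household income samples, all seed-reproducible, so every
pipeline stage is testable without field data.

## Worked example

```r
library(mangroveyield)
sc <- run_balikpapan_scenario()
sc
```

```
Balikpapan Bay mangrove growth & valuation scenario
Growth:
  peak MAI pre-thinning (m3/ha/yr)             5.39  (published 5.39, rel. err 0.03%)
  peak MAI post-thinning (m3/ha/yr)            6.71  (published 6.71, rel. err 0.06%)
  MAI gain at age 25 (%)                       24.6  (published 24.5, rel. err 0.43%)
  stems removed: 90-340 per ha
Valuation:
  wood income (IDR/yr)                    742795025  (published 742425000, rel. err 0.05%)
  wood income (US$/person/day)                0.933  (published 0.933, rel. err 0.00%)
  fishing income (IDR/person/day)             18048  (published 18048, rel. err 0.00%)
  overfishing rate (%)                         45.4  (published 45.5, rel. err 0.12%)
  max monthly NRR (%)                          11.4  (published 11.4, rel. err 0.06%)
Flags:
  post-thinning age 40: recomputed TV 219.49 vs published 229.50 (4.4% off)
```

Reading: both stand tables culminate at age 25; thinning (90–340 stems
ha⁻¹ removed) lifts the peak MAI from 5.39 to 6.71 m³ ha⁻¹ yr⁻¹, a ~24.5%
gain. Valuing the age-20 standing volume over a 20-year rotation on 300 ha
at IDR 500,000 m⁻³ gives ≈ IDR 742 million yr⁻¹ of wood income — US$0.933
per person per day across the 164-person community — against IDR 18,048
(≈US$1.36) per person per day from fishing, i.e. fishing out-earns
sustainable wood harvest by ~45%, the scenario's overfishing pressure
proxy. The flag marks one published volume cell that is internally
inconsistent with its own row attributes; it is reported, not repaired.

Individual layers work standalone:

```r
g <- growth_table(balikpapan_stand_tables()$pre)
peak_mai(g)                      # $age 25, $mai 5.3866
low_thin(generate_tree_list(500, mean_d = 15, sd_d = 3, seed = 1))
monthly_nrr(26.5, 10)            # 11.39 % per month
```

A command-line front end over the same functions ships in
`inst/scripts/mangrove_pipeline.R` (subcommands `grow`, `thin`,
`thin-contrast`, `value`, `simulate-stand`, `simulate-households`,
`reproduce`).

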