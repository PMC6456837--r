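---
title: "Growth, yield and direct-use valuation of a restored mangrove stand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth, yield and direct-use valuation of a restored mangrove stand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mangroveyield)
```

This vignette explains the models behind `mangroveyield`, the assumptions
they rest on, the tunable parameters and their defaults, and the design
choices made where more than one reasonable implementation existed. The
running example is the packaged Balikpapan Bay scenario: a naturally
restored, even-aged *Rhizophora apiculata* stand measured from age 3 to
40 years, and the fishing community whose income competes with
sustainable wood harvest from the same area.

## The mensuration model

A stand table gives, per measurement age *t*: stocking *N* (stems
ha⁻¹), mean stem diameter *D* (cm), branch-free height *H* (m) and form
factor *F*. Standing volume is the classical form-factor estimate

$$V(t) = N \cdot \frac{\pi}{4}\left(\frac{D}{100}\right)^2 H\, F
\quad [\mathrm{m^3\,ha^{-1}}],$$

i.e. stocking times the cylinder on the mean stem's basal area, shrunk by
the form factor (the ratio of true stem volume to that cylinder; it falls
from ~0.85 in young stems to ~0.60 in old ones as stems become more
tapered). The diameter's cm→m conversion happens inside `tree_volume()`;
all volumes are in m³. This is a *mean-tree* model: it assumes the stand
is even-aged and unimodal enough that the mean stem represents the
distribution. It carries no bark/branch partitioning and no allometric
biomass — out of scope by design.

Two increment series follow:

* **MAI** (mean annual increment) `= V(t)/t`, the average productivity of
  the stand over its whole life. Its maximum — the *culmination age* — is
  the biologically optimal rotation.
* **PAI** (periodic annual increment, also called CAI)
  `= (V(t) − V(t′))/(t − t′)` over the *actual* interval between
  consecutive measurements. Stand tables here have irregular spacing
  (3, 7, 10, 13, … years), so PAI always uses the true interval, never an
  assumed 1-year step. PAI is undefined for the first row and may be
  negative if volume declines.

Classically, MAI culminates where the PAI curve crosses it from above. On
a discrete annual grid this holds up to one grid step, which is exactly
what the property tests assert; `peak_mai()` breaks exact ties by the
earliest age, the economically conservative rotation signal.

All computation is kept in full precision; rounding (2 decimals for
volumes and increments, matching the conventions of published stand
tables) is applied only in writers and printed summaries.

### Agreement with the packaged tables, and one flagged cell

The packaged pre- and post-thinning tables carry the published TV/MAI/PAI
columns purely as reference values; `growth_table()` recomputes them from
N, D, H, F. Every volume cell agrees within 0.5% except the post-thinning
age-40 cell: the published 229.50 m³ ha⁻¹ is not reproducible from its own
row attributes (N = 530, D = 26, H = 13, F = 0.60 give ≈219.5). The
published MAI of 5.74 is consistent with 229.50, so the inconsistency is
in the volume cell itself. `run_balikpapan_scenario()` reproduces the
formula and *flags* the cell rather than forcing agreement; wherever that
cell would matter (e.g. the age-40 MAI gain), the contrast functions
accept externally supplied MAI values.

## Thinning

Low thinning removes the smallest stems. The rule implemented: compute
the arithmetic mean diameter of the tree list and remove every tree
*strictly* below `mean − offset`, with `offset = 2` cm by default. The
strict inequality is deliberate: boundary trees are retained, removal is
conservative, and a homogeneous stand (all diameters equal) is a no-op
even with `offset = 0`'s threshold at the mean. The mean is unweighted —
no basal-area weighting — because the tree list is the unit of
observation. Three invariants characterise the operation and are tested
as properties: the retained and removed sets partition the input
multiset; re-applying the same threshold removes nothing; and a larger
offset never removes more trees.

The stand-level contrast (`thinning_contrast()`) is *age-wise and
static*: the post-thinning table is data, not the output of a growth
response model. Stems removed at a common age is simply
`n_pre − n_post`; in the packaged tables this spans 90–340 stems ha⁻¹
(20–40% of stocking, exposed as the `removed_fraction` diagnostic), and
the MAI gain at the age-25 culmination is ≈24.5%.

## The valuation layer

**Nominal rate of return.** `i = (I_n/V_0)^{1/n} − 1`, the per-period
compound growth of a nominal value. For fisher households the package
interprets the annual figures as: capital at risk `V_0 = cost`, gross
return `I_n = net + cost`, compounding monthly (`n = 12`). This is a
modelling decision — the source tables print only net income, cost and a
monthly NRR — and it is adopted because it reproduces all six published
NRR values (9.8, 10.5, 11.0, 11.4, 11.1, 10.9% per month) to the printed
decimal; no other simple assignment of `I_n`, `V_0`, `n` tested does.
The hump of NRR against cost (maximum 11.4% at 10 M IDR) is the
diminishing-marginal-returns signal `diminishing_returns()` reports.

**Income classing.** Sturges' rule as used here computes the class count
`round(1 + 3.332·log₁₀N)` and the class width `R/(1 + 3.332·log₁₀N)` from
the income range R. For the 30-household survey spanning 13–36 M IDR this
gives six classes of width 4 (13–16, 17–20, …, 33–36 M IDR).
`classify_households()` builds integer-bounded contiguous classes — by
default from the observed range, or from explicitly supplied bounds. The
explicit-bounds path exists because the packaged household records are
*reconstructed* from the published class summary (each class contributes
its household count at the class median income, which reproduces the
published totals exactly); their range (14.5–34.5) is narrower than the
underlying survey's, so the published bounds cannot be re-derived from
them and are passed through instead. Per-class daily income is
`total_net_income / total_persons / 365 / 13,300` (IDR per US$, the
scenario's fixed exchange rate); 365 days and that rate reproduce the
published US$ column to 3 significant figures.

**Wood versus fishing.** Annual wood income spreads the standing stock
over one rotation: `area × V × price / rotation` — 300 ha, the recomputed
age-20 volume (≈99.0 m³ ha⁻¹), IDR 500,000 m⁻³ and 20 years give
≈ IDR 742 million yr⁻¹. Per-person-per-day conversion divides by the
*full* community population (164 people) and 365 days: the published
daily figures reproduce only with 164, not with the 123 people actually
sampled, so the population is an explicit parameter defaulting to 164.
The community's annual fishing income (IDR 1,080,353,280) is not
derivable from the packaged income classes and enters the scenario as a
published constant. The overfishing rate,
`100·(fishing − wood)/wood` per person per day, is scale-invariant in
the currency and evaluates to ≈45.5% — fishing out-earns sustainable
wood harvest by nearly half, the scenario's proxy for fishing pressure.
(The source study also quotes 37.3% in one passage; that figure has no
reproducible derivation from the printed data and is not implemented.
Likewise its "Average" row US$1.43 is not consistent with the printed
column at the stated exchange rate; the package reports what it
computes.)

## The synthetic-data generator

The generator exists to make every pipeline stage testable, and to state
explicitly what structure the real data are assumed to have.

* **Diameter and height** follow Chapman–Richards curves
  `y(t) = y_max (1 − e^{−kt})^p` — the standard saturating mensuration
  form. Defaults are least-squares fits to the packaged pre-thinning
  trajectory: `d_max = 30` cm, `k_d = 0.025` yr⁻¹, `p_d = 0.85`;
  `h_max = 14.5` m, `k_h = 0.048` yr⁻¹, `p_h = 1.05`. With the stocking
  and form-factor defaults below, the implied MAI curve is unimodal and
  culminates at ages 22–23, inside the 20–30 window of the emulated
  stand.
* **Stocking** declines by exponential survival `N(t) = n0·e^{−mt}`
  (`n0 = 2450` stems ha⁻¹, `m = 0.029` yr⁻¹, natural mortality only;
  `m = 0` freezes stocking), rounded to whole stems.
* **Form factor** declines linearly from 0.85 to 0.60 across the
  generated age span — a shape statement, not a biological model.
* **Tree lists** draw diameters from a normal truncated at zero
  (mean 15 cm, sd 3 cm by default; the within-stand sd has no published
  anchor and is a free parameter) with heights from the deterministic
  relation `h = 1.3 + 0.55·d`.
* **Households** draw net incomes from a normal truncated to 13–36 M IDR
  (mean 24.5, sd 6), costs as a uniform 0.35–0.45 fraction of net income
  (the band observed across the published returns table), and sizes
  uniform on 3–5 persons.

Noise is optional and off by default so invariant tests are exact; when
enabled it is multiplicative normal with a stated CV on D and H. All
randomness flows from one integer seed per call through a private RNG
stream — the caller's `.Random.seed` is saved and restored, and identical
seeds give bit-identical output. Parameter recovery is tested by fitting
the curve form back to noise-free generator output with
`minpack.lm::nlsLM` (chosen for its robustness on zero-residual fits) and
requiring `d_max`, `k_d` within 1%.

What the generator does *not* emulate: tidal dynamics, recruitment,
competition, spatial structure, measurement error in N or F, or any
income–effort feedback. Tests that pass on synthetic data therefore
certify the *arithmetic pipeline*, not the ecology of real stands.

## Numerical and interface choices

* Domain errors (non-positive dimensions, form factor outside (0, 1],
  zero costs, empty inputs) fail fast with messages naming the
  constraint; CSV readers name the offending file line.
* Ages must be strictly increasing; single-row tables are legal (PAI
  absent).
* `which.max` tie-breaking (first maximum) is relied on for both the MAI
  peak and the NRR peak, giving deterministic earliest-occurrence
  behaviour.
* Currency arithmetic is in whole-rupiah floating point; million-IDR
  survey inputs are scaled by 10⁶ at the point of conversion.
* Problem sizes in the test-suite simulations (tree lists of 200–1000
  stems, 30–45-point age grids, 5-seed property loops) are desk-scale on
  purpose: the methods are closed-form, so small cases already exercise
  every branch.

## Known limitations

The mean-tree volume model ignores diameter-distribution effects; the
thinning contrast cannot attribute the MAI gain to thinning versus site
differences (the post-thinning table is observational); the valuation is
direct-use only — no carbon, protection or non-use values, no inflation
adjustment, no fish-species-level modelling; and the single inconsistent
published volume cell means age-40 post-thinning quantities recompute
~4% below their published counterparts.
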