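---
title: "Methods: the WBCS classification, its ruleset and the synthetic study conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the WBCS classification, its ruleset and the synthetic study conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbcs)
```

## The model

The Worldwide Bioclimatic Classification System (WBCS) of Rivas-Martínez
relates a small set of temperature/precipitation indices to the observed
distribution of plant species and communities, through nested units:
macrobioclimate → bioclimate and variant → bioclimatic belt (thermotype +
ombrotype). An isobioclimate — one bioclimate with one belt — is the
elemental bioclimatic space. The system is a *threshold* classification:
every unit is an interval lookup or a small predicate over the indices, so
the scientific content of an implementation is (a) computing the indices
exactly as defined and (b) carrying a faithful, auditable threshold table.

`bioclim_indices()` computes, per cell: monthly means `Ti = (tmin + tmax)/2`;
the annual mean `T`; warmest/coldest monthly means (`Tmax`, `Tmin`) and the
coldest month's extremes (`M`, `m`); positive temperature `Tp` (tenths of °C,
summing months with `Ti > 0`) and its summer restriction `Tps`; continentality
`Ic = Tmax − Tmin`; thermicity `It = (T + m + M) × 10` and its compensated
form `Itc = It + C(Ic)`; the precipitation aggregates (`P`, positive `Pp`,
seasonal `Ps`/`Pw`/`Pps`/`Ppw`, six-month `Pss`/`Psw`, and the four-month
windows `Pcm1`–`Pcm3` around the warmest four months); and the ombrothermic
family `Io`, `Iosi`, `Ios2`, `Iosc3`, `Iosc4`, `Iod2`. All ombrothermic
ratios are `10 ×` precipitation (mm) over positive temperature (tenths of
°C), restricted to months with `Ti > 0`.

Mediterraneity (summer aridity) is diagnosed by a cascade: `Ios2 ≤ 2` flags a
dry summer; the flag is cancelled when the whole summer quarter compensates
(`Iosc3 > 2`), or when the four-month extension compensates (`Iosc4 > 2`) in
rainy territories (`Io > 6`). Macrobioclimate identification uses thermal
values recomputed *as if the cell stood at 200 m* — monthly temperatures
shifted by `0.6 °C per 100 m` of elevation difference — so that mountains are
assigned to the macrobioclimate of their region rather than to a spuriously
cold one; thermotypes, by contrast, use the true-elevation `Itc` and `Tp`,
which is what places mountain belts (oro-, cryoro-, gelid) correctly.

## The ruleset

Every threshold lives in `inst/extdata/wbcs_ruleset_1.0.yaml`, loaded by
`default_ruleset()` and validated structurally (`validate_ruleset()`: each
table must tile its domain). The interval convention is uniform:
lower-closed, upper-open, with each table's final interval closed above —
necessary because printed WBCS tables share endpoints (e.g. eucontinental
28.0–37.0 / 37.0–46.0, so `Ic = 37` is "strong"). The continentality table,
the variant constants (steppe bounds `0.2 < Io ≤ 6.0`, monthly factors 3 and
2.8) and the thermotype dispatch rule (`Ic ≥ 21` or `Itc < 120` → classify by
`Tp`) follow the printed WBCS sources directly; the remaining bands —
macrobioclimate `Tp` limits (polar < 380, boreal < 720), bioclimate `Io`
splits (0.2 / 1.0 / 2.0 mediterranean; 3.6 for the temperate/boreal xeric
forms), thermotype `Itc`/`Tp` intervals, the ombrotype scale (0.2, 0.4, 1.0,
2.0, 3.6, 6.0, 12.0, 24.0) and the compensation steps — are transcribed from
the WBCS reference material (Rivas-Martínez, Rivas Sáenz & Penas, *Global
Geobotany* 1, 2011; globalbioclimatics.org). They are data, not code, so any
alternative transcription can be loaded and audited without touching the
package.

Parameters a user may care to vary, with defaults and why:

* `reduction$temperature_coeff_per_100m = 0.6` °C/100 m — the standard WBCS
  elevational reduction coefficient applied to monthly temperatures.
* `compensation`: `C(Ic) = 0` for `Ic` in [9, 18]; `−10 × (9 − Ic)` below;
  piecewise-linear above with factors 5 / 15 / 25 / 30 over breakpoints
  18 / 21 / 28 / 46, the last factor extending beyond 66 so that any
  physically valid `Ic` gets a value. `C` is monotone non-decreasing above
  the neutral band.
* `summer_aridity`: gates at 2.0 for `Ios2`, `Iosc3`, `Iosc4`; the `Iosc4`
  branch applies only where `Io > 6.0`. The WBCS sources leave the `Io`
  condition on the four-month compensation implicit; we resolve it as a
  rainy-territory floor at the humid/subhumid boundary (6.0), on the ground
  that a single pre-summer month can only plausibly offset a dry summer where
  the annual régime is wet.
* `ombrotype$snowy_tp_max = 100`: cells whose positive temperature stays
  below the gelid ceiling keep their precipitation largely as snow and their
  `Io` is undefined or unstable; they take the supersnowy code (`Ssnw`)
  rather than an `Io` class.

## Design choices where the system is genuinely open

* **Summer quarter**: June–August north of the equator, December–February
  south, resolved from the latitude sign; the winter quarter is opposite.
* **`Ios2`** uses the *contiguous* two-month sub-window of the summer quarter
  with the highest temperature sum ("warmest two-month period" implies
  contiguity); ties take the earlier pair.
* **Windowed parameters** (`Pcm1`, `Pss`, `Psw`, the driest quarter of
  `Iod2`) are contiguous calendar windows with wrap-around, selected by the
  extreme temperature (or precipitation) sum, ties broken by the earliest
  start month. `Iod2`'s two driest months within the driest quarter need not
  be contiguous.
* **Coldest-month ties** take the earliest calendar month for `M` and `m`.
* **Steppe monthly condition** `Psi < 3T` is read per summer month against
  that month's mean (`P_i < 3 T_i` for *every* summer month): the symbols are
  monthly, and requiring all months is the strict reading of a condition
  phrased as a property of the summer.
* **Variant precedence**: steppic, then submediterranean, then normal.
* **Degenerate cells**: `Tp = 0` leaves `Io` undefined (never infinite).
  Such cells route explicitly: polar cells below the pergelid `Tp200` bound
  take the pergelid bioclimate; in other cold macrobioclimates an undefined
  `Io` skips the xeric split (aridity cannot be assessed when nothing melts)
  and the cell takes its `Ic`-based form; the ombrotype is `Ssnw`. Values
  beyond a thermotype table's extremes take the nearest (warmest or coldest)
  class.
* **Diversity baseline**: classes present in the union of all periods but
  the last, compared with the final period — "loss" is a class present early
  and absent at the end.
* **Gains/losses** are final-period minus first-period percent, not a path
  sum over intermediate transitions.

## The synthetic study conditions

`synthetic_grid_spec()` encodes the grid the package is exercised on: 4569
cells at 0.22° between 40.5–55.5 °N and 46.5–87 °E (a strongly continental
mid-latitude country), three 25-year periods. Temperature is a cosine
seasonal cycle peaking in July (half-amplitude 16.5 ± 2 °C, putting most
plain cells at `Ic` 28–37) around an annual mean of 12.5 °C at the southern
edge, lapsing 0.6 °C per degree of latitude and 0.6 °C per 100 m of
elevation; 12 % of cells, drawn in the eastern part of the domain, get
mountain elevations (800–3500 m). Annual precipitation rises from 110 mm in
the south by 17 mm per degree northward and orographically by 35 % per km of
elevation; its monthly régime blends from a southern profile (spring maximum,
pronounced summer minimum — hence mediterranean summer aridity) to a northern
early-summer-maximum profile (hence a temperate north). Periods 2 and 3 add
+0.9/+1.5 and +1.8/+3.0 °C (winter/summer), with precipitation scaled by
0.99 and 0.98 — warming stronger in summer, precipitation near-stable.
Noise is small, seeded Gaussian: σ = 0.3 °C per cell-month, 5 % multiplicative
on precipitation; `tmax`/`tmin` sit ± 5 °C around the monthly mean. A seed
fully determines the output.

This emulates the dominant structure such a territory shows under a
summer-weighted warming scenario: a mediterranean south grading through
xeric and pluviseasonal continental belts to a temperate-xeric north,
supramediterranean plains, humid oro-belts on the mountains, steppic variants
over most of the territory, and period-to-period gains of the warm
thermotypes and the arid ombrotypes. It does **not** emulate spatial
autocorrelation (cells are independent draws), real orography or coastlines,
or the small boreal pocket such territories can host in a far-northeastern
massif — with the default gradients no cell's reduced `Tp` falls below the
boreal bound, so the boreal and polar branches are exercised by the analytic
fixtures instead. Passing tests on these grids therefore validates the
index arithmetic, the rule logic and the bookkeeping, not the climatology of
any real region.

`branch_fixtures()` complements the generator: it builds one cell per
classification branch *analytically from the ruleset* — solving the annual
level so that `Tp` (or `Itc`) lands at the midpoint of the target band
(monotone one-dimensional root finding, tolerance 1e-12), choosing the
elevation whose 200 m reduction lands `Tp200` mid-macrobioclimate where
needed, and distributing precipitation to hit the `Io` midpoint under a
prescribed summer régime (arid / steppic / wet / one submediterranean
month). Because every controlling index sits mid-interval, the fixtures are
insensitive to ±1e-6 perturbations, which the suite checks. A ruleset whose
intervals cannot host a fixture raises a configuration error.

## Numerical conventions

Percentages are `count / n_cells × 100`, kept at full precision internally
and rounded half-up (`round_half_up()`) only when tables are written (two
decimals by default, one for stability/diversity). Counts are exact
integers. Classification is pure: the same grid and ruleset give
bit-identical labels, and `run_pipeline()` re-runs byte-identically.

## Problem sizes used by the test suite

The acceptance-style checks run the full pipeline at the study size
(3 × 4569 cells, a few seconds) and the property checks on 120–300-cell
grids, 40-cell random batches, and 0.01-resolution sweeps of `Ic` over
[0, 66] and `Io` over [0, 30]; these sizes give dense coverage of every
threshold while keeping the whole suite near ten seconds.

## Known limitations

* The ruleset is one transcription of the WBCS synopsis; band values not
  printed in the primary sources (notably the boreal and polar thermotype
  subdivisions and the tropical tables, which this package carries for
  completeness but does not exercise) should be re-checked against
  globalbioclimatics.org before use outside mid-latitude continental
  settings.
* No spatial operations: cells are independent; no reprojection, clipping or
  raster I/O. GeoJSON output is plate carrée cell polygons.
* Monthly climatologies only — calendar months, no water-year option, no
  daily-resolution indices, no evapotranspiration-based aridity measures.
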