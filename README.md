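# wbcs

Worldwide bioclimatic classification of gridded monthly climatologies, and
comparison of classified grids across climate periods.

`wbcs` is for vegetation biogeographers, bioclimatologists and climate-impact
analysts who have gridded monthly climate data — observed climatologies or
regional climate-model output — and want to know which bioclimatic units
operate in each cell, and how those units shift between periods. It implements
the Rivas-Martínez Worldwide Bioclimatic Classification System (WBCS), a
hierarchical threshold classification whose units track the distribution of
plant species and communities: continentality, macrobioclimate, bioclimate,
bioclimatic variant, thermotype, ombrotype, and their combination, the
isobioclimate ("natural phytotron").

## The indices and the classification

From the twelve monthly mean daily minima `tmin_i`, maxima `tmax_i` (°C) and
precipitation totals `P_i` (mm) of a cell, with `T_i = (tmin_i + tmax_i)/2`:

- **Continentality index** `Ic = Tmax − Tmin`, the annual amplitude of the
  monthly means, classed into the hyperoceanic–hypercontinental scale.
- **Thermicity index** `It = (T + m + M) × 10`, where `m` and `M` are the mean
  daily minimum and maximum of the coldest month; compensated to
  `Itc = It + C(Ic)` outside the neutral continentality band.
- **Positive temperature** `Tp = 10 × Σ {T_i : T_i > 0}` (tenths of °C), with
  the summer-quarter form `Tps`.
- **Ombrothermic index** `Io = 10 × Pp / Tp`, positive precipitation over
  positive temperature; the summer forms `Iosi`, `Ios2`, `Iosc3`, `Iosc4`
  diagnose summer aridity: a cell is *mediterranean* when `Ios2 ≤ 2` and
  neither the summer quarter (`Iosc3`) nor its four-month extension (`Iosc4`,
  in rainy territories) compensates the drought.

Classification then proceeds hierarchically: macrobioclimates from the
thermal values recomputed as if the cell stood at 200 m; bioclimates from
`Ic` and `Io` (continental vs oceanic forms split at `Ic = 21`); the steppic
variant from `Ps ≥ Pw`, `0.2 < Io ≤ 6.0` and every summer month `P_i < 3 T_i`,
the submediterranean variant from any summer month with `P_i < 2.8 T_i`;
thermotypes from `Tp` or `Itc` (by `Tp` whenever `Ic ≥ 21` or `Itc < 120`);
ombrotypes from `Io` on a scale shared by all macrobioclimates. Every
threshold lives in a versioned YAML ruleset shipped with the package
(`inst/extdata/wbcs_ruleset_1.0.yaml`) — the code carries no hard-wired
numbers, and a modified ruleset can be supplied to any function.

## Worked example

```r
library(wbcs)

# three 25-year periods of a strongly continental synthetic territory
grids  <- generate_grid(synthetic_grid_spec(seed = 42))
labels <- lapply(grids, classify_grid)
area_table(labels, "macrobioclimate")
#>          class n_1980-2004 pct_1980-2004 n_2010-2034 pct_2010-2034 n_2035-2059 pct_2035-2059 delta_pct
#>  MEDITERRANEAN        3512         76.87        3727         81.57        3941         86.26      9.39
#>      TEMPERATE        1057         23.13         842         18.43         628         13.74     -9.39
```

The table counts cells per macrobioclimate and period and expresses them as
percent of territory; `delta_pct` is the final-period minus first-period
percent. Here summer-weighted warming expands the mediterranean
(summer-arid) macrobioclimate by 9.4 points at the temperate one's expense.

```r
stability_fraction(labels, "isobioclimate")
#>           unit n_cells n_stable stable_pct change_pct
#>  isobioclimate    4569     1980   43.33552   56.66448
```

43.3 % of cells keep the same isobioclimate — the same bioclimate, thermotype
and ombrotype — through all three periods. Single cells classify too:

```r
fx <- branch_fixtures()                       # analytic one-cell-per-branch grid
classify_cell(fx$cells[fx$cells$cell_id == "MEDC_Sme_Ari", ])$isobioclimate
#> [1] "MEDC Sme Ari"
isobioclimate_name("MEDC Sme Ari")
#> [1] "mediterranean desertic continental, supramediterranean, arid"
```

`run_pipeline()` does all of the above at once and writes classified grids
(CSV/GeoJSON choropleth polygons), an area table per unit, change and
stability tables, the diversity summary, trend groupings and a run manifest.

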