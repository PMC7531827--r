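# Synthetic monthly climatologies.
#
# Two generators live here. generate_grid() draws multi-period grids with the
# statistical structure of a strongly continental mid-latitude territory:
# a cosine seasonal cycle peaking in July, latitudinal and elevational lapse,
# a south-to-north humidity gradient whose monthly regime shifts from a dry
# summer in the south to a summer maximum in the north, orographic wetting on
# mountain cells, and period-to-period warming that is larger in summer than
# in winter over near-stable precipitation. branch_fixtures() instead builds a
# small deterministic grid analytically from a ruleset's thresholds, one cell
# per classification branch, with every controlling index placed mid-interval.

seasonal_shape <- function() cospi(((1:12) - 7) / 6)   # +1 in July, -1 in January

#' Specification of a synthetic multi-period climate grid
#'
#' Defaults emulate the study conditions of a large, strongly continental
#' mid-latitude country on a 0.22 degree grid: 4569 cells between 40.5 and
#' 55.5 degrees N, annual thermal amplitude placing most plain cells at
#' continentality index 28-37, an arid south grading to a subhumid north,
#' mountain cells with elevational cooling and orographic wetting, and three
#' 25-year periods whose warming is summer-weighted with near-stable
#' precipitation.
#'
#' @param n_cells number of grid cells.
#' @param lat_range,lon_range latitude / longitude bounds, degrees.
#' @param mountain_fraction fraction of cells given mountain elevations (drawn
#'   in the eastern part of the domain).
#' @param mountain_elev_range,plain_elev_range elevation bounds, m.
#' @param baseline_t annual-mean temperature at the southern edge for a
#'   200 m cell, degrees C.
#' @param lat_lapse cooling per degree of latitude northward, degrees C.
#' @param elev_lapse cooling per 100 m of elevation above 200 m, degrees C.
#' @param amplitude seasonal half peak-to-trough amplitude, degrees C (the
#'   continentality index of a noise-free cell is twice this).
#' @param amplitude_jitter per-cell uniform jitter of the amplitude, degrees C.
#' @param diurnal_half_range half distance between tmax and tmin, degrees C.
#' @param prec_base annual precipitation at the southern edge, mm.
#' @param prec_lat_gradient added annual precipitation per degree northward, mm.
#' @param orographic_factor fractional precipitation increase per km of
#'   elevation above 200 m.
#' @param period_labels labels of the successive periods.
#' @param period_t_winter,period_t_summer per-period temperature offsets in
#'   the coldest / warmest month, degrees C (summer offset must not be below
#'   the winter offset; intermediate months are blended along the seasonal
#'   shape).
#' @param period_prec_scale per-period multiplicative precipitation factor.
#' @param noise_sd_t standard deviation of the per-cell-month temperature
#'   noise, degrees C.
#' @param noise_frac_prec standard deviation of the multiplicative
#'   precipitation noise.
#' @param seed integer seed; the seed fully determines the output.
#' @return an object of class `wbcs_synth_spec`.
#' @export
synthetic_grid_spec <- function(n_cells = 4569,
                                lat_range = c(40.5, 55.5),
                                lon_range = c(46.5, 87.0),
                                mountain_fraction = 0.12,
                                mountain_elev_range = c(800, 3500),
                                plain_elev_range = c(100, 600),
                                baseline_t = 12.5,
                                lat_lapse = 0.6,
                                elev_lapse = 0.6,
                                amplitude = 16.5,
                                amplitude_jitter = 2,
                                diurnal_half_range = 5,
                                prec_base = 110,
                                prec_lat_gradient = 17,
                                orographic_factor = 0.35,
                                period_labels = c("1980-2004", "2010-2034",
                                                  "2035-2059"),
                                period_t_winter = c(0, 0.9, 1.8),
                                period_t_summer = c(0, 1.5, 3.0),
                                period_prec_scale = c(1, 0.99, 0.98),
                                noise_sd_t = 0.3,
                                noise_frac_prec = 0.05,
                                seed = 1L) {
  spec <- as.list(environment())
  np <- length(period_labels)
  if (n_cells < 1) abort_wbcs("n_cells must be >= 1", "wbcs_config_error")
  if (length(period_t_winter) != np || length(period_t_summer) != np ||
      length(period_prec_scale) != np) {
    abort_wbcs("period offset vectors must match period_labels in length",
               "wbcs_config_error")
  }
  if (any(period_t_summer < period_t_winter)) {
    abort_wbcs("summer offsets must not be below winter offsets",
               "wbcs_config_error")
  }
  if (amplitude - amplitude_jitter < 0 || diurnal_half_range < 0) {
    abort_wbcs("amplitude and diurnal range must be non-negative",
               "wbcs_config_error")
  }
  class(spec) <- "wbcs_synth_spec"
  spec
}

# Monthly precipitation regimes, as fractions of the annual total: the
# southern profile has a spring maximum and a pronounced summer minimum, the
# northern one an early-summer maximum.
prec_weights_south <- c(0.05, 0.05, 0.10, 0.13, 0.13, 0.08,
                        0.04, 0.04, 0.07, 0.12, 0.11, 0.08)
prec_weights_north <- c(0.05, 0.05, 0.06, 0.08, 0.10, 0.13,
                        0.13, 0.11, 0.08, 0.08, 0.07, 0.06)

#' Generate synthetic climate grids for successive periods
#'
#' Draws one `climate_grid` per period from a [synthetic_grid_spec()]. Monthly
#' mean temperature is `baseline - lat_lapse * (lat - lat_south) - elev_lapse
#' * (elev - 200)/100 + amplitude * cos(seasonal) + period offset + noise`;
#' precipitation distributes a latitude- and elevation-dependent annual total
#' over a monthly regime that blends from the southern to the northern profile
#' with latitude, scaled per period and perturbed multiplicatively. `tmax` and
#' `tmin` are the monthly mean plus/minus the diurnal half-range. The same
#' spec (including its seed) always reproduces the same grids.
#'
#' @param spec a `wbcs_synth_spec`.
#' @return named list of `climate_grid` objects, one per period.
#' @export
#' @examples
#' grids <- generate_grid(synthetic_grid_spec(n_cells = 10))
#' names(grids)
generate_grid <- function(spec) {
  if (!inherits(spec, "wbcs_synth_spec")) {
    abort_wbcs("spec must be a wbcs_synth_spec", "wbcs_config_error")
  }
  set.seed(spec$seed)
  n <- spec$n_cells
  lat <- stats::runif(n, spec$lat_range[1], spec$lat_range[2])
  lon <- stats::runif(n, spec$lon_range[1], spec$lon_range[2])
  elev <- stats::runif(n, spec$plain_elev_range[1], spec$plain_elev_range[2])
  east <- which(lon >= spec$lon_range[1] + 0.6 * diff(spec$lon_range))
  n_mtn <- min(length(east), round(spec$mountain_fraction * n))
  if (n_mtn > 0) {
    mtn <- east[sample.int(length(east), n_mtn)]
    elev[mtn] <- stats::runif(n_mtn, spec$mountain_elev_range[1],
                              spec$mountain_elev_range[2])
  }
  ampl <- spec$amplitude +
    stats::runif(n, -spec$amplitude_jitter, spec$amplitude_jitter)

  s <- seasonal_shape()
  t_mean <- spec$baseline_t - spec$lat_lapse * (lat - spec$lat_range[1]) -
    spec$elev_lapse * (elev - 200) / 100
  ti_base <- outer(t_mean, rep(1, 12)) + outer(ampl, s)

  f <- (lat - spec$lat_range[1]) / diff(spec$lat_range)
  w <- outer(1 - f, prec_weights_south) + outer(f, prec_weights_north)
  p_annual <- (spec$prec_base + spec$prec_lat_gradient *
                 (lat - spec$lat_range[1])) *
    (1 + spec$orographic_factor * pmax(elev - 200, 0) / 1000)
  prec_base_mat <- p_annual * w

  sw <- (s + 1) / 2   # 0 in the coldest month, 1 in the warmest
  grids <- vector("list", length(spec$period_labels))
  names(grids) <- spec$period_labels
  for (p in seq_along(spec$period_labels)) {
    off <- spec$period_t_winter[p] +
      (spec$period_t_summer[p] - spec$period_t_winter[p]) * sw
    ti <- ti_base + matrix(off, n, 12, byrow = TRUE) +
      matrix(stats::rnorm(n * 12, 0, spec$noise_sd_t), n, 12)
    prec <- prec_base_mat * spec$period_prec_scale[p] *
      pmax(matrix(1 + stats::rnorm(n * 12, 0, spec$noise_frac_prec), n, 12), 0)
    cells <- data.frame(cell_id = sprintf("c%05d", seq_len(n)),
                        lat = lat, lon = lon, elev_m = elev,
                        stringsAsFactors = FALSE)
    cells[, month_cols("tmin")] <- ti - spec$diurnal_half_range
    cells[, month_cols("tmax")] <- ti + spec$diurnal_half_range
    cells[, month_cols("prec")] <- prec
    grids[[p]] <- climate_grid(cells, period_label = spec$period_labels[p])
  }
  grids
}

# ---- analytic branch fixtures -----------------------------------------------

# Annual-mean level placing the cosine profile's positive temperature sum at
# tp_target (tenths of degC), for a given half-amplitude.
solve_tm_for_tp <- function(tp_target, half_amplitude) {
  s <- seasonal_shape()
  f <- function(tm) 10 * sum(pmax(tm + half_amplitude * s, 0)) - tp_target
  if (f(100) < 0 || f(-100) > 0) {
    abort_wbcs("unreachable Tp target in fixture construction",
               "wbcs_config_error")
  }
  stats::uniroot(f, c(-100, 100), tol = 1e-12)$root
}

# Elevation whose 200 m reduction shift moves the profile's positive
# temperature sum to tp200_target.
solve_elev_for_tp200 <- function(ti, tp200_target, ruleset) {
  coeff <- ruleset$reduction$temperature_coeff_per_100m
  ref <- ruleset$reduction$reference_elevation_m
  f <- function(e) {
    10 * sum(pmax(ti + coeff * (e - ref) / 100, 0)) - tp200_target
  }
  if (f(ref) > 0) return(ref)   # already above target at the reference height
  if (f(20000) < 0) {
    abort_wbcs("unreachable Tp200 target in fixture construction",
               "wbcs_config_error")
  }
  stats::uniroot(f, c(ref, 20000), tol = 1e-9)$root
}

# Distribute an annual positive-precipitation total over the months. The
# regime fixes the summer months (and zeroes the month before summer so the
# four-month compensable index stays controlled):
#   arid    no precipitation in May-August
#   steppe  summer months get 2.5 * Ti  (steppic: below the 3 * Ti bound)
#   wet     summer months get 3.5 * Ti  (above every variant bound)
#   subm    3.5 / 2.5 / 3.5 * Ti        (one submediterranean month)
# The remainder is spread over the other months with Ti > 0, proportionally to
# Ti; if no such month exists it is added to the positive summer months.
fixture_prec <- function(ti, pp_target, regime, summer = 6:8) {
  fac <- switch(regime,
                arid = c(0, 0, 0),
                steppe = c(2.5, 2.5, 2.5),
                wet = c(3.5, 3.5, 3.5),
                subm = c(3.5, 2.5, 3.5),
                abort_wbcs(sprintf("unknown regime %s", regime),
                           "wbcs_config_error"))
  prec <- numeric(12)
  pos <- ti > 0
  prec[summer] <- ifelse(pos[summer], fac * ti[summer], 0)
  rest <- pp_target - sum(prec)
  if (rest < -1e-9) {
    abort_wbcs("fixture infeasible: summer regime exceeds the Io budget",
               "wbcs_config_error")
  }
  pre_summer <- ((summer[1] - 2L) %% 12L) + 1L
  open <- setdiff(which(pos), c(summer, pre_summer))
  if (length(open) == 0L) open <- intersect(summer, which(pos))
  if (length(open) == 0L) {
    abort_wbcs("fixture infeasible: no month can carry precipitation",
               "wbcs_config_error")
  }
  prec[open] <- prec[open] + rest * ti[open] / sum(ti[open])
  prec
}

# Midpoint of the intersection of Io intervals; an open upper end takes 1.5x
# the lower bound.
io_midpoint <- function(lo, hi) {
  lo <- max(lo); hi <- min(hi)
  if (hi <= lo) {
    abort_wbcs("fixture infeasible: empty Io interval intersection",
               "wbcs_config_error")
  }
  if (is.infinite(hi)) lo * 1.5 else (lo + hi) / 2
}

band_mid <- function(tbl, code, min_key = "min", max_key = "max") {
  k <- which(band_codes(tbl) == code)
  if (!length(k)) {
    abort_wbcs(sprintf("fixture infeasible: no band for code %s", code),
               "wbcs_config_error")
  }
  lo <- band_mins(tbl, min_key)[k]; hi <- band_maxs(tbl, max_key)[k]
  if (is.infinite(hi)) lo + 250 else (lo + hi) / 2
}

io_band <- function(tbl, code) {
  k <- which(band_codes(tbl) == code)
  c(band_mins(tbl, "io_min")[k], band_maxs(tbl, "io_max")[k])
}

ic_mid <- function(ruleset, subtype, level) {
  rows <- ruleset$continentality$rows
  k <- which(vapply(rows, function(r) r$subtype, "") == subtype &
               vapply(rows, function(r) r$level, "") == level)[1]
  (rows[[k]]$ic_min + rows[[k]]$ic_max) / 2
}

#' Deterministic fixtures covering every classification branch
#'
#' Builds a small climate grid, one cell per targeted class combination,
#' analytically from a ruleset's thresholds: each controlling index (Ic, Tp or
#' Itc, Io) is placed at the midpoint of its target interval, so no fixture
#' sits near a class boundary. Together the cells cover all bioclimates,
#' thermotypes, ombrotypes, variants and continentality subtypes a strongly
#' continental mid-latitude territory with high mountains can host:
#' 10 bioclimates, 11 thermotypes, 10 ombrotypes (including the supersnowy
#' branch), the three variants and 4 continentality subtypes.
#'
#' @param ruleset a `wbcs_ruleset`. A ruleset whose intervals cannot host a
#'   fixture (empty intersections, unreachable targets) raises a
#'   configuration error.
#' @return a `climate_grid` with attribute `expected`: a data frame of the
#'   intended `bioclimate`, `thermotype`, `ombrotype` and `variant` per cell.
#' @export
#' @examples
#' fx <- branch_fixtures()
#' attr(fx, "expected")[1, ]
branch_fixtures <- function(ruleset = default_ruleset()) {
  tt <- ruleset$thermotype
  ob <- ruleset$ombrotype$classes
  bc <- ruleset$bioclimate$mediterranean$io_classes
  med_band <- function(code) {   # Io band of a mediterranean bioclimate code
    k <- which(vapply(bc, function(r) r$continental, "") == code |
                 vapply(bc, function(r) r$oceanic, "") == code)
    c(band_mins(bc, "io_min")[k], band_maxs(bc, "io_max")[k])
  }
  temp_wet <- c(ruleset$bioclimate$temperate$xeric_io_max, Inf)
  temp_dry <- c(0, ruleset$bioclimate$temperate$xeric_io_max)
  bor_wet <- c(ruleset$bioclimate$boreal$xeric_io_max, Inf)
  bor_dry <- c(0, ruleset$bioclimate$boreal$xeric_io_max)
  euw <- ic_mid(ruleset, "Eucontinental", "weak")
  boreal_tp200 <- (ruleset$macrobioclimate$polar_tp200_max +
                     ruleset$macrobioclimate$boreal_tp200_max) / 2
  warm_tp200 <- ruleset$macrobioclimate$boreal_tp200_max + 280

  # One row per fixture: thermal target (Tp or Itc band of a thermotype),
  # Io target (intersection of the bioclimate and ombrotype bands), summer
  # regime and the Ic subtype/level.
  fx <- list(
    list(id = "MEDC_Sme_Ari", bio = "MEDC", th = "Sme", om = "Ari", var = "Stp",
         ic = euw, tp = band_mid(tt$mediterranean$tp, "Sme"),
         io = io_midpoint(c(med_band("MEDC")[1], io_band(ob, "Ari")[1]),
                          c(med_band("MEDC")[2], io_band(ob, "Ari")[2])),
         regime = "arid"),
    list(id = "MEDC_Mme_Har", bio = "MEDC", th = "Mme", om = "Har", var = "Nor",
         ic = euw, tp = band_mid(tt$mediterranean$tp, "Mme"),
         io = io_midpoint(c(med_band("MEDC")[1], io_band(ob, "Har")[1]),
                          c(med_band("MEDC")[2], io_band(ob, "Har")[2])),
         regime = "arid"),
    list(id = "MEDC_Tme_Ari", bio = "MEDC", th = "Tme", om = "Ari", var = "Nor",
         ic = euw, tp = band_mid(tt$mediterranean$tp, "Tme"),
         io = io_midpoint(c(med_band("MEDC")[1], io_band(ob, "Ari")[1]),
                          c(med_band("MEDC")[2], io_band(ob, "Ari")[2])),
         regime = "arid"),
    list(id = "MEHC_Sme_Uha", bio = "MEHC", th = "Sme", om = "Uha", var = "Nor",
         ic = euw, tp = band_mid(tt$mediterranean$tp, "Sme"),
         io = io_midpoint(c(med_band("MEHC")[1], io_band(ob, "Uha")[1]),
                          c(med_band("MEHC")[2], io_band(ob, "Uha")[2])),
         regime = "arid"),
    list(id = "MEXC_Sme_Sar", bio = "MEXC", th = "Sme", om = "Sar", var = "Stp",
         ic = euw, tp = band_mid(tt$mediterranean$tp, "Sme"),
         io = io_midpoint(c(med_band("MEXC")[1], io_band(ob, "Sar")[1]),
                          c(med_band("MEXC")[2], io_band(ob, "Sar")[2])),
         regime = "arid"),
    list(id = "MEXC_Sme_Sar_hyper", bio = "MEXC", th = "Sme", om = "Sar",
         var = "Stp", ic = ic_mid(ruleset, "Hypercontinental", "weak"),
         tp = band_mid(tt$mediterranean$tp, "Sme"),
         io = io_midpoint(c(med_band("MEXC")[1], io_band(ob, "Sar")[1]),
                          c(med_band("MEXC")[2], io_band(ob, "Sar")[2])),
         regime = "arid"),
    list(id = "MEXO_Sme_Sar", bio = "MEXO", th = "Sme", om = "Sar", var = "Nor",
         ic = ic_mid(ruleset, "Semicontinental", "strong"),
         itc = band_mid(tt$mediterranean$itc, "Sme"),
         io = io_midpoint(c(med_band("MEXO")[1], io_band(ob, "Sar")[1]),
                          c(med_band("MEXO")[2], io_band(ob, "Sar")[2])),
         regime = "arid"),
    list(id = "MEDO_Mme_Ari", bio = "MEDO", th = "Mme", om = "Ari", var = "Nor",
         ic = ic_mid(ruleset, "Semicontinental", "strong"),
         itc = band_mid(tt$mediterranean$itc, "Mme"),
         io = io_midpoint(c(med_band("MEDO")[1], io_band(ob, "Ari")[1]),
                          c(med_band("MEDO")[2], io_band(ob, "Ari")[2])),
         regime = "arid"),
    list(id = "MEPC_Sme_Sec", bio = "MEPC", th = "Sme", om = "Sec", var = "Stp",
         ic = euw, tp = band_mid(tt$mediterranean$tp, "Sme"),
         io = io_midpoint(c(med_band("MEPC")[1], io_band(ob, "Sec")[1]),
                          c(med_band("MEPC")[2], io_band(ob, "Sec")[2])),
         regime = "arid"),
    list(id = "MEPC_Ome_Shu", bio = "MEPC", th = "Ome", om = "Shu", var = "Stp",
         ic = euw, tp = band_mid(tt$mediterranean$tp, "Ome"),
         io = io_midpoint(c(med_band("MEPC")[1], io_band(ob, "Shu")[1]),
                          c(med_band("MEPC")[2], io_band(ob, "Shu")[2])),
         regime = "arid", tp200 = warm_tp200),
    list(id = "MEPC_Ome_Hum", bio = "MEPC", th = "Ome", om = "Hum", var = "Nor",
         ic = euw, tp = band_mid(tt$mediterranean$tp, "Ome"),
         io = io_midpoint(c(med_band("MEPC")[1], io_band(ob, "Hum")[1]),
                          c(med_band("MEPC")[2], io_band(ob, "Hum")[2])),
         regime = "arid", tp200 = warm_tp200),
    list(id = "MEPC_Cme_Shu", bio = "MEPC", th = "Cme", om = "Shu", var = "Stp",
         ic = euw, tp = band_mid(tt$mediterranean$tp, "Cme"),
         io = io_midpoint(c(med_band("MEPC")[1], io_band(ob, "Shu")[1]),
                          c(med_band("MEPC")[2], io_band(ob, "Shu")[2])),
         regime = "arid", tp200 = warm_tp200),
    list(id = "TEXE_Ste_Sec", bio = "TEXE", th = "Ste", om = "Sec", var = "Stp",
         ic = euw, tp = band_mid(tt$temperate$tp, "Ste"),
         io = io_midpoint(c(temp_dry[1], io_band(ob, "Sec")[1]),
                          c(temp_dry[2], io_band(ob, "Sec")[2])),
         regime = "steppe"),
    list(id = "TECO_Ste_Shu_sbm", bio = "TECO", th = "Ste", om = "Shu",
         var = "Sbm", ic = ic_mid(ruleset, "Subcontinental", "weak"),
         tp = band_mid(tt$temperate$tp, "Ste"),
         io = io_midpoint(c(temp_wet[1], io_band(ob, "Shu")[1]),
                          c(temp_wet[2], io_band(ob, "Shu")[2])),
         regime = "subm"),
    list(id = "TECO_Ote_Hum", bio = "TECO", th = "Ote", om = "Hum", var = "Nor",
         ic = euw, tp = band_mid(tt$temperate$tp, "Ote"),
         io = io_midpoint(c(temp_wet[1], io_band(ob, "Hum")[1]),
                          c(temp_wet[2], io_band(ob, "Hum")[2])),
         regime = "wet", tp200 = warm_tp200),
    list(id = "TECO_Cte_Hhu", bio = "TECO", th = "Cte", om = "Hhu", var = "Nor",
         ic = euw, tp = band_mid(tt$temperate$tp, "Cte"),
         io = io_midpoint(c(temp_wet[1], io_band(ob, "Hhu")[1]),
                          c(temp_wet[2], io_band(ob, "Hhu")[2])),
         regime = "wet", tp200 = warm_tp200),
    list(id = "TECO_Cte_Uhh", bio = "TECO", th = "Cte", om = "Uhh", var = "Nor",
         ic = euw, tp = band_mid(tt$temperate$tp, "Cte"),
         io = io_midpoint(c(temp_wet[1], io_band(ob, "Uhh")[1]),
                          c(temp_wet[2], io_band(ob, "Uhh")[2])),
         regime = "wet", tp200 = warm_tp200),
    list(id = "TECO_Gel_Ssnw", bio = "TECO", th = "Gel",
         om = ruleset$ombrotype$snowy_code, var = "Nor",
         ic = euw, tp = band_mid(tt$temperate$tp, "Gel"),
         io = io_midpoint(c(temp_wet[1]), c(Inf)),
         regime = "wet", tp200 = warm_tp200),
    list(id = "BOCO_Obo_Shu", bio = "BOCO", th = "Obo", om = "Shu", var = "Stp",
         ic = euw, tp = band_mid(tt$boreal$tp, "Obo"),
         io = io_midpoint(c(bor_wet[1], io_band(ob, "Shu")[1]),
                          c(bor_wet[2], io_band(ob, "Shu")[2])),
         regime = "steppe", tp200 = boreal_tp200),
    list(id = "BOXE_Obo_Sec", bio = "BOXE", th = "Obo", om = "Sec", var = "Stp",
         ic = euw, tp = band_mid(tt$boreal$tp, "Obo"),
         io = io_midpoint(c(bor_dry[1], io_band(ob, "Sec")[1]),
                          c(bor_dry[2], io_band(ob, "Sec")[2])),
         regime = "steppe", tp200 = boreal_tp200),
    list(id = "BOCO_Cbo_Hum", bio = "BOCO", th = "Cbo", om = "Hum", var = "Nor",
         ic = euw, tp = band_mid(tt$boreal$tp, "Cbo"),
         io = io_midpoint(c(bor_wet[1], io_band(ob, "Hum")[1]),
                          c(bor_wet[2], io_band(ob, "Hum")[2])),
         regime = "wet", tp200 = boreal_tp200)
  )

  rows <- lapply(fx, function(x) {
    a <- x$ic / 2
    s <- seasonal_shape()
    if (!is.null(x$itc)) {
      # thermotype targeted through Itc: It = (T + m + M)*10 = (3*Tm - 2*A)*10
      # for the cosine profile (the coldest month's extremes are Tm - A -/+
      # the diurnal half-range, which cancels in m + M).
      C <- continentality_compensation(x$ic, ruleset)
      tm <- ((x$itc - C) / 10 + 2 * a) / 3
    } else {
      tm <- solve_tm_for_tp(x$tp, a)
    }
    ti <- tm + a * s
    elev <- ruleset$reduction$reference_elevation_m
    if (!is.null(x$tp200)) elev <- solve_elev_for_tp200(ti, x$tp200, ruleset)
    tp <- 10 * sum(pmax(ti, 0))
    prec <- fixture_prec(ti, x$io * tp / 10, x$regime)
    cell <- data.frame(cell_id = x$id, lat = 48, lon = 70, elev_m = elev,
                       stringsAsFactors = FALSE)
    cell[, month_cols("tmin")] <- rbind(ti - 5)
    cell[, month_cols("tmax")] <- rbind(ti + 5)
    cell[, month_cols("prec")] <- rbind(prec)
    cell
  })
  cells <- do.call(rbind, rows)
  grid <- climate_grid(cells, period_label = "fixtures")
  attr(grid, "expected") <- data.frame(
    cell_id = vapply(fx, function(x) x$id, ""),
    bioclimate = vapply(fx, function(x) x$bio, ""),
    thermotype = vapply(fx, function(x) x$th, ""),
    ombrotype = vapply(fx, function(x) x$om, ""),
    variant = vapply(fx, function(x) x$var, ""),
    stringsAsFactors = FALSE
  )
  grid
}
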