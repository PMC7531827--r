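# Climatic parameters and bioclimatic indices.
#
# All quantities follow the WBCS conventions: monthly mean temperature Ti is
# the average of the monthly mean daily minimum and maximum; positive
# temperature sums (Tp, Tps) are expressed in tenths of a degree; ombrothermic
# indices are 10 * precipitation (mm) / positive temperature (tenths of degC).
# The summer quarter is June-August in the northern hemisphere and
# December-February in the southern one, resolved from the latitude sign.

#' Monthly mean temperatures
#'
#' `Ti = (tmin_i + tmax_i) / 2` for each calendar month.
#'
#' @param tmin,tmax numeric vectors of length 12 (or n x 12 matrices) of
#'   monthly mean daily minimum / maximum temperature, degrees C, Jan-Dec.
#' @return object of the same shape with the monthly means.
#' @export
#' @examples
#' monthly_means(rep(-20, 12), rep(-10, 12))[1]
monthly_means <- function(tmin, tmax) (tmin + tmax) / 2

# Coerce a length-12 vector to a 1 x 12 matrix.
as_row <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1)
}

#' Thermal parameters of one cell
#'
#' Computes, from the monthly means and the monthly extremes, the annual mean
#' `T`, the warmest and coldest monthly means `Tmax`/`Tmin`, the mean daily
#' maximum `M` and minimum `m` of the coldest month (ties broken by the
#' earliest calendar month), the positive annual temperature `Tp` and its
#' summer-quarter restriction `Tps` (tenths of degC), the continentality index
#' `Ic = Tmax - Tmin` and the thermicity index `It = (T + m + M) * 10`.
#'
#' @param Ti monthly mean temperatures (length 12).
#' @param tmin,tmax monthly mean daily minima / maxima (length 12).
#' @param summer month indices of the summer quarter (default 6:8).
#' @return named list with `T`, `Tmax`, `Tmin`, `M`, `m`, `Tp`, `Tps`, `Ic`,
#'   `It` and `coldest_month`.
#' @export
#' @examples
#' thermal_parameters(rep(10, 12), rep(5, 12), rep(15, 12))$Tp
thermal_parameters <- function(Ti, tmin, tmax, summer = 6:8) {
  TI <- as_row(Ti); TMIN <- as_row(tmin); TMAX <- as_row(tmax)
  cold <- max.col(-TI, ties.method = "first")
  i <- seq_len(nrow(TI))
  out <- list(
    T = rowMeans(TI),
    Tmax = apply(TI, 1, max),
    Tmin = apply(TI, 1, min),
    M = TMAX[cbind(i, cold)],
    m = TMIN[cbind(i, cold)],
    Tp = 10 * rowSums(pmax(TI, 0)),
    Tps = 10 * rowSums(pmax(TI[, summer, drop = FALSE], 0)),
    coldest_month = cold
  )
  out$Ic <- out$Tmax - out$Tmin
  out$It <- (out$T + out$m + out$M) * 10
  if (length(Ti) == 12 && !is.matrix(Ti)) out <- lapply(out, unname)
  out
}

#' Precipitation parameters of one cell
#'
#' Annual (`P`), positive (`Pp`: months with `Ti > 0`), summer- and
#' winter-quarter (`Ps`, `Pw`, and positive forms `Pps`, `Ppw`) precipitation;
#' precipitation of the warmest / coldest six contiguous months (`Pss`,
#' `Psw`); and the four-month windows around the warmest four months of the
#' year: `Pcm1` (the contiguous four-month window with the highest temperature
#' sum, calendar wrap-around allowed, ties broken by the earliest start
#' month), `Pcm2` (the four months after that window) and `Pcm3` (the four
#' months before it).
#'
#' @param prec monthly precipitation totals, mm (length 12).
#' @param Ti monthly mean temperatures (length 12).
#' @param summer month indices of the summer quarter; the winter quarter is
#'   the opposite one.
#' @return named list of the quantities above.
#' @export
precipitation_parameters <- function(prec, Ti, summer = 6:8) {
  PREC <- as_row(prec); TI <- as_row(Ti)
  winter <- ((summer - 1L + 6L) %% 12L) + 1L
  pos <- TI > 0
  i <- seq_len(nrow(TI))
  w6t <- wrap_window_sums(TI, 6L); w6p <- wrap_window_sums(PREC, 6L)
  s_warm6 <- max.col(w6t, ties.method = "first")
  s_cold6 <- max.col(-w6t, ties.method = "first")
  w4t <- wrap_window_sums(TI, 4L); w4p <- wrap_window_sums(PREC, 4L)
  s4 <- max.col(w4t, ties.method = "first")
  s4_after <- ((s4 - 1L + 4L) %% 12L) + 1L
  s4_before <- ((s4 - 1L - 4L) %% 12L) + 1L
  out <- list(
    P = rowSums(PREC),
    Pp = rowSums(PREC * pos),
    Ps = rowSums(PREC[, summer, drop = FALSE]),
    Pw = rowSums(PREC[, winter, drop = FALSE]),
    Pps = rowSums((PREC * pos)[, summer, drop = FALSE]),
    Ppw = rowSums((PREC * pos)[, winter, drop = FALSE]),
    Pss = w6p[cbind(i, s_warm6)],
    Psw = w6p[cbind(i, s_cold6)],
    Pcm1 = w4p[cbind(i, s4)],
    Pcm2 = w4p[cbind(i, s4_after)],
    Pcm3 = w4p[cbind(i, s4_before)],
    warm4_start = s4
  )
  if (length(prec) == 12 && !is.matrix(prec)) out <- lapply(out, unname)
  out
}

# 10 * precipitation / positive temperature-in-tenths over a set of months,
# NA where no month contributes positive temperature.
ombro_ratio <- function(PREC, TI, months) {
  TIm <- TI[, months, drop = FALSE]
  PRm <- PREC[, months, drop = FALSE]
  pos <- TIm > 0
  tp <- 10 * rowSums(pmax(TIm, 0))
  p <- rowSums(PRm * pos)
  ifelse(tp > 0, 10 * p / tp, NA_real_)
}

#' Ombrothermic indices of one cell
#'
#' The annual ombrothermic index `Io = 10 * Pp / Tp` (`NA` when `Tp = 0`: such
#' cells are routed to the degenerate branch by the classifier, never given an
#' infinite Io); the per-summer-month indices `Iosi`; `Ios2` over the
#' contiguous two warmest summer months; the compensable indices `Iosc3` (the
#' summer quarter) and `Iosc4` (the summer quarter plus the immediately
#' preceding month); and `Iod2`, over the two driest months of the driest
#' contiguous quarter of the year.
#'
#' @inheritParams precipitation_parameters
#' @return named list with `Io`, `Iosi` (length 3, one per summer month),
#'   `Ios2`, `Iosc3`, `Iosc4`, `Iod2`.
#' @export
#' @examples
#' ombrothermic_indices(rep(20, 12), rep(10, 12))$Io
ombrothermic_indices <- function(prec, Ti, summer = 6:8) {
  PREC <- as_row(prec); TI <- as_row(Ti)
  n <- nrow(TI)
  i <- seq_len(n)
  Io <- ombro_ratio(PREC, TI, 1:12)

  iosi <- sapply(summer, function(mm) {
    ifelse(TI[, mm] > 0, PREC[, mm] / TI[, mm], NA_real_)
  })
  iosi <- as_row(iosi)

  # warmest contiguous two-month period of the summer quarter
  t_pair1 <- TI[, summer[1]] + TI[, summer[2]]
  t_pair2 <- TI[, summer[2]] + TI[, summer[3]]
  use2 <- t_pair2 > t_pair1       # earliest pair wins ties
  ios2 <- numeric(n)
  for (k in i) {
    mo <- if (use2[k]) summer[2:3] else summer[1:2]
    ios2[k] <- ombro_ratio(PREC[k, , drop = FALSE], TI[k, , drop = FALSE], mo)
  }

  iosc3 <- ombro_ratio(PREC, TI, summer)
  pre <- ((summer[1] - 2L) %% 12L) + 1L
  iosc4 <- ombro_ratio(PREC, TI, c(pre, summer))

  # driest contiguous quarter, then its two driest months (not necessarily
  # contiguous)
  w3p <- wrap_window_sums(PREC, 3L)
  s3 <- max.col(-w3p, ties.method = "first")
  iod2 <- numeric(n)
  for (k in i) {
    mo <- wrap_window_months(s3[k], 3L)
    dry2 <- mo[order(PREC[k, mo])[1:2]]
    iod2[k] <- ombro_ratio(PREC[k, , drop = FALSE], TI[k, , drop = FALSE], dry2)
  }
  out <- list(Io = Io, Iosi = iosi, Ios2 = ios2, Iosc3 = iosc3,
              Iosc4 = iosc4, Iod2 = iod2)
  if (length(prec) == 12 && !is.matrix(prec)) {
    out$Iosi <- drop(out$Iosi)
    out <- lapply(out, unname)
  }
  out
}

#' Continentality compensation term C(Ic)
#'
#' Stepwise compensation added to the thermicity index: zero inside the
#' neutral Ic band, negative below it (hyperoceanic territories), and
#' accumulating piecewise-linearly with the ruleset's step factors above it.
#' Beyond the last tabulated breakpoint the last factor keeps applying, so the
#' term is monotone non-decreasing over the whole continental range.
#'
#' @param Ic continentality index, degrees C (vectorised).
#' @param ruleset a `wbcs_ruleset`.
#' @return numeric vector of compensation values.
#' @export
continentality_compensation <- function(Ic, ruleset = default_ruleset()) {
  if (any(Ic < 0, na.rm = TRUE)) {
    abort_wbcs("Ic must be non-negative", "wbcs_config_error")
  }
  comp <- ruleset$compensation
  lo <- comp$neutral_ic_min
  hi <- comp$neutral_ic_max
  C <- numeric(length(Ic))
  below <- !is.na(Ic) & Ic < lo
  C[below] <- -comp$oceanic_factor * (lo - Ic[below])
  for (step in comp$continental_steps) {
    smin <- step$ic_min; smax <- band_maxs(list(step), "ic_max")
    f <- step$factor
    above <- !is.na(Ic) & Ic > smin
    C[above] <- C[above] + f * (pmin(Ic[above], smax) - smin)
  }
  # the last factor keeps applying above the final breakpoint
  last <- comp$continental_steps[[length(comp$continental_steps)]]
  last_max <- band_maxs(list(last), "ic_max")
  beyond <- !is.na(Ic) & Ic > last_max
  C[beyond] <- C[beyond] + last$factor * (Ic[beyond] - last_max)
  C[is.na(Ic)] <- NA_real_
  C
}

#' Compensated thermicity index
#'
#' `Itc = It + C(Ic)`, with the stepwise compensation term of
#' [continentality_compensation()].
#'
#' @param It thermicity index `(T + m + M) * 10`.
#' @param Ic continentality index.
#' @param ruleset a `wbcs_ruleset`.
#' @return numeric vector of compensated thermicity values.
#' @export
compensated_thermicity <- function(It, Ic, ruleset = default_ruleset()) {
  It + continentality_compensation(Ic, ruleset)
}

#' Thermal values reduced to the reference elevation
#'
#' Recomputes `T`, `M`, `Itc` and `Tp` as if the cell stood at the ruleset's
#' reference elevation (200 m): every monthly temperature is shifted by
#' `coeff * (elevation - reference) / 100` degrees C before the quantities are
#' recomputed. A cell already at the reference elevation is returned
#' unchanged.
#'
#' @param Ti monthly mean temperatures (length 12 or n x 12).
#' @param tmin,tmax monthly extremes (same shape).
#' @param elevation_m elevation(s) in metres.
#' @param Ic continentality index (unchanged by a uniform shift; needed for
#'   the compensation term).
#' @param ruleset a `wbcs_ruleset`.
#' @return named list with `T200`, `M200`, `m200`, `It200`, `Itc200`, `Tp200`
#'   and the applied `shift`.
#' @export
#' @examples
#' reduce_to_200m(rep(5, 12), rep(0, 12), rep(10, 12), elevation_m = 200,
#'                Ic = 0)$Tp200
reduce_to_200m <- function(Ti, tmin, tmax, elevation_m, Ic,
                           ruleset = default_ruleset()) {
  red <- ruleset$reduction
  if (is.null(red$temperature_coeff_per_100m) ||
      is.null(red$reference_elevation_m)) {
    abort_wbcs("ruleset: missing reduction coefficients", "wbcs_config_error")
  }
  TI <- as_row(Ti); TMIN <- as_row(tmin); TMAX <- as_row(tmax)
  shift <- red$temperature_coeff_per_100m *
    (elevation_m - red$reference_elevation_m) / 100
  TI200 <- TI + shift
  TMAX200 <- TMAX + shift
  TMIN200 <- TMIN + shift
  cold <- max.col(-TI200, ties.method = "first")
  i <- seq_len(nrow(TI))
  T200 <- rowMeans(TI200)
  M200 <- TMAX200[cbind(i, cold)]
  m200 <- TMIN200[cbind(i, cold)]
  It200 <- (T200 + m200 + M200) * 10
  out <- list(
    T200 = T200, M200 = M200, m200 = m200, It200 = It200,
    Itc200 = compensated_thermicity(It200, Ic, ruleset),
    Tp200 = 10 * rowSums(pmax(TI200, 0)),
    shift = rep_len(shift, nrow(TI))
  )
  if (length(Ti) == 12 && !is.matrix(Ti)) out <- lapply(out, unname)
  out
}

#' Summer-aridity (mediterraneity) diagnosis
#'
#' A cell has an arid summer when `Ios2` is at or below the ruleset gate
#' (default 2.0) and the compensation cascade fails: compensation succeeds
#' when `Iosc3` exceeds its gate, or when `Iosc4` exceeds its gate in
#' territories with `Io` above the ruleset's Io floor. Cells with an undefined
#' `Ios2` (no positive summer temperature) are never flagged arid — they are
#' routed to the cold macrobioclimates upstream of this test.
#'
#' @param Io,Ios2,Iosc3,Iosc4 ombrothermic indices (vectorised).
#' @param ruleset a `wbcs_ruleset`.
#' @return logical vector: `TRUE` for an uncompensated arid summer.
#' @export
#' @examples
#' summer_aridity(Io = 1, Ios2 = 3.5, Iosc3 = 3, Iosc4 = 3)
summer_aridity <- function(Io, Ios2, Iosc3, Iosc4, ruleset = default_ruleset()) {
  sa <- ruleset$summer_aridity
  arid <- !is.na(Ios2) & Ios2 <= sa$ios2_max
  comp3 <- !is.na(Iosc3) & Iosc3 > sa$iosc3_gate
  comp4 <- !is.na(Iosc4) & !is.na(Io) & Iosc4 > sa$iosc4_gate &
    Io > sa$iosc4_io_min
  arid & !(comp3 | comp4)
}

#' All WBCS indices for every cell of a grid
#'
#' Computes the full set of climatic parameters and bioclimatic indices — the
#' thermal and precipitation parameters, the ombrothermic cascade, the
#' compensated thermicity, the summer-aridity flag and the 200 m-reduced
#' values — for each cell, vectorised over the grid.
#'
#' @param grid a `climate_grid`.
#' @param ruleset a `wbcs_ruleset`.
#' @return data frame with one row per cell and one column per index symbol
#'   (`T`, `Tmax`, `Tmin`, `M`, `m`, `Tp`, `Tps`, `P`, `Pp`, `Ps`, `Pw`,
#'   `Pps`, `Ppw`, `Pss`, `Psw`, `Pcm1`, `Pcm2`, `Pcm3`, `Ic`, `It`, `C`,
#'   `Itc`, `Io`, `Iosi_1..3`, `Ios2`, `Iosc3`, `Iosc4`, `Iod2`,
#'   `summer_arid`, `T200`, `M200`, `Itc200`, `Tp200`), plus `cell_id`,
#'   `hemisphere` and the summer-quarter months. Suitable for flat CSV export.
#' @export
bioclim_indices <- function(grid, ruleset = default_ruleset()) {
  stopifnot(inherits(grid, "climate_grid"))
  cells <- grid$cells
  TMIN <- as.matrix(cells[, month_cols("tmin")])
  TMAX <- as.matrix(cells[, month_cols("tmax")])
  PREC <- as.matrix(cells[, month_cols("prec")])
  TI <- monthly_means(TMIN, TMAX)
  hemi <- ifelse(cells$lat >= 0, "N", "S")

  blocks <- lapply(unique(hemi), function(h) {
    rows <- which(hemi == h)
    summer <- if (h == "N") 6:8 else c(12L, 1L, 2L)
    ti <- TI[rows, , drop = FALSE]
    th <- thermal_parameters(ti, TMIN[rows, , drop = FALSE],
                             TMAX[rows, , drop = FALSE], summer = summer)
    pr <- precipitation_parameters(PREC[rows, , drop = FALSE], ti,
                                   summer = summer)
    om <- ombrothermic_indices(PREC[rows, , drop = FALSE], ti, summer = summer)
    C <- continentality_compensation(th$Ic, ruleset)
    red <- reduce_to_200m(ti, TMIN[rows, , drop = FALSE],
                          TMAX[rows, , drop = FALSE],
                          cells$elev_m[rows], th$Ic, ruleset)
    data.frame(
      row = rows,
      cell_id = cells$cell_id[rows],
      hemisphere = h,
      summer_1 = summer[1], summer_2 = summer[2], summer_3 = summer[3],
      T = th$T, Tmax = th$Tmax, Tmin = th$Tmin, M = th$M, m = th$m,
      Tp = th$Tp, Tps = th$Tps, Ic = th$Ic, It = th$It,
      C = C, Itc = th$It + C,
      P = pr$P, Pp = pr$Pp, Ps = pr$Ps, Pw = pr$Pw, Pps = pr$Pps,
      Ppw = pr$Ppw, Pss = pr$Pss, Psw = pr$Psw,
      Pcm1 = pr$Pcm1, Pcm2 = pr$Pcm2, Pcm3 = pr$Pcm3,
      Io = om$Io,
      Iosi_1 = om$Iosi[, 1], Iosi_2 = om$Iosi[, 2], Iosi_3 = om$Iosi[, 3],
      Ios2 = om$Ios2, Iosc3 = om$Iosc3, Iosc4 = om$Iosc4, Iod2 = om$Iod2,
      summer_arid = summer_aridity(om$Io, om$Ios2, om$Iosc3, om$Iosc4,
                                   ruleset),
      T200 = red$T200, M200 = red$M200, m200 = red$m200,
      Itc200 = red$Itc200, Tp200 = red$Tp200,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, blocks)
  out <- out[order(out$row), , drop = FALSE]
  out$row <- NULL
  rownames(out) <- NULL
  out
}
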