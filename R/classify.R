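# Hierarchical assignment of the seven WBCS bioclimatic units. All thresholds
# come from the ruleset; the functions here only implement the dispatch logic
# the classification prescribes:
#   continentality (Ic) -> macrobioclimate (reduced thermal values + summer
#   aridity) -> bioclimate (Ic, Io) -> variant (Ps/Pw, Io, monthly summer
#   ombrothermy) -> thermotype (Ic/Itc/Tp dispatch) -> ombrotype (Io) ->
#   isobioclimate (bioclimate + thermotype + ombrotype).

#' Continentality type, subtype and level
#'
#' Looks `Ic` up in the ruleset's continentality table (lower-closed,
#' upper-open intervals; the final row is upper-closed and also receives any
#' `Ic` above its bound).
#'
#' @param Ic continentality index, degrees C (vectorised, must be >= 0).
#' @param ruleset a `wbcs_ruleset`.
#' @return data frame with columns `type`, `subtype`, `level`, `code` and
#'   `Ic`.
#' @export
#' @examples
#' classify_continentality(c(30, 37, 10.5))$subtype
classify_continentality <- function(Ic, ruleset = default_ruleset()) {
  if (any(is.na(Ic)) || any(Ic < 0)) {
    abort_wbcs("Ic must be non-negative and non-missing", "wbcs_input_error")
  }
  rows <- ruleset$continentality$rows
  idx <- interval_match(Ic, band_mins(rows, "ic_min"), band_maxs(rows, "ic_max"))
  data.frame(
    type = vapply(rows, function(r) r$type, "")[idx],
    subtype = vapply(rows, function(r) r$subtype, "")[idx],
    level = vapply(rows, function(r) r$level, "")[idx],
    code = vapply(rows, function(r) r$code, "")[idx],
    Ic = Ic,
    stringsAsFactors = FALSE
  )
}

#' Macrobioclimate of each cell
#'
#' Applies the macrobioclimate predicates, in order, to the 200 m-reduced
#' thermal values and the summer-aridity flag: polar (`Tp200` below the polar
#' bound), boreal (`Tp200` below the boreal bound), tropical (warm-limit rule
#' on `T200` and `m`, carried for completeness), mediterranean (uncompensated
#' summer aridity), temperate (otherwise). The predicates are exhaustive for
#' any well-formed ruleset.
#'
#' @param indices index table from [bioclim_indices()] (needs `Tp200`, `T200`,
#'   `m`, `summer_arid`).
#' @param ruleset a `wbcs_ruleset`.
#' @return character vector of macrobioclimate codes.
#' @export
classify_macrobioclimate <- function(indices, ruleset = default_ruleset()) {
  mb <- ruleset$macrobioclimate
  out <- rep(NA_character_, nrow(indices))
  out[indices$Tp200 < mb$polar_tp200_max] <- "POLAR"
  todo <- is.na(out)
  out[todo & indices$Tp200 < mb$boreal_tp200_max] <- "BOREAL"
  todo <- is.na(out)
  out[todo & indices$T200 >= mb$tropical_t200_min &
        indices$m >= mb$tropical_m_min] <- "TROPICAL"
  todo <- is.na(out)
  out[todo & indices$summer_arid] <- "MEDITERRANEAN"
  out[is.na(out)] <- "TEMPERATE"
  if (anyNA(out)) {
    abort_wbcs(sprintf("macrobioclimate predicates not exhaustive for cell(s) %s",
                       paste(indices$cell_id[is.na(out)], collapse = ", ")),
               "wbcs_classification_error")
  }
  out
}

#' Bioclimate of each cell
#'
#' Second-level classification from `Ic` and `Io`: the mediterranean humidity
#' classes (pluviseasonal / xeric / desertic / hyperdesertic) split on the
#' ruleset's Io bands with oceanic and continental forms separated at the Ic
#' boundary; temperate, boreal and polar territories are xeric below the
#' ruleset's dry-Io bound and otherwise split by Ic into hyperoceanic, oceanic
#' and continental forms. Polar cells whose `Tp200` stays below the pergelid
#' bound carry no defined `Io` and are routed to the explicit pergelid branch;
#' in the other cold macrobioclimates a cell with undefined `Io` (no month
#' above 0 degC at true elevation) skips the xeric split and takes its
#' Ic-based form directly.
#'
#' @param macro macrobioclimate codes from [classify_macrobioclimate()].
#' @param Ic,Io index vectors (same length).
#' @param Tp200 reduced positive temperature (needed for the pergelid branch;
#'   defaults to `Inf`, which disables it).
#' @param ruleset a `wbcs_ruleset`.
#' @return character vector of 4-letter bioclimate codes.
#' @export
classify_bioclimate <- function(macro, Ic, Io, Tp200 = Inf,
                                ruleset = default_ruleset()) {
  bc <- ruleset$bioclimate
  n <- length(macro)
  Tp200 <- rep_len(Tp200, n)
  out <- rep(NA_character_, n)

  med <- macro == "MEDITERRANEAN"
  if (any(med)) {
    cls <- bc$mediterranean$io_classes
    idx <- interval_match(Io[med], rev(band_mins(cls, "io_min")),
                          rev(band_maxs(cls, "io_max")))
    idx <- length(cls) + 1L - idx   # classes are listed wet to dry
    oce <- vapply(cls, function(r) r$oceanic, "")[idx]
    con <- vapply(cls, function(r) r$continental, "")[idx]
    out[med] <- ifelse(Ic[med] < bc$oceanic_ic_max, oce, con)
  }
  for (mk in c("TEMPERATE", "BOREAL", "POLAR")) {
    sel <- macro == mk
    if (!any(sel)) next
    sub <- bc[[tolower(mk)]]
    lab <- rep(NA_character_, sum(sel))
    if (mk == "POLAR") {
      lab[Tp200[sel] < sub$pergelid_tp200_max] <- sub$pergelid
    }
    io <- Io[sel]; ic <- Ic[sel]
    open <- is.na(lab)
    # Undefined Io (no month above 0 degC at true elevation): the xeric split
    # cannot be assessed, so the cell takes the Ic-based form directly; its
    # thermotype/ombrotype land in the gelid/supersnowy branch downstream.
    lab[open & !is.na(io) & io < sub$xeric_io_max] <- sub$xeric
    open <- is.na(lab)
    lab[open & ic < sub$hyperoceanic_ic_max] <- sub$hyperoceanic
    open <- is.na(lab)
    lab[open & ic < bc$oceanic_ic_max] <- sub$oceanic
    lab[is.na(lab)] <- sub$continental
    out[sel] <- lab
  }
  trop <- macro == "TROPICAL"
  if (any(trop)) {
    cls <- bc$tropical$io_classes
    idx <- interval_match(Io[trop], rev(band_mins(cls, "io_min")),
                          rev(band_maxs(cls, "io_max")))
    idx <- length(cls) + 1L - idx
    out[trop] <- vapply(cls, function(r) r$code, "")[idx]
  }
  if (anyNA(out)) {
    abort_wbcs("bioclimate rules not exhaustive (undefined Io?)",
               "wbcs_classification_error")
  }
  out
}

#' Bioclimatic variant of each cell
#'
#' Steppic (`Stp`) when three conditions hold together: `Ps >= Pw`, `Io`
#' within the steppe band (0.2 < Io <= 6.0 by default) and every summer month
#' with `Psi < 3 * Ti`. Otherwise submediterranean (`Sbm`, temperate / boreal
#' / polar territories only) when at least one summer month has
#' `Pi < 2.8 * Ti`. Everything else is the normal variant (`Nor`).
#'
#' @param macro macrobioclimate codes.
#' @param indices index table from [bioclim_indices()] (needs `Ps`, `Pw`,
#'   `Io` and the summer months).
#' @param grid the `climate_grid` the indices came from (for the monthly
#'   series).
#' @param ruleset a `wbcs_ruleset`.
#' @return character vector of variant codes.
#' @export
classify_variant <- function(macro, indices, grid,
                             ruleset = default_ruleset()) {
  va <- ruleset$variants
  cells <- grid$cells
  PREC <- as.matrix(cells[, month_cols("prec")])
  TI <- monthly_means(as.matrix(cells[, month_cols("tmin")]),
                      as.matrix(cells[, month_cols("tmax")]))
  n <- nrow(indices)
  smonths <- cbind(indices$summer_1, indices$summer_2, indices$summer_3)
  i <- seq_len(n)
  ps_mat <- cbind(PREC[cbind(i, smonths[, 1])], PREC[cbind(i, smonths[, 2])],
                  PREC[cbind(i, smonths[, 3])])
  ts_mat <- cbind(TI[cbind(i, smonths[, 1])], TI[cbind(i, smonths[, 2])],
                  TI[cbind(i, smonths[, 3])])

  stp <- macro %in% va$steppic$macros &
    indices$Ps >= indices$Pw &
    !is.na(indices$Io) &
    indices$Io > va$steppic$io_min & indices$Io <= va$steppic$io_max &
    rowSums(ps_mat < va$steppic$monthly_factor * ts_mat) == 3L

  sbm <- macro %in% va$submediterranean$macros &
    rowSums(ps_mat < va$submediterranean$monthly_factor * ts_mat) >= 1L

  out <- rep(va$normal$code, n)
  out[sbm] <- va$submediterranean$code
  out[stp] <- va$steppic$code
  out
}

# Band-table lookup: tables are listed warm/high to cold/low; values above the
# warmest band take the warmest code, below the coldest band the coldest.
band_table_lookup <- function(x, tbl) {
  mins <- rev(band_mins(tbl)); maxs <- rev(band_maxs(tbl))
  codes <- rev(band_codes(tbl))
  idx <- interval_match(x, mins, maxs)
  idx[!is.na(x) & x < mins[1]] <- 1L            # below the table: coldest class
  codes[idx]
}

#' Thermotype of each cell
#'
#' Mediterranean and temperate territories: when `Ic` is at or above the
#' continental dispatch bound, or `Itc` is below the ruleset's Itc floor, the
#' thermotype is read from the macrobioclimate's Tp intervals; otherwise from
#' its Itc intervals. Boreal, polar and tropical thermotypes are read directly
#' from Tp. Unreduced (true-elevation) `Itc` and `Tp` are used. Values beyond
#' a table's extremes take the nearest (warmest / coldest) class.
#'
#' @param macro macrobioclimate codes.
#' @param Ic,Itc,Tp index vectors.
#' @param ruleset a `wbcs_ruleset`.
#' @return character vector of thermotype codes.
#' @export
classify_thermotype <- function(macro, Ic, Itc, Tp,
                                ruleset = default_ruleset()) {
  tt <- ruleset$thermotype
  out <- rep(NA_character_, length(macro))
  for (mk in unique(macro)) {
    sel <- macro == mk
    tab <- tt[[tolower(mk)]]
    if (is.null(tab)) {
      abort_wbcs(sprintf("no thermotype table for macrobioclimate %s", mk),
                 "wbcs_config_error")
    }
    if (mk %in% c("MEDITERRANEAN", "TEMPERATE")) {
      by_tp <- Ic[sel] >= tt$dispatch_ic_min | Itc[sel] < tt$dispatch_itc_min
      lab <- rep(NA_character_, sum(sel))
      lab[by_tp] <- band_table_lookup(Tp[sel][by_tp], tab$tp)
      lab[!by_tp] <- band_table_lookup(Itc[sel][!by_tp], tab$itc)
      out[sel] <- lab
    } else {
      out[sel] <- band_table_lookup(Tp[sel], tab$tp)
    }
  }
  out
}

#' Ombrotype of each cell
#'
#' The ombrotype thresholds are the same for all macrobioclimates: the unique
#' Io interval containing the value. Cells whose positive temperature stays
#' below the ruleset's snowy bound (gelid belts; `Io` undefined or
#' meaningless) take the supersnowy code.
#'
#' @param Io annual ombrothermic index.
#' @param Tp positive annual temperature, tenths of degC (default `Inf`
#'   disables the snowy branch).
#' @param ruleset a `wbcs_ruleset`.
#' @return character vector of ombrotype codes.
#' @export
#' @examples
#' classify_ombrotype(c(0.7, 0))
classify_ombrotype <- function(Io, Tp = Inf, ruleset = default_ruleset()) {
  ob <- ruleset$ombrotype
  n <- length(Io)
  Tp <- rep_len(Tp, n)
  out <- rep(NA_character_, n)
  snowy <- Tp < ob$snowy_tp_max
  out[snowy] <- ob$snowy_code
  open <- !snowy
  if (any(open & is.na(Io))) {
    abort_wbcs("undefined Io reached the ombrotype lookup", "wbcs_classification_error")
  }
  cls <- ob$classes
  idx <- interval_match(Io[open], band_mins(cls, "io_min"),
                        band_maxs(cls, "io_max"))
  out[open] <- band_codes(cls)[idx]
  out
}

#' Classify every cell of a climate grid
#'
#' Runs the whole chain — indices, 200 m reduction, the six unit classifiers
#' and the isobioclimate assembly — and returns one label row per cell. The
#' classification is deterministic: the same grid and ruleset always give the
#' same labels.
#'
#' @param grid a `climate_grid`.
#' @param ruleset a `wbcs_ruleset`.
#' @param indices optionally, a precomputed table from [bioclim_indices()].
#' @return data frame with columns `cell_id`, `continentality_type`,
#'   `continentality_subtype`, `continentality_level`, `continentality`,
#'   `macrobioclimate`, `bioclimate`, `variant`, `thermotype`, `ombrotype`,
#'   `isobioclimate`; the grid's period label is attached as attribute
#'   `period_label`.
#' @export
#' @examples
#' g <- generate_grid(synthetic_grid_spec(n_cells = 20))[[1]]
#' head(classify_grid(g))
classify_grid <- function(grid, ruleset = default_ruleset(), indices = NULL) {
  stopifnot(inherits(grid, "climate_grid"))
  if (is.null(indices)) indices <- bioclim_indices(grid, ruleset)
  cont <- classify_continentality(indices$Ic, ruleset)
  macro <- classify_macrobioclimate(indices, ruleset)
  bio <- classify_bioclimate(macro, indices$Ic, indices$Io, indices$Tp200,
                             ruleset)
  variant <- classify_variant(macro, indices, grid, ruleset)
  thermo <- classify_thermotype(macro, indices$Ic, indices$Itc, indices$Tp,
                                ruleset)
  ombro <- classify_ombrotype(indices$Io, indices$Tp, ruleset)
  out <- data.frame(
    cell_id = indices$cell_id,
    continentality_type = cont$type,
    continentality_subtype = cont$subtype,
    continentality_level = cont$level,
    continentality = paste(cont$type, cont$subtype, cont$level, sep = ", "),
    macrobioclimate = macro,
    bioclimate = bio,
    variant = variant,
    thermotype = thermo,
    ombrotype = ombro,
    isobioclimate = paste(bio, thermo, ombro),
    stringsAsFactors = FALSE
  )
  attr(out, "period_label") <- grid$period_label
  out
}

#' Classify a single cell record
#'
#' Convenience wrapper around [classify_grid()] for one cell, given as a named
#' list or one-row data frame in the canonical schema.
#'
#' @param cell named list / one-row data frame with `cell_id`, `lat`, `lon`,
#'   `elev_m` and the 12-month `tmin`, `tmax`, `prec` fields (either as
#'   canonical columns or as length-12 vectors named `tmin`, `tmax`, `prec`).
#' @param ruleset a `wbcs_ruleset`.
#' @return one-row classification data frame (see [classify_grid()]).
#' @export
classify_cell <- function(cell, ruleset = default_ruleset()) {
  if (!is.data.frame(cell)) {
    row <- data.frame(cell_id = as.character(cell$cell_id %||% "cell"),
                      lat = cell$lat, lon = cell$lon %||% 0,
                      elev_m = cell$elev_m %||% 0)
    row[, month_cols("tmin")] <- rbind(cell$tmin)
    row[, month_cols("tmax")] <- rbind(cell$tmax)
    row[, month_cols("prec")] <- rbind(cell$prec)
    cell <- row
  }
  classify_grid(climate_grid(cell, period_label = "single-cell"),
                ruleset = ruleset)
}

#' Catalogue of isobioclimates across classified periods
#'
#' Collects the distinct isobioclimate codes found in one or more classified
#' periods, orders them by the ruleset's canonical (bioclimate, thermotype,
#' ombrotype) ranking and assigns stable key numbers from 1. Supplying extra
#' periods that introduce no new codes leaves the catalogue unchanged.
#'
#' @param labels a classification data frame or a list of them (one per
#'   period).
#' @param ruleset a `wbcs_ruleset`.
#' @return data frame with columns `key`, `isobioclimate`, `bioclimate`,
#'   `thermotype`, `ombrotype`, `name`.
#' @export
build_isobioclimate_catalog <- function(labels, ruleset = default_ruleset()) {
  if (is.data.frame(labels)) labels <- list(labels)
  iso <- unique(unlist(lapply(labels, function(l) l$isobioclimate)))
  parts <- do.call(rbind, strsplit(iso, " ", fixed = TRUE))
  ord <- order(code_rank(parts[, 1], ruleset$order$bioclimate),
               code_rank(parts[, 2], ruleset$order$thermotype),
               code_rank(parts[, 3], ruleset$order$ombrotype))
  iso <- iso[ord]; parts <- parts[ord, , drop = FALSE]
  data.frame(
    key = seq_along(iso),
    isobioclimate = iso,
    bioclimate = parts[, 1],
    thermotype = parts[, 2],
    ombrotype = parts[, 3],
    name = isobioclimate_name(iso, ruleset),
    stringsAsFactors = FALSE
  )
}
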