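# Multi-period comparison of classified grids: area tables per bioclimatic
# unit, per-cell change and stability masks, aggregate trend groupings and
# bioclimatic-diversity loss.

unit_columns <- c("continentality", "macrobioclimate", "bioclimate",
                  "variant", "thermotype", "ombrotype", "isobioclimate")

check_periods <- function(periods, unit) {
  if (is.data.frame(periods)) periods <- list(periods)
  if (length(periods) < 1L) {
    abort_wbcs("at least one classified period is required", "wbcs_input_error")
  }
  if (!unit %in% names(periods[[1]])) {
    abort_wbcs(sprintf("unknown bioclimatic unit: %s (expected one of %s)",
                       unit, paste(unit_columns, collapse = ", ")),
               "wbcs_input_error")
  }
  ids <- periods[[1]]$cell_id
  for (k in seq_along(periods)) {
    if (!setequal(periods[[k]]$cell_id, ids) ||
        nrow(periods[[k]]) != length(ids)) {
      abort_wbcs("periods are not classified on the same cell set",
                 "wbcs_alignment_error")
    }
    periods[[k]] <- periods[[k]][match(ids, periods[[k]]$cell_id), ,
                                 drop = FALSE]
  }
  if (is.null(names(periods)) || any(!nzchar(names(periods)))) {
    names(periods) <- vapply(periods, function(p) {
      attr(p, "period_label") %||% ""
    }, "")
    blank <- !nzchar(names(periods))
    names(periods)[blank] <- paste0("period_", which(blank))
  }
  periods
}

# Canonical display order for the classes of one unit.
unit_class_order <- function(classes, unit, ruleset) {
  key <- switch(unit,
    macrobioclimate = ruleset$order$macrobioclimate,
    bioclimate = ruleset$order$bioclimate,
    thermotype = ruleset$order$thermotype,
    ombrotype = ruleset$order$ombrotype,
    variant = c(ruleset$variants$steppic$code,
                ruleset$variants$submediterranean$code,
                ruleset$variants$normal$code),
    NULL)
  if (unit == "isobioclimate") {
    parts <- do.call(rbind, strsplit(classes, " ", fixed = TRUE))
    return(classes[order(code_rank(parts[, 1], ruleset$order$bioclimate),
                         code_rank(parts[, 2], ruleset$order$thermotype),
                         code_rank(parts[, 3], ruleset$order$ombrotype))])
  }
  if (is.null(key)) return(sort(classes))
  classes[order(match(classes, key), classes)]
}

#' Per-class area table across classified periods
#'
#' Tabulates, for one bioclimatic unit, the number of cells and the percent of
#' territory in each class for every period, plus the gain/loss column: the
#' final-period percent minus the first-period percent.
#'
#' @param periods list of classification data frames from [classify_grid()],
#'   all on the same cell set (a single data frame is accepted).
#' @param unit one of `r paste(unit_columns, collapse = ", ")`.
#' @param ruleset a `wbcs_ruleset` (for the canonical class ordering).
#' @return data frame with one row per class: `class`, then `n_<period>` and
#'   `pct_<period>` per period, then `delta_pct`. Attributes `unit` and
#'   `n_cells` are attached. Percentages are unrounded; round at print time
#'   with [round_half_up()].
#' @export
area_table <- function(periods, unit, ruleset = default_ruleset()) {
  periods <- check_periods(periods, unit)
  n <- nrow(periods[[1]])
  classes <- unique(unlist(lapply(periods, function(p) p[[unit]])))
  classes <- unit_class_order(classes, unit, ruleset)
  out <- data.frame(class = classes, stringsAsFactors = FALSE)
  for (k in seq_along(periods)) {
    counts <- table(factor(periods[[k]][[unit]], levels = classes))
    out[[paste0("n_", names(periods)[k])]] <- as.integer(counts)
    out[[paste0("pct_", names(periods)[k])]] <- as.numeric(counts) / n * 100
  }
  first <- paste0("pct_", names(periods)[1])
  last <- paste0("pct_", names(periods)[length(periods)])
  out$delta_pct <- out[[last]] - out[[first]]
  attr(out, "unit") <- unit
  attr(out, "n_cells") <- n
  attr(out, "periods") <- names(periods)
  out
}

#' Fraction of territory with a stable classification
#'
#' Percent of cells whose class for the given unit is identical in every
#' supplied period; the complement is the change percent.
#'
#' @inheritParams area_table
#' @return one-row data frame: `unit`, `n_cells`, `n_stable`, `stable_pct`,
#'   `change_pct`.
#' @export
stability_fraction <- function(periods, unit, ruleset = default_ruleset()) {
  periods <- check_periods(periods, unit)
  if (length(periods) < 2L) {
    abort_wbcs("stability needs at least two periods", "wbcs_input_error")
  }
  ref <- periods[[1]][[unit]]
  stable <- rep(TRUE, length(ref))
  for (k in seq_along(periods)[-1]) {
    stable <- stable & periods[[k]][[unit]] == ref
  }
  n <- length(ref)
  data.frame(unit = unit, n_cells = n, n_stable = sum(stable),
             stable_pct = sum(stable) / n * 100,
             change_pct = sum(!stable) / n * 100,
             stringsAsFactors = FALSE)
}

#' Per-cell change mask between two classified periods
#'
#' @param period_a,period_b classification data frames on the same cell set.
#' @param unit the bioclimatic unit to compare.
#' @return data frame with `cell_id`, `before`, `after`, `changed`; exportable
#'   as a change map through [write_classified_grid()].
#' @export
change_mask <- function(period_a, period_b, unit) {
  periods <- check_periods(list(period_a, period_b), unit)
  data.frame(
    cell_id = periods[[1]]$cell_id,
    before = periods[[1]][[unit]],
    after = periods[[2]][[unit]],
    changed = periods[[1]][[unit]] != periods[[2]][[unit]],
    stringsAsFactors = FALSE
  )
}

#' Loss of bioclimatic diversity across periods
#'
#' For each unit: the number of distinct classes present in the early periods
#' (union of all but the final period), the number present in the final
#' period, the number that disappeared (present early, absent at the end) and
#' the percent loss relative to the early count.
#'
#' @param periods list of >= 2 classification data frames.
#' @param units character vector of units to summarise.
#' @return data frame with one row per unit: `unit`, `n_initial`, `n_final`,
#'   `n_disappeared`, `pct_loss`.
#' @export
diversity_summary <- function(periods, units = unit_columns) {
  stopifnot(length(periods) >= 2L)
  out <- lapply(units, function(u) {
    p <- check_periods(periods, u)
    early <- unique(unlist(lapply(p[-length(p)], function(x) x[[u]])))
    final <- unique(p[[length(p)]][[u]])
    gone <- setdiff(early, final)
    data.frame(unit = u, n_initial = length(early), n_final = length(final),
               n_disappeared = length(gone),
               pct_loss = length(gone) / length(early) * 100,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Aggregate gains and losses over class groupings
#'
#' Sums the `delta_pct` column of an area table over declared groups of class
#' codes (for example warm vs cold thermotypes, or the arid vs non-arid
#' ombrotypes). A grouping that covers every class sums to zero up to
#' rounding, since per-period percentages each sum to 100.
#'
#' @param tbl an area table from [area_table()].
#' @param groups named list of character vectors of class codes; codes absent
#'   from the table contribute zero.
#' @return data frame with `group`, `classes` (those actually present) and
#'   `delta_pct`.
#' @export
#' @examples
#' # See thermotype_belts() for ready-made warm/cold thermotype groups.
trend_summary <- function(tbl, groups) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  out <- lapply(names(groups), function(g) {
    sel <- tbl$class %in% groups[[g]]
    data.frame(group = g,
               classes = paste(tbl$class[sel], collapse = "+"),
               delta_pct = sum(tbl$delta_pct[sel]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Ready-made thermotype belt groupings
#'
#' Groups thermotype codes into the warm belts (infra-, thermo-, meso-) and
#' the cold belts (supra-, oro-, cryoro-, boreal, polar and gelid), the
#' grouping used to summarise a warming trend.
#'
#' @param ruleset a `wbcs_ruleset`.
#' @return named list with elements `warm` and `cold`.
#' @export
thermotype_belts <- function(ruleset = default_ruleset()) {
  all_t <- ruleset$order$thermotype
  warm <- all_t[substr(all_t, 1, 1) %in% c("I", "T", "M") & all_t != "Gel"]
  list(warm = warm, cold = setdiff(all_t, warm))
}

#' Ready-made ombrotype aridity groupings
#'
#' Groups ombrotype codes into the arid group (ultrahyperarid to semiarid) and
#' the non-arid group (dry and wetter, plus the supersnowy code), the grouping
#' used to summarise an aridification trend.
#'
#' @param ruleset a `wbcs_ruleset`.
#' @return named list with elements `arid` and `humid`.
#' @export
ombrotype_groups <- function(ruleset = default_ruleset()) {
  all_o <- ruleset$order$ombrotype
  arid <- c("Uha", "Har", "Ari", "Sar")
  list(arid = intersect(all_o, arid), humid = setdiff(all_o, arid))
}
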