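# The classification ruleset: a versioned, human-readable YAML file holding
# every threshold the classifier applies. The package ships one transcription
# of the WBCS synopsis (inst/extdata/wbcs_ruleset_1.0.yaml); users can load a
# modified copy to audit or adjust any band without touching code.

the <- new.env(parent = emptyenv())

#' Load a WBCS classification ruleset
#'
#' Reads a ruleset YAML file, validates its structure (each threshold table
#' must totally order and tile its domain without gaps under the lower-closed
#' / upper-open interval convention) and returns a `wbcs_ruleset` object.
#'
#' @param path path to a ruleset YAML file.
#' @return an object of class `wbcs_ruleset` (a validated nested list).
#' @seealso [default_ruleset()]
#' @export
load_ruleset <- function(path) {
  if (!file.exists(path)) {
    abort_wbcs(sprintf("ruleset file not found: %s", path), "wbcs_config_error")
  }
  rs <- yaml::read_yaml(path)
  rs$.path <- path
  class(rs) <- "wbcs_ruleset"
  validate_ruleset(rs)
  rs
}

#' The packaged WBCS ruleset
#'
#' Returns the threshold ruleset shipped with the package (version
#' `wbcs-1.0`), loading and caching it on first use.
#'
#' @return a `wbcs_ruleset` object.
#' @export
#' @examples
#' rs <- default_ruleset()
#' rs$version
default_ruleset <- function() {
  if (is.null(the$default_ruleset)) {
    path <- system.file("extdata", "wbcs_ruleset_1.0.yaml", package = "wbcs")
    the$default_ruleset <- load_ruleset(path)
  }
  the$default_ruleset
}

# A [min, max) table must tile its domain: contiguous, increasing, no gaps.
check_tiling <- function(mins, maxs, what) {
  if (any(maxs <= mins)) {
    abort_wbcs(sprintf("ruleset: empty interval in %s", what), "wbcs_config_error")
  }
  if (length(mins) > 1 && any(abs(mins[-1] - maxs[-length(maxs)]) > 1e-9)) {
    abort_wbcs(sprintf("ruleset: %s intervals do not tile their domain", what),
               "wbcs_config_error")
  }
  invisible(TRUE)
}

band_mins <- function(tbl, key = "min") vapply(tbl, function(r) as.numeric(r[[key]]), 0)
band_maxs <- function(tbl, key = "max") {
  vapply(tbl, function(r) {
    v <- r[[key]]
    if (is.character(v) && v %in% c(".inf", "inf", "Inf")) Inf else as.numeric(v)
  }, 0)
}
band_codes <- function(tbl) vapply(tbl, function(r) as.character(r$code), "")

#' Validate a ruleset's internal consistency
#'
#' Checks that every interval table tiles its domain, that dispatch constants
#' and compensation steps are present, and that the ranking and naming tables
#' cover all codes used by the threshold tables.
#'
#' @param rs a `wbcs_ruleset` object.
#' @return `rs`, invisibly; signals a `wbcs_config_error` otherwise.
#' @export
validate_ruleset <- function(rs) {
  need <- c("version", "continentality", "reduction", "compensation",
            "summer_aridity", "macrobioclimate", "bioclimate", "variants",
            "thermotype", "ombrotype", "order", "names")
  missing <- setdiff(need, names(rs))
  if (length(missing)) {
    abort_wbcs(sprintf("ruleset: missing sections: %s",
                       paste(missing, collapse = ", ")), "wbcs_config_error")
  }
  ct <- rs$continentality$rows
  check_tiling(band_mins(ct, "ic_min"), band_maxs(ct, "ic_max"), "continentality")

  cs <- rs$compensation$continental_steps
  check_tiling(band_mins(cs, "ic_min"), band_maxs(cs, "ic_max"),
               "compensation steps")
  if (abs(band_mins(cs, "ic_min")[1] - rs$compensation$neutral_ic_max) > 1e-9) {
    abort_wbcs("ruleset: compensation steps must start at the neutral band edge",
               "wbcs_config_error")
  }

  om <- rs$ombrotype$classes
  check_tiling(band_mins(om, "io_min"), band_maxs(om, "io_max"), "ombrotype")

  med <- rs$bioclimate$mediterranean$io_classes
  check_tiling(rev(band_mins(med, "io_min")), rev(band_maxs(med, "io_max")),
               "mediterranean bioclimate Io bands")

  for (macro in c("mediterranean", "temperate", "boreal", "polar", "tropical")) {
    tp <- rs$thermotype[[macro]]$tp
    check_tiling(rev(band_mins(tp)), rev(band_maxs(tp)),
                 sprintf("%s thermotype Tp bands", macro))
    itc <- rs$thermotype[[macro]]$itc
    if (!is.null(itc)) {
      check_tiling(rev(band_mins(itc)), rev(band_maxs(itc)),
                   sprintf("%s thermotype Itc bands", macro))
    }
  }

  used <- c(band_codes(rs$thermotype$mediterranean$tp),
            band_codes(rs$thermotype$temperate$tp),
            band_codes(rs$thermotype$boreal$tp),
            band_codes(rs$thermotype$polar$tp),
            band_codes(rs$thermotype$tropical$tp))
  if (!all(used %in% rs$order$thermotype)) {
    abort_wbcs("ruleset: thermotype codes missing from the ranking order",
               "wbcs_config_error")
  }
  if (!all(band_codes(rs$ombrotype$classes) %in% rs$order$ombrotype)) {
    abort_wbcs("ruleset: ombrotype codes missing from the ranking order",
               "wbcs_config_error")
  }
  invisible(rs)
}

#' @export
print.wbcs_ruleset <- function(x, ...) {
  cat("<wbcs_ruleset>", x$version, "\n")
  cat("  continentality rows:", length(x$continentality$rows), "\n")
  cat("  ombrotype classes:", length(x$ombrotype$classes), "\n")
  cat("  reduction:", x$reduction$temperature_coeff_per_100m,
      "degC / 100 m to", x$reduction$reference_elevation_m, "m\n")
  invisible(x)
}

# Rank helpers: position of a code in the ruleset's canonical ordering.
code_rank <- function(codes, order) match(codes, order)

#' Long (prose) name of a classification code
#'
#' Maps unit codes to the spelled-out names used in catalogues and legends,
#' e.g. `MEDC` to "mediterranean desertic continental".
#'
#' @param code character vector of codes.
#' @param unit one of `"macrobioclimate"`, `"bioclimate"`, `"variant"`,
#'   `"thermotype"`, `"ombrotype"`.
#' @param ruleset a `wbcs_ruleset`.
#' @return character vector of long names (NA for unknown codes).
#' @export
#' @examples
#' code_name("Sme", "thermotype")
code_name <- function(code, unit, ruleset = default_ruleset()) {
  tbl <- ruleset$names[[unit]]
  if (is.null(tbl)) abort_wbcs(sprintf("unknown unit: %s", unit), "wbcs_config_error")
  out <- unlist(tbl)[code]
  unname(out)
}

#' Long name of an isobioclimate code string
#'
#' An isobioclimate code is `"<bioclimate> <thermotype> <ombrotype>"`; its long
#' name joins the three component names, e.g. `"MEDC Sme Ari"` becomes
#' "mediterranean desertic continental, supramediterranean, arid".
#'
#' @param iso character vector of isobioclimate codes.
#' @param ruleset a `wbcs_ruleset`.
#' @return character vector of long names.
#' @export
isobioclimate_name <- function(iso, ruleset = default_ruleset()) {
  parts <- strsplit(iso, " ", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 3L) return(NA_character_)
    paste(c(code_name(p[1], "bioclimate", ruleset),
            code_name(p[2], "thermotype", ruleset),
            code_name(p[3], "ombrotype", ruleset)), collapse = ", ")
  }, "")
}
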