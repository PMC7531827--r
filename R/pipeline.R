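# End-to-end driver: classify one or more periods, tabulate every bioclimatic
# unit, compare periods and write the full report bundle.

#' Pipeline configuration
#'
#' @param inputs named list of inputs, one per period, in chronological order:
#'   each element is a `climate_grid` or a path to a canonical CSV; names are
#'   the period labels.
#' @param out_dir output directory (created if missing).
#' @param ruleset a `wbcs_ruleset`.
#' @param map_format `"geojson"` or `"none"` (CSV tables are always written).
#' @param digits decimal places for the printed percentages (counts are exact
#'   integers; stored tables keep full precision, the written ones are rounded
#'   half-up).
#' @return an object of class `wbcs_pipeline_config`.
#' @export
pipeline_config <- function(inputs, out_dir, ruleset = default_ruleset(),
                            map_format = c("geojson", "none"), digits = 2) {
  map_format <- match.arg(map_format)
  if (length(inputs) < 1L) {
    abort_wbcs("at least one period input is required", "wbcs_config_error")
  }
  if (is.null(names(inputs)) || any(!nzchar(names(inputs)))) {
    abort_wbcs("inputs must be a named list (names = period labels)",
               "wbcs_config_error")
  }
  for (inp in inputs) {
    if (!inherits(inp, "climate_grid") &&
        !(is.character(inp) && file.exists(inp))) {
      abort_wbcs("each input must be a climate_grid or an existing file path",
                 "wbcs_config_error")
    }
  }
  structure(list(inputs = inputs, out_dir = out_dir, ruleset = ruleset,
                 map_format = map_format, digits = digits),
            class = "wbcs_pipeline_config")
}

round_pct_cols <- function(tbl, digits) {
  for (cn in grep("^(pct_|delta_pct|stable_pct|change_pct|pct_loss)",
                  names(tbl), value = TRUE)) {
    tbl[[cn]] <- round_half_up(tbl[[cn]], digits)
  }
  tbl
}

#' Run the full classification and comparison pipeline
#'
#' Reads (or takes) one climate grid per period, classifies every cell,
#' and writes to the output directory: per-period classified grids (CSV and,
#' optionally, GeoJSON maps), an area table per bioclimatic unit, the
#' isobioclimate catalogue and, when at least two periods are supplied,
#' first-to-last change masks per unit, the stability table, the diversity
#' summary and the warm/cold-thermotype and arid-ombrotype trend summaries.
#' A run manifest (ruleset version, input checksums, cell count) is written as
#' JSON. Re-running with identical inputs and ruleset yields identical tables.
#'
#' @param config a `wbcs_pipeline_config`.
#' @return invisibly, a list with the classifications, area tables, catalogue,
#'   and (when applicable) stability, diversity and trend tables.
#' @export
#' @examples
#' grids <- generate_grid(synthetic_grid_spec(n_cells = 30))
#' cfg <- pipeline_config(grids, out_dir = tempfile(), map_format = "none")
#' res <- run_pipeline(cfg)
#' names(res)
run_pipeline <- function(config) {
  stopifnot(inherits(config, "wbcs_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  rs <- config$ruleset
  stage <- "read"
  res <- list()
  tryCatch(
    {
      grids <- lapply(names(config$inputs), function(lbl) {
        inp <- config$inputs[[lbl]]
        if (inherits(inp, "climate_grid")) inp
        else read_climate_grid(inp, period_label = lbl)
      })
      names(grids) <- names(config$inputs)

      stage <- "classify"
      labels <- lapply(grids, classify_grid, ruleset = rs)
      for (lbl in names(labels)) {
        write_classified_grid(grids[[lbl]], labels[[lbl]],
                              file.path(config$out_dir,
                                        sprintf("classified_%s.csv", lbl)),
                              format = "csv")
        if (config$map_format == "geojson") {
          write_classified_grid(grids[[lbl]], labels[[lbl]],
                                file.path(config$out_dir,
                                          sprintf("classified_%s.geojson", lbl)),
                                format = "geojson")
        }
      }
      res$labels <- labels

      stage <- "tabulate"
      res$area_tables <- lapply(stats::setNames(nm = unit_columns),
                                function(u) area_table(labels, u, rs))
      for (u in unit_columns) {
        utils::write.csv(round_pct_cols(res$area_tables[[u]], config$digits),
                         file.path(config$out_dir,
                                   sprintf("area_%s.csv", u)),
                         row.names = FALSE)
      }
      res$catalog <- build_isobioclimate_catalog(labels, rs)
      utils::write.csv(res$catalog,
                       file.path(config$out_dir, "isobioclimate_catalog.csv"),
                       row.names = FALSE)

      if (length(labels) >= 2L) {
        stage <- "compare"
        first <- labels[[1]]
        last <- labels[[length(labels)]]
        res$masks <- lapply(stats::setNames(nm = unit_columns), function(u) {
          m <- change_mask(first, last, u)
          utils::write.csv(m, file.path(config$out_dir,
                                        sprintf("change_%s.csv", u)),
                           row.names = FALSE)
          if (config$map_format == "geojson") {
            write_classified_grid(grids[[1]], m,
                                  file.path(config$out_dir,
                                            sprintf("change_%s.geojson", u)),
                                  format = "geojson")
          }
          m
        })
        res$stability <- do.call(rbind, lapply(unit_columns, function(u) {
          stability_fraction(labels, u, rs)
        }))
        utils::write.csv(round_pct_cols(res$stability, 1),
                         file.path(config$out_dir, "stability.csv"),
                         row.names = FALSE)
        res$diversity <- diversity_summary(labels)
        utils::write.csv(round_pct_cols(res$diversity, 1),
                         file.path(config$out_dir, "diversity.csv"),
                         row.names = FALSE)
        res$trends <- list(
          thermotype = trend_summary(res$area_tables$thermotype,
                                     thermotype_belts(rs)),
          ombrotype = trend_summary(res$area_tables$ombrotype,
                                    ombrotype_groups(rs))
        )
        utils::write.csv(round_pct_cols(rbind(res$trends$thermotype,
                                              res$trends$ombrotype),
                                        config$digits),
                         file.path(config$out_dir, "trends.csv"),
                         row.names = FALSE)
      }

      stage <- "manifest"
      checksums <- vapply(config$inputs, function(inp) {
        if (is.character(inp)) unname(tools::md5sum(inp)) else
          paste0("cells:", nrow(inp$cells))
      }, "")
      manifest <- list(
        ruleset_version = rs$version,
        periods = names(config$inputs),
        inputs = as.list(checksums),
        n_cells = nrow(grids[[1]]$cells)
      )
      jsonlite::write_json(manifest,
                           file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    },
    error = function(e) {
      abort_wbcs(sprintf("pipeline stage '%s': %s", stage,
                         conditionMessage(e)),
                 class(e)[1])
    }
  )
  invisible(res)
}
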