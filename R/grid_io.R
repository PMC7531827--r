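# Reading, validating and writing gridded monthly climatologies.
#
# Canonical table schema (CSV, one row per cell):
#   cell_id, lat, lon, elev_m,
#   tmin_01..tmin_12, tmax_01..tmax_12, prec_01..prec_12
# Temperatures are monthly means of daily minima / maxima in degrees C,
# precipitation is the monthly total in mm, months are calendar months
# January to December (no water-year option).

canonical_columns <- function() {
  c("cell_id", "lat", "lon", "elev_m",
    month_cols("tmin"), month_cols("tmax"), month_cols("prec"))
}

#' Construct a climate grid from a cell table
#'
#' @param cells data frame in the canonical schema (see
#'   [read_climate_grid()]).
#' @param period_label text label for the climatology period, e.g.
#'   `"1980-2004"`.
#' @param resolution_deg grid spacing in degrees (default 0.22).
#' @param cell_area_km2 nominal area of one cell in km^2 (default 590.9).
#' @return an object of class `climate_grid`: a list with elements `cells`,
#'   `period_label`, `resolution_deg`, `cell_area_km2`.
#' @export
climate_grid <- function(cells, period_label = "unlabelled",
                         resolution_deg = 0.22, cell_area_km2 = 590.9) {
  cells <- validate_cells(cells)
  structure(
    list(cells = cells, period_label = period_label,
         resolution_deg = resolution_deg, cell_area_km2 = cell_area_km2),
    class = "climate_grid"
  )
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("<climate_grid> %d cells, period %s, %.2f deg resolution\n",
              nrow(x$cells), x$period_label, x$resolution_deg))
  invisible(x)
}

# Full invariant check of a canonical cell table. Violating rows are rejected
# together, with their identifiers listed, so a bad file fails loudly once.
validate_cells <- function(cells) {
  cols <- canonical_columns()
  if (anyDuplicated(names(cells))) {
    abort_wbcs(sprintf("duplicated columns: %s",
                       paste(unique(names(cells)[duplicated(names(cells))]),
                             collapse = ", ")), "wbcs_schema_error")
  }
  missing <- setdiff(cols, names(cells))
  if (length(missing)) {
    abort_wbcs(sprintf("missing columns: %s", paste(missing, collapse = ", ")),
               "wbcs_schema_error")
  }
  cells <- cells[, cols]
  if (nrow(cells) == 0L) {
    abort_wbcs("climate grid is empty", "wbcs_validation_error")
  }
  cells$cell_id <- as.character(cells$cell_id)
  num_cols <- setdiff(cols, "cell_id")
  for (cn in num_cols) {
    v <- cells[[cn]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(coerced) & !is.na(v) & trimws(as.character(v)) != "")
      if (length(bad)) {
        abort_wbcs(sprintf("non-numeric value in column %s, row(s) %s (cell %s)",
                           cn, paste(bad, collapse = ", "),
                           paste(cells$cell_id[bad], collapse = ", ")),
                   "wbcs_parse_error")
      }
      cells[[cn]] <- coerced
    }
    if (anyNA(cells[[cn]])) {
      bad <- which(is.na(cells[[cn]]))
      abort_wbcs(sprintf("missing value in column %s for cell(s) %s", cn,
                         paste(cells$cell_id[bad], collapse = ", ")),
                 "wbcs_parse_error")
    }
  }
  if (anyDuplicated(cells$cell_id)) {
    dup <- unique(cells$cell_id[duplicated(cells$cell_id)])
    abort_wbcs(sprintf("duplicated cell_id(s): %s", paste(dup, collapse = ", ")),
               "wbcs_validation_error")
  }
  tmin <- as.matrix(cells[, month_cols("tmin")])
  tmax <- as.matrix(cells[, month_cols("tmax")])
  prec <- as.matrix(cells[, month_cols("prec")])
  bad_ids <- character(0)
  bad_why <- character(0)
  note <- function(flag, why) {
    if (any(flag)) {
      bad_ids <<- c(bad_ids, cells$cell_id[flag])
      bad_why <<- c(bad_why, rep(why, sum(flag)))
    }
  }
  note(rowSums(prec < 0) > 0, "negative precipitation")
  note(rowSums(tmax < tmin) > 0, "tmax < tmin")
  note(cells$lat < -90 | cells$lat > 90, "latitude outside [-90, 90]")
  note(cells$lon < -180 | cells$lon > 180, "longitude outside [-180, 180]")
  if (length(bad_ids)) {
    u <- !duplicated(bad_ids)
    abort_wbcs(sprintf("invalid cell record(s): %s",
                       paste(sprintf("%s (%s)", bad_ids[u], bad_why[u]),
                             collapse = "; ")),
               "wbcs_validation_error")
  }
  rownames(cells) <- NULL
  cells
}

#' Read a gridded monthly climatology
#'
#' Reads and validates a climate table. Two dialects are supported:
#' `"canonical"` (one CSV in the canonical schema) and `"triplet"` (the
#' supplementary-material layout: three tables, one per variable, each with
#' `cell_id, lat, lon, elev_m, m_01..m_12`).
#'
#' @param path for `"canonical"`, one file path; for `"triplet"`, a character
#'   vector with named elements `tmin`, `tmax` and `prec`.
#' @param dialect `"canonical"` or `"triplet"`.
#' @param period_label,resolution_deg,cell_area_km2 passed to
#'   [climate_grid()].
#' @return a validated `climate_grid`.
#' @export
#' @examples
#' g <- generate_grid(synthetic_grid_spec(n_cells = 4))[[1]]
#' f <- tempfile(fileext = ".csv")
#' write_climate_grid(g, f)
#' g2 <- read_climate_grid(f, period_label = g$period_label)
#' nrow(g2$cells)
read_climate_grid <- function(path, dialect = c("canonical", "triplet"),
                              period_label = "unlabelled",
                              resolution_deg = 0.22, cell_area_km2 = 590.9) {
  dialect <- match.arg(dialect)
  if (dialect == "canonical") {
    if (!file.exists(path)) {
      abort_wbcs(sprintf("file not found: %s", path), "wbcs_schema_error")
    }
    cells <- utils::read.csv(path, check.names = FALSE,
                             colClasses = c(cell_id = "character"))
  } else {
    if (!all(c("tmin", "tmax", "prec") %in% names(path))) {
      abort_wbcs("triplet dialect needs paths named tmin, tmax and prec",
                 "wbcs_schema_error")
    }
    parts <- lapply(path[c("tmin", "tmax", "prec")], function(p) {
      if (!file.exists(p)) {
        abort_wbcs(sprintf("file not found: %s", p), "wbcs_schema_error")
      }
      utils::read.csv(p, check.names = FALSE,
                      colClasses = c(cell_id = "character"))
    })
    for (v in names(parts)) {
      need <- c("cell_id", "lat", "lon", "elev_m", month_cols("m"))
      missing <- setdiff(need, names(parts[[v]]))
      if (length(missing)) {
        abort_wbcs(sprintf("triplet table %s: missing columns %s", v,
                           paste(missing, collapse = ", ")),
                   "wbcs_schema_error")
      }
    }
    base <- parts$tmin[, c("cell_id", "lat", "lon", "elev_m")]
    for (v in c("tmax", "prec")) {
      if (!identical(parts[[v]]$cell_id, base$cell_id)) {
        abort_wbcs(sprintf("triplet table %s: cell_id set differs from tmin", v),
                   "wbcs_validation_error")
      }
    }
    cells <- cbind(base,
                   stats::setNames(parts$tmin[, month_cols("m")], month_cols("tmin")),
                   stats::setNames(parts$tmax[, month_cols("m")], month_cols("tmax")),
                   stats::setNames(parts$prec[, month_cols("m")], month_cols("prec")))
  }
  climate_grid(cells, period_label = period_label,
               resolution_deg = resolution_deg, cell_area_km2 = cell_area_km2)
}

#' Write a climate grid in the canonical CSV schema
#'
#' @param grid a `climate_grid`.
#' @param path output CSV path.
#' @return `path`, invisibly. Numeric values are written at full precision so
#'   that read-back reproduces the grid.
#' @export
write_climate_grid <- function(grid, path) {
  stopifnot(inherits(grid, "climate_grid"))
  utils::write.csv(grid$cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a classified grid to CSV or GeoJSON
#'
#' CSV output holds one row per cell with coordinates and all unit labels.
#' GeoJSON output (RFC 7946, WGS84, lon-lat order) holds one square Polygon
#' feature per cell (cell centre +/- half the grid resolution) with the labels
#' as properties; read-back reproduces the labels exactly.
#'
#' @param grid the `climate_grid` that was classified.
#' @param labels classification table from [classify_grid()] (one row per
#'   cell, matched by `cell_id`).
#' @param path output file path.
#' @param format `"csv"` or `"geojson"`.
#' @return `path`, invisibly.
#' @export
write_classified_grid <- function(grid, labels, path,
                                  format = c("csv", "geojson")) {
  format <- match.arg(format)
  stopifnot(inherits(grid, "climate_grid"))
  cells <- grid$cells
  if (!setequal(cells$cell_id, labels$cell_id) ||
      nrow(labels) != nrow(cells)) {
    abort_wbcs("labels do not match the grid's cells one-to-one",
               "wbcs_alignment_error")
  }
  labels <- labels[match(cells$cell_id, labels$cell_id), , drop = FALSE]
  if (format == "csv") {
    out <- cbind(cells[, c("cell_id", "lat", "lon", "elev_m")],
                 labels[, setdiff(names(labels), "cell_id"), drop = FALSE])
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  } else {
    h <- grid$resolution_deg / 2
    prop_cols <- setdiff(names(labels), "cell_id")
    features <- lapply(seq_len(nrow(cells)), function(i) {
      lon <- cells$lon[i]; lat <- cells$lat[i]
      ring <- list(c(lon - h, lat - h), c(lon + h, lat - h),
                   c(lon + h, lat + h), c(lon - h, lat + h),
                   c(lon - h, lat - h))
      props <- as.list(labels[i, prop_cols, drop = FALSE])
      props <- c(list(cell_id = cells$cell_id[i], elev_m = cells$elev_m[i]),
                 props)
      list(type = "Feature",
           geometry = list(type = "Polygon", coordinates = list(ring)),
           properties = props)
    })
    fc <- list(type = "FeatureCollection", features = features)
    jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read back a classified grid written as CSV
#'
#' @param path CSV written by [write_classified_grid()].
#' @return data frame of labels (with coordinates).
#' @export
read_classified_grid <- function(path) {
  utils::read.csv(path, check.names = FALSE,
                  colClasses = c(cell_id = "character"))
}
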