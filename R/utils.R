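# Shared internal helpers: interval lookups under the package-wide interval
# convention, calendar-wrapped window sums, and half-up rounding for tables.

#' @importFrom stats setNames
NULL

month_cols <- function(prefix) sprintf("%s_%02d", prefix, 1:12)

#' Match values to a table of [min, max) intervals
#'
#' Convention used by every threshold table: lower-closed, upper-open; the
#' final interval is upper-closed, and values above the final upper bound fall
#' into the final interval. Values below the first lower bound return `NA`.
#'
#' @param x numeric vector.
#' @param mins,maxs interval bounds, ordered so that `mins[k+1] == maxs[k]`.
#' @return integer vector of interval indices (NA below the table).
#' @keywords internal
#' @noRd
interval_match <- function(x, mins, maxs) {
  idx <- rep(NA_integer_, length(x))
  for (k in seq_along(mins)) {
    hit <- !is.na(x) & x >= mins[k] & x < maxs[k]
    idx[hit] <- k
  }
  last <- length(mins)
  idx[!is.na(x) & x >= maxs[last]] <- last
  idx
}

# Sums of `width` consecutive columns of an n x 12 matrix for every start
# month, with calendar wrap-around. Column s of the result is the sum over
# months s, s+1, ..., s+width-1 (mod 12).
wrap_window_sums <- function(mat, width) {
  stopifnot(ncol(mat) == 12L)
  out <- matrix(0, nrow(mat), 12L)
  for (s in 1:12) {
    idx <- ((s - 1L + 0:(width - 1L)) %% 12L) + 1L
    out[, s] <- rowSums(mat[, idx, drop = FALSE])
  }
  out
}

# Months of the window of `width` starting at month s (wrap-around).
wrap_window_months <- function(s, width) ((s - 1L + 0:(width - 1L)) %% 12L) + 1L

#' Round half away from zero (the convention of printed area tables)
#'
#' `round()` rounds half to even; climatological tables round 0.125 to 0.13.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.125, 2.675), 2)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_wbcs <- function(msg, class) {
  stop(structure(
    class = c(class, "wbcs_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
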