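# Hand-built single cells in the canonical schema.

make_cell_df <- function(ti, prec, lat = 48, lon = 70, elev = 200,
                         id = "cell", diurnal = 5) {
  stopifnot(length(ti) == 12, length(prec) == 12)
  df <- data.frame(cell_id = id, lat = lat, lon = lon, elev_m = elev,
                   stringsAsFactors = FALSE)
  df[, sprintf("tmin_%02d", 1:12)] <- rbind(ti - diurnal)
  df[, sprintf("tmax_%02d", 1:12)] <- rbind(ti + diurnal)
  df[, sprintf("prec_%02d", 1:12)] <- rbind(prec)
  df
}

make_grid <- function(..., period_label = "test") {
  climate_grid(do.call(rbind, list(...)), period_label = period_label)
}

# A continental mid-latitude profile with a controllable summer.
base_ti <- function(mean_t = 8, amp = 16) {
  mean_t + amp * cospi(((1:12) - 7) / 6)
}

# Random valid cells for property tests.
random_cells <- function(n, seed) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i) {
    ti <- runif(1, -12, 18) + runif(1, 2, 24) * cospi(((1:12) - 7) / 6) +
      rnorm(12, 0, 1.5)
    prec <- runif(12, 0, 90)
    make_cell_df(ti, prec, lat = runif(1, 40, 56), lon = runif(1, 46, 87),
                 elev = runif(1, 0, 3500), id = sprintf("r%03d", i))
  }))
}
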