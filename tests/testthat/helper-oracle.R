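# Independent single-cell oracle: scalar loops, no shared code with the
# package's vectorised implementation. Reads thresholds from the same ruleset
# object but re-implements every rule from scratch, so agreement between the
# two routes is informative.

oracle_window_sum <- function(x, s, width) {
  sum(x[((s - 1 + 0:(width - 1)) %% 12) + 1])
}

oracle_best_window <- function(ti, width, minimise = FALSE) {
  best_s <- 1
  best <- oracle_window_sum(ti, 1, width)
  for (s in 2:12) {
    v <- oracle_window_sum(ti, s, width)
    if ((minimise && v < best) || (!minimise && v > best)) {
      best <- v
      best_s <- s
    }
  }
  best_s
}

oracle_C <- function(ic, rs) {
  comp <- rs$compensation
  if (ic < comp$neutral_ic_min) {
    return(-comp$oceanic_factor * (comp$neutral_ic_min - ic))
  }
  C <- 0
  for (st in comp$continental_steps) {
    if (ic > st$ic_min) C <- C + st$factor * (min(ic, st$ic_max) - st$ic_min)
  }
  last <- comp$continental_steps[[length(comp$continental_steps)]]
  if (ic > last$ic_max) C <- C + last$factor * (ic - last$ic_max)
  C
}

oracle_ratio <- function(prec, ti, months) {
  tp <- 0
  p <- 0
  for (m in months) {
    if (ti[m] > 0) {
      tp <- tp + 10 * ti[m]
      p <- p + prec[m]
    }
  }
  if (tp > 0) 10 * p / tp else NA_real_
}

oracle_indices <- function(row, rs) {
  ti <- numeric(12)
  tmin <- numeric(12)
  tmax <- numeric(12)
  prec <- numeric(12)
  for (m in 1:12) {
    tmin[m] <- row[[sprintf("tmin_%02d", m)]]
    tmax[m] <- row[[sprintf("tmax_%02d", m)]]
    prec[m] <- row[[sprintf("prec_%02d", m)]]
    ti[m] <- (tmin[m] + tmax[m]) / 2
  }
  summer <- if (row$lat >= 0) 6:8 else c(12, 1, 2)
  winter <- if (row$lat >= 0) c(12, 1, 2) else 6:8
  cold <- which.min(ti)
  Tp <- sum(ifelse(ti > 0, 10 * ti, 0))
  Tps <- sum(ifelse(ti[summer] > 0, 10 * ti[summer], 0))
  Ic <- max(ti) - min(ti)
  It <- (mean(ti) + tmin[cold] + tmax[cold]) * 10
  s6 <- oracle_best_window(ti, 6)
  c6 <- oracle_best_window(ti, 6, minimise = TRUE)
  s4 <- oracle_best_window(ti, 4)
  months4 <- function(s) ((s - 1 + 0:3) %% 12) + 1
  pre <- ((summer[1] - 2) %% 12) + 1
  # warmest contiguous summer pair
  pair <- if (ti[summer[2]] + ti[summer[3]] > ti[summer[1]] + ti[summer[2]]) {
    summer[2:3]
  } else {
    summer[1:2]
  }
  dq <- oracle_best_window(prec, 3, minimise = TRUE)
  dq_months <- ((dq - 1 + 0:2) %% 12) + 1
  dry2 <- dq_months[order(prec[dq_months])[1:2]]
  shift <- rs$reduction$temperature_coeff_per_100m *
    (row$elev_m - rs$reduction$reference_elevation_m) / 100
  ti200 <- ti + shift
  cold200 <- which.min(ti200)
  Io <- oracle_ratio(prec, ti, 1:12)
  Ios2 <- oracle_ratio(prec, ti, pair)
  Iosc3 <- oracle_ratio(prec, ti, summer)
  Iosc4 <- oracle_ratio(prec, ti, c(pre, summer))
  sa <- rs$summer_aridity
  comp <- (!is.na(Iosc3) && Iosc3 > sa$iosc3_gate) ||
    (!is.na(Iosc4) && !is.na(Io) && Iosc4 > sa$iosc4_gate &&
       Io > sa$iosc4_io_min)
  list(
    T = mean(ti), Tmax = max(ti), Tmin = min(ti),
    M = tmax[cold], m = tmin[cold], Tp = Tp, Tps = Tps, Ic = Ic, It = It,
    Itc = It + oracle_C(Ic, rs),
    P = sum(prec), Pp = sum(prec[ti > 0]),
    Ps = sum(prec[summer]), Pw = sum(prec[winter]),
    Pps = sum(prec[summer][ti[summer] > 0]),
    Ppw = sum(prec[winter][ti[winter] > 0]),
    Pss = oracle_window_sum(prec, s6, 6), Psw = oracle_window_sum(prec, c6, 6),
    Pcm1 = sum(prec[months4(s4)]),
    Pcm2 = sum(prec[months4(((s4 - 1 + 4) %% 12) + 1)]),
    Pcm3 = sum(prec[months4(((s4 - 1 - 4) %% 12) + 1)]),
    Io = Io, Ios2 = Ios2, Iosc3 = Iosc3, Iosc4 = Iosc4,
    Iod2 = oracle_ratio(prec, ti, dry2),
    summer_arid = !is.na(Ios2) && Ios2 <= sa$ios2_max && !comp,
    T200 = mean(ti200),
    Itc200 = (mean(ti200) + tmin[cold200] + shift + tmax[cold200] + shift) *
      10 + oracle_C(Ic, rs),
    Tp200 = sum(ifelse(ti200 > 0, 10 * ti200, 0)),
    summer = summer, ti = ti, prec = prec
  )
}

# Scalar rule evaluator for one cell: plain if/else over the ruleset.
oracle_classify <- function(row, rs) {
  x <- oracle_indices(row, rs)
  mb <- rs$macrobioclimate
  macro <- if (x$Tp200 < mb$polar_tp200_max) {
    "POLAR"
  } else if (x$Tp200 < mb$boreal_tp200_max) {
    "BOREAL"
  } else if (x$T200 >= mb$tropical_t200_min && x$m >= mb$tropical_m_min) {
    "TROPICAL"
  } else if (x$summer_arid) {
    "MEDITERRANEAN"
  } else {
    "TEMPERATE"
  }

  bc <- rs$bioclimate
  continental <- x$Ic >= bc$oceanic_ic_max
  bio <- if (macro == "MEDITERRANEAN") {
    hit <- NULL
    for (cl in bc$mediterranean$io_classes) {
      hi <- if (identical(cl$io_max, ".inf")) Inf else cl$io_max
      if (x$Io >= cl$io_min && (x$Io < hi || is.infinite(hi))) {
        hit <- cl
        break
      }
    }
    if (continental) hit$continental else hit$oceanic
  } else {
    sub <- bc[[tolower(macro)]]
    if (macro == "POLAR" && x$Tp200 < sub$pergelid_tp200_max) {
      sub$pergelid
    } else if (!is.na(x$Io) && x$Io < sub$xeric_io_max) {
      sub$xeric
    } else if (x$Ic < sub$hyperoceanic_ic_max) {
      sub$hyperoceanic
    } else if (!continental) {
      sub$oceanic
    } else {
      sub$continental
    }
  }

  va <- rs$variants
  stp <- macro %in% va$steppic$macros && x$Ps >= x$Pw && !is.na(x$Io) &&
    x$Io > va$steppic$io_min && x$Io <= va$steppic$io_max
  if (stp) {
    for (m in x$summer) {
      if (x$prec[m] >= va$steppic$monthly_factor * x$ti[m]) stp <- FALSE
    }
  }
  sbm <- FALSE
  if (macro %in% va$submediterranean$macros) {
    for (m in x$summer) {
      if (x$prec[m] < va$submediterranean$monthly_factor * x$ti[m]) sbm <- TRUE
    }
  }
  variant <- if (stp) va$steppic$code else if (sbm) va$submediterranean$code
    else va$normal$code

  tt <- rs$thermotype
  tab <- tt[[tolower(macro)]]
  scan_bands <- function(v, bands) {
    # bands listed warm to cold; clamp beyond both ends
    mins <- sapply(bands, function(b) b$min)
    maxs <- sapply(bands, function(b) if (identical(b$max, ".inf")) Inf else b$max)
    codes <- sapply(bands, function(b) b$code)
    if (v >= maxs[1]) return(codes[1])
    for (k in seq_along(bands)) {
      if (v >= mins[k] && v < maxs[k]) return(codes[k])
    }
    codes[length(codes)]
  }
  thermo <- if (macro %in% c("MEDITERRANEAN", "TEMPERATE")) {
    if (x$Ic >= tt$dispatch_ic_min || x$Itc < tt$dispatch_itc_min) {
      scan_bands(x$Tp, tab$tp)
    } else {
      scan_bands(x$Itc, tab$itc)
    }
  } else {
    scan_bands(x$Tp, tab$tp)
  }

  ob <- rs$ombrotype
  ombro <- if (x$Tp < ob$snowy_tp_max) {
    ob$snowy_code
  } else {
    hit <- NA_character_
    for (cl in ob$classes) {
      hi <- if (identical(cl$io_max, ".inf")) Inf else cl$io_max
      if (x$Io >= cl$io_min && (x$Io < hi || is.infinite(hi))) {
        hit <- cl$code
        break
      }
    }
    hit
  }

  list(macrobioclimate = macro, bioclimate = bio, variant = variant,
       thermotype = thermo, ombrotype = ombro,
       isobioclimate = paste(bio, thermo, ombro))
}
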