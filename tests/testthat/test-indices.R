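test_that("monthly means average the extremes", {
  expect_equal(monthly_means(rep(10, 12), rep(10, 12)), rep(10, 12))
  expect_equal(monthly_means(c(-20, rep(0, 11)), c(-10, rep(0, 11)))[1], -15)
  tmin <- rnorm(12, 0, 10); tmax <- tmin + runif(12, 0, 12)
  expect_equal(mean(monthly_means(tmin, tmax)), mean(c(tmin, tmax)))
})

test_that("thermal parameters follow their definitions", {
  th <- thermal_parameters(rep(10, 12), rep(5, 12), rep(15, 12))
  expect_equal(th$Tp, 1200)
  expect_equal(th$Ic, 0)

  th <- thermal_parameters(rep(-5, 12), rep(-10, 12), rep(0, 12))
  expect_equal(th$Tp, 0)
  expect_equal(th$Tps, 0)

  ti <- 5 + 20 * cospi(((1:12) - 7) / 6)   # Tmax 25, Tmin -15
  th <- thermal_parameters(ti, ti - 5, ti + 5)
  expect_equal(th$Ic, 40)
  expect_equal(th$It, (th$T + th$m + th$M) * 10)
})

test_that("coldest-month ties resolve to the earliest calendar month", {
  ti <- c(-5, 3, 3, 3, 3, 3, 3, 3, 3, 3, 3, -5)   # Jan and Dec tie
  tmin <- ti - (1:12) / 10                         # distinguishable extremes
  tmax <- ti + (1:12) / 10
  th <- thermal_parameters(ti, tmin, tmax)
  brute <- which(ti == min(ti))[1]
  expect_equal(th$m, tmin[brute])
  expect_equal(th$M, tmax[brute])
})

test_that("precipitation parameters follow their definitions", {
  pr <- precipitation_parameters(rep(30, 12), base_ti())
  expect_equal(pr$P, 360)
  expect_equal(pr$Ps, 90)
  expect_equal(pr$Pw, 90)
  expect_equal(pr$Pcm1, 120)

  pr <- precipitation_parameters(runif(12, 10, 50), rep(-2, 12))
  expect_equal(pr$Pp, 0)

  prec <- rep(0, 12); prec[7] <- 50
  pr <- precipitation_parameters(prec, base_ti())
  expect_equal(pr$Ps, 50)
  expect_equal(pr$Pw, 0)
})

test_that("ombrothermic indices follow their definitions", {
  om <- ombrothermic_indices(rep(20, 12), rep(10, 12))
  expect_equal(om$Io, 2.0)   # 10 * 240 / 1200

  om <- ombrothermic_indices(rep(0, 12), base_ti())
  expect_equal(om$Io, 0)
  expect_equal(om$Ios2, 0)

  # summer (P, T) = (10, 20), (5, 25), (8, 24): the warmest contiguous pair is
  # the last two months
  ti <- c(rep(1, 5), 20, 25, 24, rep(1, 4))
  prec <- c(rep(0, 5), 10, 5, 8, rep(0, 4))
  om <- ombrothermic_indices(prec, ti)
  expect_equal(om$Ios2, 10 * 13 / 490)
  expect_equal(om$Iosi, c(10 / 20, 5 / 25, 8 / 24))

  # Tp = 0 leaves Io undefined, never infinite
  om <- ombrothermic_indices(rep(30, 12), rep(-3, 12))
  expect_true(is.na(om$Io))
})

test_that("continentality compensation is zero in the neutral band and steps upward", {
  expect_equal(continentality_compensation(c(9, 12, 18)), c(0, 0, 0))
  expect_equal(compensated_thermicity(150, 12), 150)
  # transcribed steps: 5/(18,21], 15/(21,28], 25/(28,46]
  expect_equal(continentality_compensation(30), 3 * 5 + 7 * 15 + 2 * 25)
  expect_equal(continentality_compensation(5), -40)
  ic <- seq(18, 80, by = 0.25)
  C <- continentality_compensation(ic)
  expect_true(all(diff(C) >= 0))
  expect_error(continentality_compensation(-1), class = "wbcs_config_error")
})

test_that("200 m reduction is a no-op at 200 m and shifts months by the coefficient", {
  ti <- base_ti(5)
  red <- reduce_to_200m(ti, ti - 5, ti + 5, elevation_m = 200, Ic = 32)
  th <- thermal_parameters(ti, ti - 5, ti + 5)
  expect_equal(red$T200, th$T)
  expect_equal(red$Tp200, th$Tp)
  expect_equal(red$M200, th$M)

  red <- reduce_to_200m(ti, ti - 5, ti + 5, elevation_m = 1200, Ic = 32)
  th6 <- thermal_parameters(ti + 6, ti + 1, ti + 11)
  expect_equal(red$shift, 6)
  expect_equal(red$Tp200, th6$Tp)
  expect_equal(red$T200, th$T + 6)
})

test_that("reduction strictly increases Tp200 above 200 m when a month sits in (-shift, 0]", {
  for (seed in 1:20) {
    set.seed(seed)
    ti <- runif(1, -10, 10) + runif(1, 5, 20) * cospi(((1:12) - 7) / 6)
    elev <- runif(1, 300, 3000)
    shift <- 0.6 * (elev - 200) / 100
    if (!any(ti <= 0 & ti > -shift)) next
    red <- reduce_to_200m(ti, ti - 5, ti + 5, elevation_m = elev, Ic = 30)
    tp <- thermal_parameters(ti, ti - 5, ti + 5)$Tp
    expect_gt(red$Tp200, tp)
  }
})

test_that("summer-aridity cascade follows the gates", {
  expect_false(summer_aridity(Io = 1, Ios2 = 3.5, Iosc3 = 0, Iosc4 = 0))
  expect_true(summer_aridity(Io = 1, Ios2 = 1.0, Iosc3 = 1.2, Iosc4 = 1.5))
  expect_false(summer_aridity(Io = 1, Ios2 = 1.8, Iosc3 = 2.5, Iosc4 = 0))
  # the Iosc4 branch compensates only in rainy territories
  expect_false(summer_aridity(Io = 7, Ios2 = 1.8, Iosc3 = 1.0, Iosc4 = 2.5))
  expect_true(summer_aridity(Io = 5, Ios2 = 1.8, Iosc3 = 1.0, Iosc4 = 2.5))
})

test_that("index invariances hold on random cells", {
  rs <- default_ruleset()
  cells <- random_cells(25, seed = 42)
  g <- climate_grid(cells)
  idx <- bioclim_indices(g)

  # order relations
  expect_true(all(idx$Tps <= idx$Tp + 1e-9))
  expect_true(all(idx$Pps <= idx$Pp + 1e-9))
  expect_true(all(idx$Pp <= idx$P + 1e-9))
  expect_true(all(idx$Ps + idx$Pw <= idx$P + 1e-9))
  expect_true(all(idx$Ic >= 0))
  expect_true(all(idx$M >= idx$m))

  # uniform warming leaves Ic unchanged and never decreases Tp
  shift <- cells
  tcols <- c(sprintf("tmin_%02d", 1:12), sprintf("tmax_%02d", 1:12))
  shift[, tcols] <- shift[, tcols] + 3
  idx2 <- bioclim_indices(climate_grid(shift))
  expect_equal(idx2$Ic, idx$Ic)
  expect_true(all(idx2$Tp >= idx$Tp))

  # scaling precipitation by k scales the linear quantities by k
  k <- 1.7
  scaled <- cells
  pcols <- sprintf("prec_%02d", 1:12)
  scaled[, pcols] <- scaled[, pcols] * k
  idx3 <- bioclim_indices(climate_grid(scaled))
  for (cn in c("P", "Pp", "Ps", "Pw", "Io", "Ios2")) {
    expect_equal(idx3[[cn]], k * idx[[cn]], tolerance = 1e-12)
  }

  # purity: recomputation is bit-identical
  expect_identical(idx, bioclim_indices(g))
})

test_that("windowed quantities match a brute-force scan over all windows", {
  rs <- default_ruleset()
  cells <- random_cells(30, seed = 99)
  idx <- bioclim_indices(climate_grid(cells))
  for (i in seq_len(nrow(cells))) {
    o <- oracle_indices(cells[i, ], rs)
    for (q in c("Pcm1", "Pcm2", "Pcm3", "Pss", "Psw", "Ios2", "Iod2")) {
      expect_equal(idx[[q]][i], o[[q]], tolerance = 1e-12,
                   label = sprintf("%s cell %d", q, i))
    }
  }
})

test_that("the full index table agrees with the independent scalar oracle", {
  rs <- default_ruleset()
  cells <- random_cells(40, seed = 4)
  idx <- bioclim_indices(climate_grid(cells))
  keys <- c("T", "Tmax", "Tmin", "M", "m", "Tp", "Tps", "Ic", "It", "Itc",
            "P", "Pp", "Ps", "Pw", "Pps", "Ppw", "Io", "Iosc3", "Iosc4",
            "T200", "Itc200", "Tp200")
  for (i in seq_len(nrow(cells))) {
    o <- oracle_indices(cells[i, ], rs)
    for (q in keys) {
      expect_equal(idx[[q]][i], o[[q]], tolerance = 1e-9,
                   label = sprintf("%s cell %d", q, i))
    }
    expect_identical(idx$summer_arid[i], o$summer_arid)
  }
})
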