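test_that("summer rain alone flips a continental cell from mediterranean to temperate", {
  ti <- base_ti(8, 16)                     # continental profile, Tp well above the boreal band
  dry <- rep(0, 12); dry[c(3, 4, 10, 11)] <- 60
  arid_cell <- make_cell_df(ti, dry, id = "arid")
  wet <- dry; wet[6:8] <- 3 * ti[6:8]      # Iosi = 3 > 2 each summer month
  rain_cell <- make_cell_df(ti, wet, id = "rainy")
  lab <- classify_grid(make_grid(arid_cell, rain_cell))
  expect_identical(lab$macrobioclimate, c("MEDITERRANEAN", "TEMPERATE"))
})

test_that("cold mountain cells reach the boreal and polar Tp bands", {
  rs <- default_ruleset()
  ti <- -6 + 14 * cospi(((1:12) - 7) / 6)  # Tp ~ 250 at true elevation
  # pick elevations whose reduction lands mid-band
  idx <- bioclim_indices(climate_grid(
    make_cell_df(ti, rep(40, 12), elev = 200, id = "x")))
  shift_for <- function(tp200) {
    f <- function(d) 10 * sum(pmax(ti + d, 0)) - tp200
    uniroot(f, c(0, 60))$root
  }
  e_boreal <- 200 + 100 * shift_for(550) / 0.6
  # at the reference height this profile's Tp already sits in the polar band
  expect_lt(idx$Tp200, rs$macrobioclimate$polar_tp200_max)
  g <- make_grid(
    make_cell_df(ti, rep(40, 12), elev = e_boreal, id = "boreal"),
    make_cell_df(ti, rep(40, 12), elev = 200, id = "polar")
  )
  lab <- classify_grid(g)
  expect_identical(lab$macrobioclimate, c("BOREAL", "POLAR"))
})

test_that("bioclimates split on Io bands and the Ic = 21 oceanic boundary", {
  expect_identical(classify_bioclimate("MEDITERRANEAN", 33, 0.7), "MEDC")
  expect_identical(classify_bioclimate("MEDITERRANEAN", 19, 0.7), "MEDO")
  expect_identical(classify_bioclimate("MEDITERRANEAN", 33, 1.5), "MEXC")
  expect_identical(classify_bioclimate("MEDITERRANEAN", 33, 2.5), "MEPC")
  expect_identical(classify_bioclimate("MEDITERRANEAN", 33, 0.1), "MEHC")
  expect_identical(classify_bioclimate("TEMPERATE", 30, 2.8), "TEXE")
  expect_identical(classify_bioclimate("TEMPERATE", 30, 4.5), "TECO")
  expect_identical(classify_bioclimate("TEMPERATE", 15, 4.5), "TEOC")
  expect_identical(classify_bioclimate("BOREAL", 30, 2.8), "BOXE")
  expect_identical(classify_bioclimate("BOREAL", 30, 4.5), "BOCO")
})

test_that("the steppe variant requires its three printed conditions", {
  rs <- default_ruleset()
  # summer (P, T) = (20, 20), (15, 22), (18, 21); Ps >= Pw; Io inside (0.2, 6]
  ti <- c(rep(2, 5), 20, 22, 21, rep(2, 4))
  prec <- rep(4, 12); prec[6:8] <- c(20, 15, 18)
  g <- make_grid(make_cell_df(ti, prec, id = "stp"))
  idx <- bioclim_indices(g)
  expect_true(idx$Ps >= idx$Pw)
  expect_true(idx$Io > 0.2 && idx$Io <= 6)
  macro <- classify_macrobioclimate(idx)
  expect_identical(classify_variant(macro, idx, g), "Stp")

  # raising Io above 6.0 with non-summer rain disqualifies the steppe variant
  prec2 <- prec; prec2[c(3, 4, 10, 11)] <- 220
  g2 <- make_grid(make_cell_df(ti, prec2, id = "nostp"))
  idx2 <- bioclim_indices(g2)
  expect_gt(idx2$Io, 6)
  macro2 <- classify_macrobioclimate(idx2)
  v2 <- classify_variant(macro2, idx2, g2)
  expect_false(v2 == "Stp")
  expect_true(v2 %in% c("Sbm", "Nor"))

  # a summer month at or above 3 * Ti also disqualifies it
  prec3 <- prec; prec3[7] <- 3 * ti[7]
  g3 <- make_grid(make_cell_df(ti, prec3, id = "wetjul"))
  idx3 <- bioclim_indices(g3)
  expect_false(classify_variant(classify_macrobioclimate(idx3), idx3, g3) ==
                 "Stp")
})

test_that("one summer month below 2.8 * Ti makes a temperate cell submediterranean", {
  ti <- base_ti(8, 14)
  ti[7] <- 20
  prec <- rep(60, 12)
  prec[6:8] <- c(3.2 * ti[6], 40, 3.2 * ti[8])   # July: 40 < 2.8 * 20 = 56
  prec[c(3, 4, 5, 9, 10)] <- 150                 # Io > 6 so Stp cannot fire
  g <- make_grid(make_cell_df(ti, prec, id = "sbm"))
  idx <- bioclim_indices(g)
  macro <- classify_macrobioclimate(idx)
  expect_identical(macro, "TEMPERATE")
  expect_identical(classify_variant(macro, idx, g), "Sbm")

  # with July at 2.8 * Ti the condition fails and the cell is normal
  prec[7] <- 2.8 * 20
  g2 <- make_grid(make_cell_df(ti, prec, id = "nor"))
  idx2 <- bioclim_indices(g2)
  expect_identical(classify_variant(classify_macrobioclimate(idx2), idx2, g2),
                   "Nor")
})

test_that("thermotypes dispatch between Itc and Tp as printed", {
  # continental (Ic >= 21): always by Tp
  expect_identical(classify_thermotype("MEDITERRANEAN", 33, 500, 1200), "Sme")
  expect_identical(classify_thermotype("MEDITERRANEAN", 33, 500, 1800), "Mme")
  # oceanic with Itc >= 120: by Itc
  expect_identical(classify_thermotype("MEDITERRANEAN", 15, 300, 1200), "Mme")
  # oceanic with Itc < 120: back to Tp
  expect_identical(classify_thermotype("MEDITERRANEAN", 15, 80, 1200), "Sme")
  # boreal: directly by Tp, whatever Ic and Itc
  expect_identical(classify_thermotype("BOREAL", 10, 400, 335), "Obo")
  expect_identical(classify_thermotype("BOREAL", 40, -100, 175), "Cbo")
  # beyond the table's ends: nearest class
  expect_identical(classify_thermotype("TEMPERATE", 30, 0, 50), "Gel")
  expect_identical(classify_thermotype("TEMPERATE", 30, 0, 9000), "Ite")
})

test_that("ombrotypes tile the Io axis and rank monotonically", {
  expect_identical(classify_ombrotype(c(0.7, 0, 1.5, 2.8, 30)),
                   c("Ari", "Uha", "Sar", "Sec", "Uhh"))
  rs <- default_ruleset()
  io <- sort(runif(300, 0, 30))
  ranks <- match(classify_ombrotype(io), rs$order$ombrotype)
  expect_true(all(diff(ranks) >= 0))
  # gelid cells take the snowy code regardless of Io
  expect_identical(classify_ombrotype(5, Tp = 50), "Ssnw")
})

test_that("classify_cell is deterministic and assembles the isobioclimate", {
  fx <- branch_fixtures()
  cell <- fx$cells[fx$cells$cell_id == "MEDC_Sme_Ari", ]
  lab <- classify_cell(cell)
  expect_identical(lab$isobioclimate, "MEDC Sme Ari")
  expect_identical(lab, classify_cell(cell))
  lab2 <- classify_cell(list(cell_id = "v", lat = 48,
                             tmin = as.numeric(cell[sprintf("tmin_%02d", 1:12)]),
                             tmax = as.numeric(cell[sprintf("tmax_%02d", 1:12)]),
                             prec = as.numeric(cell[sprintf("prec_%02d", 1:12)])))
  expect_identical(lab2$isobioclimate, "MEDC Sme Ari")
})

test_that("the isobioclimate catalogue is ordered, keyed from 1 and idempotent", {
  a <- data.frame(cell_id = c("1", "2"),
                  isobioclimate = c("MEXC Sme Sar", "MEPC Sme Sec"))
  cat1 <- build_isobioclimate_catalog(a)
  expect_identical(cat1$key, 1:2)
  expect_identical(cat1$isobioclimate, c("MEPC Sme Sec", "MEXC Sme Sar"))
  b <- data.frame(cell_id = c("1", "2"),
                  isobioclimate = c("MEPC Sme Sec", "MEPC Sme Sec"))
  cat2 <- build_isobioclimate_catalog(list(a, b))
  expect_identical(cat2, cat1)
})

test_that("vectorised classification equals the scalar rule evaluator", {
  rs <- default_ruleset()
  fx <- branch_fixtures(rs)
  cells <- rbind(fx$cells, random_cells(40, seed = 17))
  lab <- classify_grid(climate_grid(cells), rs)
  for (i in seq_len(nrow(cells))) {
    o <- oracle_classify(cells[i, ], rs)
    for (u in c("macrobioclimate", "bioclimate", "variant", "thermotype",
                "ombrotype", "isobioclimate")) {
      expect_identical(lab[[u]][i], o[[u]],
                       label = sprintf("%s for %s", u, cells$cell_id[i]))
    }
  }
})
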