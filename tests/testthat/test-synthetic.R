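test_that("the same spec and seed reproduce the grids exactly", {
  s <- synthetic_grid_spec(n_cells = 50, seed = 21)
  g1 <- generate_grid(s)
  g2 <- generate_grid(s)
  expect_identical(g1, g2)
  g3 <- generate_grid(synthetic_grid_spec(n_cells = 50, seed = 22))
  expect_false(identical(g1[[1]]$cells, g3[[1]]$cells))
})

test_that("generated grids satisfy the cell invariants", {
  g <- generate_grid(synthetic_grid_spec(n_cells = 200, seed = 9))
  for (p in g) {
    cells <- p$cells
    expect_true(all(cells[, sprintf("prec_%02d", 1:12)] >= 0))
    expect_true(all(cells[, sprintf("tmax_%02d", 1:12)] >=
                      cells[, sprintf("tmin_%02d", 1:12)]))
    expect_false(anyDuplicated(cells$cell_id) > 0)
  }
})

test_that("zero noise and zero deltas give identical classifications per period", {
  s <- synthetic_grid_spec(n_cells = 120, seed = 13,
                           period_t_winter = c(0, 0), period_t_summer = c(0, 0),
                           period_prec_scale = c(1, 1),
                           period_labels = c("a", "b"),
                           noise_sd_t = 0, noise_frac_prec = 0)
  g <- generate_grid(s)
  la <- classify_grid(g$a)
  lb <- classify_grid(g$b)
  attr(la, "period_label") <- attr(lb, "period_label") <- NULL
  expect_identical(la, lb)
})

test_that("summer-weighted warming never shrinks the warm-thermotype area", {
  s <- synthetic_grid_spec(n_cells = 400, seed = 31,
                           noise_sd_t = 0, noise_frac_prec = 0)
  g <- generate_grid(s)
  warm <- thermotype_belts()$warm
  counts <- vapply(g, function(p) {
    sum(classify_grid(p)$thermotype %in% warm)
  }, 0L)
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[3], counts[1])
})

test_that("noise-free grids recover the analytically implied class layout", {
  rs <- default_ruleset()
  s <- synthetic_grid_spec(n_cells = 150, seed = 61,
                           noise_sd_t = 0, noise_frac_prec = 0)
  g <- generate_grid(s)[[1]]
  lab <- classify_grid(g, rs)
  for (i in seq_len(nrow(g$cells))) {
    o <- oracle_classify(g$cells[i, ], rs)
    expect_identical(lab$isobioclimate[i], o$isobioclimate,
                     label = sprintf("cell %s", g$cells$cell_id[i]))
    expect_identical(lab$variant[i], o$variant)
  }
})

test_that("warming alone never raises an ombrotype's humidity rank", {
  rs <- default_ruleset()
  cells <- random_cells(40, seed = 77)
  tcols <- c(sprintf("tmin_%02d", 1:12), sprintf("tmax_%02d", 1:12))
  idx <- bioclim_indices(climate_grid(cells))
  warmed <- cells
  warmed[, tcols] <- warmed[, tcols] + 2
  idx2 <- bioclim_indices(climate_grid(warmed))
  # restrict to cells already positive in every month: no positivity boundary
  # can be crossed, so Tp grows while Pp stays fixed
  all_pos <- apply(monthly_means(as.matrix(cells[, tcols[1:12]]),
                                 as.matrix(cells[, tcols[13:24]])) > 0, 1, all)
  ranks1 <- match(classify_ombrotype(idx$Io[all_pos], idx$Tp[all_pos]),
                  rs$order$ombrotype)
  ranks2 <- match(classify_ombrotype(idx2$Io[all_pos], idx2$Tp[all_pos]),
                  rs$order$ombrotype)
  expect_true(all(ranks2 <= ranks1))
})

test_that("branch fixtures cover every reported class and hit their targets", {
  rs <- default_ruleset()
  fx <- branch_fixtures(rs)
  lab <- classify_grid(fx, rs)
  exp <- attr(fx, "expected")
  m <- merge(exp, lab, by = "cell_id", suffixes = c(".want", ".got"))
  expect_identical(m$bioclimate.got, m$bioclimate.want)
  expect_identical(m$thermotype.got, m$thermotype.want)
  expect_identical(m$ombrotype.got, m$ombrotype.want)
  expect_identical(m$variant.got, m$variant.want)

  # the classes reported for a strongly continental territory with mountains
  expect_true(all(c("MEPC", "MEXO", "MEXC", "MEDO", "MEDC", "MEHC",
                    "TECO", "TEXE", "BOCO", "BOXE") %in% lab$bioclimate))
  expect_true(all(c("Tme", "Mme", "Sme", "Ome", "Cme", "Ste", "Ote", "Cte",
                    "Obo", "Cbo", "Gel") %in% lab$thermotype))
  expect_true(all(c("Uha", "Har", "Ari", "Sar", "Sec", "Shu", "Hum", "Hhu",
                    "Uhh", "Ssnw") %in% lab$ombrotype))
  expect_true(all(c("Stp", "Sbm", "Nor") %in% lab$variant))
  expect_true(all(c("Semicontinental", "Subcontinental", "Eucontinental",
                    "Hypercontinental") %in% lab$continentality_subtype))
})

test_that("mid-interval fixtures are insensitive to 1e-6 perturbations", {
  rs <- default_ruleset()
  fx <- branch_fixtures(rs)
  lab0 <- classify_grid(fx, rs)
  vcols <- setdiff(names(fx$cells), c("cell_id", "lat", "lon", "elev_m"))
  for (eps in c(-1e-6, 1e-6)) {
    cells <- fx$cells
    cells[, vcols] <- cells[, vcols] + eps
    pcols <- grep("^prec", vcols, value = TRUE)
    cells[, pcols] <- pmax(as.matrix(cells[, pcols]), 0)
    lab <- classify_grid(climate_grid(cells), rs)
    expect_identical(lab$isobioclimate, lab0$isobioclimate,
                     label = sprintf("eps %g", eps))
    expect_identical(lab$variant, lab0$variant)
  }
})

test_that("an unsuitable ruleset raises a configuration error in fixture building", {
  path <- system.file("extdata", "wbcs_ruleset_1.0.yaml", package = "wbcs")
  rs <- yaml::read_yaml(path)
  rs$macrobioclimate$boreal_tp200_max <- 1e6   # no warm macro can host fixtures
  class(rs) <- "wbcs_ruleset"
  expect_error(branch_fixtures(rs), class = "wbcs_config_error")
})

test_that("spec validation rejects inconsistent period deltas", {
  expect_error(synthetic_grid_spec(period_t_winter = c(0, 2, 2),
                                   period_t_summer = c(0, 1, 3)),
               class = "wbcs_config_error")
  expect_error(synthetic_grid_spec(n_cells = 0), class = "wbcs_config_error")
  expect_error(synthetic_grid_spec(period_t_winter = c(0, 0)),
               class = "wbcs_config_error")
})
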