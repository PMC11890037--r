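gm <- methods::new("GrassMassModel", vegtype = "x", coefficient = 0.05,
                   adjR2 = 0.9, n = 10L)

test_that("unit-level trunkload operations match hand evaluations", {
  expect_equal(grassTrunkload(gm, height = 30, basalArea = 60), 90)
  expect_equal(grassTrunkload(gm, height = 0, basalArea = 60), 0)
  expect_equal(annualGrassTrunkload(c(10, 30), c(0.5, 0.5)), 20)
  expect_error(annualGrassTrunkload(c(10, 30), c(0.5, 0.4)), "sum to 1")

  expect_equal(forbTrunkload(62.7, 1, 1), 62.7)
  expect_equal(forbTrunkload(62.7, 1, 0), 0)
  expect_equal(forbTrunkload(c(100, 20), c(0.25, 0.75), 0.5), 20)

  # equal-weight mean of the two available species
  expect_equal(leafTrunkload(c(36.8, 22.8), c(0.5, 0.5), c(0.9, 0.8)), 29.8)
  # availability filter removes everything
  expect_equal(leafTrunkload(c(36.8, 22.8), c(0.5, 0.5), c(0.2, 0.25)), 0)
  # one available species: exactly its trunkload, weights renormalized
  expect_equal(leafTrunkload(c(36.8, 22.8), c(0.3, 0.7), c(0.9, 0.1)), 36.8)

  expect_equal(barkTrunkload(c(sp = 34.2), c(sp = 1)), 34.2)
  expect_equal(barkTrunkload(c(a = 30, b = 20), c(a = 0.5, b = 0.5)), 25)
  expect_warning(out <- barkTrunkload(numeric(0), numeric(0)), "empty")
  expect_identical(out, 0)
  expect_error(barkTrunkload(c(a = 30), c(a = 0.8)), "sum to 1")
})

test_that("bark surfaces are constant over the annual cycle", {
  st <- simulateStudy(trunkloadParams(seed = 31), nUnits = 4, nDays = 40)
  s <- runDailyModel(st, smoothing = "off")
  for (g in elephantGroups()) {
    m <- getSurface(s, "bark", g)
    expect_equal(max(apply(m, 1, stats::var)), 0)
  }
})

test_that("the daily run is deterministic and matches brute-force per-cell recomputation", {
  p <- trunkloadParams(seed = 17)
  st <- simulateStudy(p, nUnits = 5, nDays = 30)
  models <- fitTrunkloadModels(st)
  s1 <- runDailyModel(st, models, smoothing = "off")
  s2 <- runDailyModel(st, models, smoothing = "off")
  for (nm in SummarizedExperiment::assayNames(s1))
    expect_identical(SummarizedExperiment::assay(s1, nm),
                     SummarizedExperiment::assay(s2, nm))

  units <- studyTable(st, "units")
  win <- studyTable(st, "window")
  window <- c(as.Date(win$start_date), as.Date(win$start_date) + win$n_days - 1)
  forbMass <- stats::setNames(studyTable(st, "forb_species")$mass_g,
                              studyTable(st, "forb_species")$species)
  annMass <- stats::setNames(studyTable(st, "annual_grass")$mass_g,
                             studyTable(st, "annual_grass")$species)
  leafUnit <- stats::setNames(studyTable(st, "woody_species")$leaf_unit_mass_g,
                              studyTable(st, "woody_species")$species)
  gr <- studyTable(st, "greenness")
  for (ui in seq_len(nrow(units))) {
    u <- units$unit[ui]
    sv <- studyTable(st, "height_surveys")
    daily <- interpolateDailyHeights(sv[sv$unit == u, ], window,
                                     smoothing = "off")
    gc <- studyTable(st, "grass_cover")
    gc <- gc[gc$unit == u, ]
    fc <- studyTable(st, "forb_cover")
    fc <- fc[fc$unit == u, ]
    wc <- studyTable(st, "woody_cover")
    for (d in sample(seq_len(30), 6)) {
      for (g in elephantGroups()) {
        if (units$herb_layer[ui] == "perennial") {
          B <- models@unitBasalArea[[g]][models@unitBasalArea$unit == u]
          a <- models@grass[[units$vegtype[ui]]]@coefficient
          expect_equal(getSurface(s1, "green_grass", g)[ui, d],
                       a * daily$h_green[d] * B, tolerance = 1e-12)
          expect_equal(getSurface(s1, "mixed_grass", g)[ui, d],
                       a * daily$h_mixed[d] * B, tolerance = 1e-12)
        } else {
          expect_equal(getSurface(s1, "green_grass", g)[ui, d],
                       sum(annMass[gc$species] * gc$cover), tolerance = 1e-12)
        }
        expect_equal(getSurface(s1, "forb", g)[ui, d],
                     sum(forbMass[fc$species] * fc$cover) * daily$h_forb_rel[d],
                     tolerance = 1e-12)
        wg <- wc[wc$unit == u & wc$group == g, ]
        green <- gr$green_fraction[match(paste(wg$species, d),
                                         paste(gr$species, gr$day))]
        sLeaf <- models@leaf[[g]]@slope * leafUnit[wg$species] +
          models@leaf[[g]]@intercept
        avail <- green > 0.25
        exp_leaf <- if (any(avail))
          sum(sLeaf[avail] * wg$rel_density[avail] / sum(wg$rel_density[avail]))
        else 0
        expect_equal(getSurface(s1, "leaf", g)[ui, d], unname(exp_leaf),
                     tolerance = 1e-12)
        bm <- models@barkMeans[models@barkMeans$group == g, ]
        w <- stats::setNames(bm$mean_bark_g, bm$species)[wg$species]
        w[is.na(w)] <- 0
        expect_equal(getSurface(s1, "bark", g)[ui, d],
                     sum(w * wg$rel_density), tolerance = 1e-12)
      }
    }
  }
})

test_that("a unit without height surveys is rejected by name", {
  st <- simulateStudy(trunkloadParams(seed = 23), nUnits = 3, nDays = 15)
  st@tables$height_surveys <-
    st@tables$height_surveys[st@tables$height_surveys$unit != 2, ]
  expect_error(runDailyModel(st, smoothing = "off"), "unit 2")
})

test_that("landscape summaries are area-weighted with unit-range extremes", {
  m <- matrix(c(10, 30, 10, 30), nrow = 2,
              dimnames = list(c("1", "2"), c("d1", "d2")))
  equalArea <- matrix(c(1L, 2L), 1)
  s <- makeSurfaces(list(green_grass_bull = m), raster = equalArea)
  out <- landscapeSummary(s)
  gg <- out[out$forage == "green_grass" & out$group == "bull", ]
  expect_equal(gg$mean, c(20, 20))
  expect_equal(gg$min, c(10, 10))
  expect_equal(gg$max, c(30, 30))

  skewed <- matrix(c(1L, 1L, 1L, 2L), 1)  # unit areas 3:1
  out2 <- landscapeSummary(s, raster = skewed)
  gg2 <- out2[out2$forage == "green_grass" & out2$group == "bull", ]
  expect_equal(gg2$mean, c(15, 15))

  same <- makeSurfaces(list(green_grass_bull = matrix(
    7, 2, 2, dimnames = list(c("1", "2"), c("d1", "d2")))), equalArea)
  out3 <- landscapeSummary(same)
  gg3 <- out3[out3$forage == "green_grass" & out3$group == "bull", ]
  expect_true(all(gg3$mean == 7 & gg3$min == 7 & gg3$max == 7))

  orphan <- matrix(c(1L, 3L), 1)
  expect_error(landscapeSummary(s, raster = orphan), "3")
})

test_that("daily min <= mean <= max on every simulated surface", {
  st <- simulateStudy(trunkloadParams(seed = 37), nUnits = 6, nDays = 30)
  out <- landscapeSummary(runDailyModel(st, smoothing = "off"))
  expect_true(all(out$min <= out$mean + 1e-12))
  expect_true(all(out$mean <= out$max + 1e-12))
})

test_that("bull surfaces dominate herd surfaces except forbs, which coincide", {
  st <- simulateStudy(trunkloadParams(seed = 41), nUnits = 8, nDays = 40)
  s <- runDailyModel(st, smoothing = "off")
  for (f in c("green_grass", "mixed_grass", "leaf", "bark")) {
    expect_true(all(getSurface(s, f, "bull") >= getSurface(s, f, "herd")),
                info = f)
  }
  expect_identical(getSurface(s, "forb", "bull"), getSurface(s, "forb", "herd"))
})
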