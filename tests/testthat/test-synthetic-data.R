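test_that("the generator is deterministic under a fixed seed", {
  a <- simulateStudy(trunkloadParams(seed = 1), nUnits = 4, nDays = 20)
  b <- simulateStudy(trunkloadParams(seed = 1), nUnits = 4, nDays = 20)
  expect_identical(a@tables, b@tables)
  expect_identical(studyRaster(a), studyRaster(b))
  c <- simulateStudy(trunkloadParams(seed = 2), nUnits = 4, nDays = 20)
  expect_false(identical(a@tables$tuft_samples, c@tables$tuft_samples))
})

test_that("zero-noise samples are exact evaluations of the ground truth", {
  p <- zeroNoiseParams(seed = 4)
  st <- simulateStudy(p, nUnits = 1, nDays = 20)
  tufts <- studyTable(st, "tuft_samples")
  a <- p@grassCoef[tufts$vegtype]
  expect_equal(tufts$mass_g,
               unname(a * tufts$height_cm *
                        basalAreaFromCircumference(tufts$circumference_cm)),
               tolerance = 1e-12)
  leaf <- studyTable(st, "leaf_observations")
  expect_equal(leaf$trunkload_g,
               unname(p@leafSlope[leaf$group] * leaf$leaf_unit_mass_g +
                        p@leafIntercept[leaf$group]),
               tolerance = 1e-12)
  bark <- studyTable(st, "branch_samples")
  bc <- p@barkCoef[match(bark$species, p@barkCoef$species), ]
  X <- bark$length_cm * bark$diameter_mm
  expect_equal(bark$bark_mass_g, bc$a * X + bc$b * X^2, tolerance = 1e-12)
})

test_that("community composition tables are normalized and reference declared ids", {
  st <- simulateStudy(trunkloadParams(seed = 7), nUnits = 9, nDays = 15)
  gc <- studyTable(st, "grass_cover")
  expect_true(all(abs(tapply(gc$cover, gc$unit, sum) - 1) < 1e-9))
  fc <- studyTable(st, "forb_cover")
  expect_true(all(abs(tapply(fc$cover, fc$unit, sum) - 1) < 1e-9))
  wc <- studyTable(st, "woody_cover")
  key <- paste(wc$unit, wc$group)
  expect_true(all(abs(tapply(wc$rel_density, key, sum) - 1) < 1e-9))
  units <- studyTable(st, "units")$unit
  expect_true(all(gc$unit %in% units))
  expect_true(all(studyTable(st, "height_surveys")$unit %in% units))
  ids <- studyRaster(st)
  expect_true(all(ids[ids > 0] %in% units))
})

test_that("denormalized covers are rejected with the table named", {
  st <- simulateStudy(trunkloadParams(seed = 7), nUnits = 3, nDays = 15)
  tabs <- st@tables
  tabs$forb_cover$cover[1] <- tabs$forb_cover$cover[1] + 0.1
  expect_error(trunkload:::.newStudy(tabs, studyRaster(st), trueParams(st)),
               "forb_cover")
  tabs2 <- st@tables
  tabs2$woody_cover$rel_density[1] <- 2
  expect_error(trunkload:::.newStudy(tabs2, studyRaster(st), trueParams(st)),
               "woody_cover")
})

test_that("all generated masses, heights, covers and densities are nonnegative", {
  st <- simulateStudy(trunkloadParams(seed = 11), nUnits = 6, nDays = 25)
  expect_true(all(studyTable(st, "tuft_samples")$mass_g >= 0))
  hs <- studyTable(st, "height_surveys")
  expect_true(all(hs$h_green_cm >= 0) && all(hs$h_dry_cm >= 0) &&
                all(hs$h_forb_cm >= 0))
  expect_true(all(studyTable(st, "grass_cover")$cover >= 0))
  expect_true(all(studyTable(st, "woody_cover")$rel_density >= 0))
  expect_true(all(studyTable(st, "branch_samples")$bark_mass_g >= 0))
  gr <- studyTable(st, "greenness")
  expect_true(all(gr$green_fraction >= 0 & gr$green_fraction <= 1))
})

test_that("greenness trajectories cross the 25% threshold at the senescence day", {
  p <- trunkloadParams(seed = 1)
  st <- simulateStudy(p, nUnits = 1, nDays = 364)
  gr <- studyTable(st, "greenness")
  woody <- p@woodySpecies
  # species that fully senesce before the next flush; the remainder keep a
  # green canopy above the threshold throughout the window
  deciduous <- woody[woody$senescence_day + 0.25 * woody$ramp_days <
                       woody$regreen_day, ]
  expect_gt(nrow(deciduous), 0)
  for (i in seq_len(nrow(deciduous))) {
    ws <- deciduous[i, ]
    g <- gr[gr$species == ws$species, ]
    expect_equal(g$green_fraction[g$day == ws$senescence_day], 0.25,
                 tolerance = 1e-9)
    # available strictly before the senescence day, not on it
    expect_gt(g$green_fraction[g$day == ws$senescence_day - 1], 0.25)
  }
  # persistent species never drop below the availability threshold
  persistent <- setdiff(woody$species, deciduous$species)
  expect_gt(length(persistent), 0)
  expect_true(all(gr$green_fraction[gr$species %in% persistent] > 0.25))
})

test_that("tuft-selection samples respect the group ceilings", {
  p <- trunkloadParams(seed = 5)
  bull <- tuftSelectionSample(p, "bull", 4000)
  herd <- tuftSelectionSample(p, "herd", 4000)
  comm <- tuftSelectionSample(p, "community", 4000)
  expect_gt(mean(bull), mean(herd))       # ceiling ordering by construction
  expect_gt(mean(comm), mean(bull))
  # law of large numbers: sample mean approaches the configured ceiling
  big <- tuftSelectionSample(p, "bull", 10000)
  expect_lt(abs(mean(big) - p@ceilings[["bull"]]) / p@ceilings[["bull"]], 0.02)
  expect_identical(tuftSelectionSample(p, "herd", 100),
                   tuftSelectionSample(p, "herd", 100))
  expect_error(tuftSelectionSample(p, "calf", 10), "unknown group")
})
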