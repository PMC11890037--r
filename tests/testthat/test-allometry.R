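test_that("basal area follows the circular-base closed form", {
  expect_identical(basalAreaFromCircumference(0), 0)
  expect_equal(basalAreaFromCircumference(2 * pi), pi, tolerance = 1e-12)
  expect_equal(basalAreaFromCircumference(35.5), 35.5^2 / (4 * pi))
  expect_equal(round(basalAreaFromCircumference(35.5), 2), 100.29)
  expect_error(basalAreaFromCircumference(-1), ">= 0")
})

test_that("the grass coefficient equals the closed-form origin-regression slope", {
  s <- data.frame(vegtype = "21", height_cm = 10, basal_area_cm2 = 2,
                  mass_g = 1)
  expect_equal(unname(coef(fitGrassMassCoefficient(s)[["21"]])), 0.05)

  set.seed(42)
  for (r in 1:20) {
    n <- sample(3:40, 1)
    d <- data.frame(vegtype = "v", height_cm = runif(n, 1, 100),
                    basal_area_cm2 = runif(n, 1, 300),
                    mass_g = runif(n, 1, 500))
    x <- d$height_cm * d$basal_area_cm2
    oracle <- sum(d$mass_g * x) / sum(x^2)
    fit <- fitGrassMassCoefficient(d)[["v"]]
    expect_equal(unname(coef(fit)), oracle, tolerance = 1e-10)
  }
  expect_error(
    fitGrassMassCoefficient(data.frame(vegtype = "v", height_cm = 0,
                                       basal_area_cm2 = 0, mass_g = 1)),
    "zero")
})

test_that("noisy tuft samples recover the generating coefficient within 5%", {
  # n = 125, 5% CV multiplicative noise
  set.seed(99)
  a <- 0.050541
  H <- runif(125, 5, 100); B <- runif(125, 5, 300)
  sdl <- sqrt(log(1 + 0.05^2))
  d <- data.frame(vegtype = "27", height_cm = H, basal_area_cm2 = B,
                  mass_g = a * H * B * rlnorm(125, -sdl^2 / 2, sdl))
  fit <- fitGrassMassCoefficient(d)[["27"]]
  expect_lt(abs(coef(fit)[["a"]] - a) / a, 0.05)
  expect_gt(fit@adjR2, 0.9)
})

test_that("tuft ceilings are group means with rank-based contrasts", {
  set.seed(8)
  p <- trunkloadParams(seed = 8)
  sel <- list(bull = tuftSelectionSample(p, "bull", 100),
              herd = tuftSelectionSample(p, "herd", 100))
  comm <- tuftSelectionSample(p, "community", 100)
  fit <- estimateTuftCeiling(sel, comm)
  expect_equal(fit$ceilings$bull@ceiling, mean(sel$bull))
  # configured means 35.5 / 22.3 recovered within sampling error (4 SEs)
  for (g in c("bull", "herd")) {
    se <- stats::sd(sel[[g]]) / sqrt(100)
    expect_lt(abs(fit$ceilings[[g]]@ceiling - p@ceilings[[g]]), 4 * se)
  }
  expect_s3_class(fit$test$dunn, "data.frame")
  expect_equal(nrow(fit$test$dunn), 3)  # all pairwise contrasts

  # identical samples: contrasts non-significant
  x <- rep(c(10, 20, 30, 40), 10)
  same <- estimateTuftCeiling(list(bull = x, herd = x), x)
  expect_true(all(same$test$dunn$p > 0.9))

  # disjoint supports: omnibus p below any conventional threshold
  apart <- estimateTuftCeiling(list(bull = rnorm(50, 100, 1),
                                    herd = rnorm(50, 50, 1)),
                               rnorm(50, 150, 1))
  expect_lt(apart$test$kruskal$p.value, 1e-6)
  expect_error(estimateTuftCeiling(list(bull = numeric(0)), comm), "empty")
})

test_that("the selection ceiling excludes over-ceiling tufts and never increases the mean", {
  expect_equal(cappedMeanBasalArea(c(10, 20, 100), ceiling = 25),
               mean(basalAreaFromCircumference(c(10, 20))))
  circ <- c(5, 10, 15)
  expect_equal(cappedMeanBasalArea(circ, ceiling = 100),
               mean(basalAreaFromCircumference(circ)))  # no-op ceiling
  expect_warning(out <- cappedMeanBasalArea(c(30, 40), ceiling = 1),
                 "no tufts")
  expect_identical(out, 0)
  set.seed(13)
  for (r in 1:20) {
    circ <- rlnorm(50, 3, 0.5)
    ceiling <- runif(1, 5, 60)
    capped <- suppressWarnings(cappedMeanBasalArea(circ, ceiling))
    expect_lte(capped, mean(basalAreaFromCircumference(circ)))
  }
})

test_that("leaf-trunkload regressions are fitted with intercepts per group", {
  # exact recovery from noise-free observations
  obs <- data.frame(
    group = rep(c("bull", "herd"), each = 4),
    leaf_unit_mass_g = rep(c(0.1, 0.5, 1, 2), 2))
  obs$trunkload_g <- ifelse(obs$group == "bull",
                            72.902 * obs$leaf_unit_mass_g + 14.196,
                            67.669 * obs$leaf_unit_mass_g + 9.001)
  fit <- fitLeafTrunkloadModel(obs)
  expect_equal(unname(coef(fit$models$bull)), c(14.196, 72.902),
               tolerance = 1e-9)
  expect_equal(unname(coef(fit$models$herd)), c(9.001, 67.669),
               tolerance = 1e-9)
  expect_equal(predict(fit$models$bull, 0), 14.196, tolerance = 1e-9)
  expect_equal(predict(fit$models$herd, 1), 76.670, tolerance = 1e-9)
  expect_s3_class(fit$ancova, "data.frame")
  expect_true(fit$ancova$p < 0.05)  # separated parallel-ish lines
  expect_error(
    fitLeafTrunkloadModel(data.frame(group = "bull", leaf_unit_mass_g = 1,
                                     trunkload_g = 80)),
    "at least 3")
})

test_that("bark-mass models are zero-intercept quadratics in length x diameter", {
  m <- methods::new("BarkMassModel", species = "Colophospermum mopane",
                    a = 0.164715, b = 0.001772, adjR2 = 0.94, n = 12L)
  expect_equal(round(predict(m, 100), 2), 34.19)
  expect_identical(predict(m, 0), 0)

  # a quadratic through its own points is recovered exactly
  L <- c(10, 20, 40, 60, 35); D <- c(3, 5, 4, 6, 2)
  X <- L * D
  s <- data.frame(species = "sp", length_cm = L, diameter_mm = D,
                  bark_mass_g = 0.3 * X + 0.0005 * X^2)
  fit <- fitBarkMassModel(s)[["sp"]]
  expect_equal(unname(coef(fit)), c(0.3, 0.0005), tolerance = 1e-9)
  expect_error(fitBarkMassModel(s[1:2, ]), "at least 3")
})

test_that("mean bark mass sums fork predictions per branch", {
  models <- fitBarkMassModel(data.frame(
    species = "sp", length_cm = c(10, 20, 40), diameter_mm = c(3, 5, 4),
    bark_mass_g = 0.2 * c(30, 100, 160) + 0.001 * c(30, 100, 160)^2))
  one <- data.frame(group = "bull", species = "sp", branch_id = "b1",
                    fork_length_cm = 30, fork_diameter_mm = 4)
  r1 <- meanBarkMass(one, models)
  expect_equal(r1$means$mean_bark_g, predict(models$sp, 120), tolerance = 1e-9)
  two <- rbind(one, one)  # two identical forks: exactly double
  two$branch_id <- "b2"
  r2 <- meanBarkMass(rbind(one, two), models)
  pb <- r2$perBranch
  expect_equal(pb$bark_g[pb$branch_id == "b2"],
               2 * pb$bark_g[pb$branch_id == "b1"], tolerance = 1e-12)
  expect_error(meanBarkMass(transform(one, species = "other"), models),
               "other")
})

test_that("bulls stripping larger branches yield larger bark means for every species", {
  st <- simulateStudy(trunkloadParams(seed = 21), nUnits = 1, nDays = 10)
  models <- fitBarkMassModel(studyTable(st, "branch_samples"))
  fit <- meanBarkMass(studyTable(st, "debarked_branches"), models)
  m <- fit$means
  for (sp in unique(m$species)) {
    expect_gt(m$mean_bark_g[m$group == "bull" & m$species == sp],
              m$mean_bark_g[m$group == "herd" & m$species == sp])
  }
  expect_s3_class(fit$test, "data.frame")
  expect_lt(fit$test$p[fit$test$effect == "group"], 0.001)
})

test_that("zero-noise generation round-trips every coefficient through the fits", {
  p <- zeroNoiseParams(seed = 2)
  st <- simulateStudy(p, nUnits = 4, nDays = 20)
  m <- fitTrunkloadModels(st)
  for (v in names(p@grassCoef))
    expect_lt(abs(m@grass[[v]]@coefficient - p@grassCoef[[v]]) /
                p@grassCoef[[v]], 1e-8)
  for (g in elephantGroups()) {
    expect_lt(abs(m@leaf[[g]]@slope - p@leafSlope[[g]]) / p@leafSlope[[g]],
              1e-8)
    expect_lt(abs(m@leaf[[g]]@intercept - p@leafIntercept[[g]]) /
                p@leafIntercept[[g]], 1e-8)
  }
  for (i in seq_len(nrow(p@barkCoef))) {
    fit <- m@bark[[p@barkCoef$species[i]]]
    expect_lt(abs(fit@a - p@barkCoef$a[i]) / p@barkCoef$a[i], 1e-8)
    expect_lt(abs(fit@b - p@barkCoef$b[i]) / p@barkCoef$b[i], 1e-8)
  }
})
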