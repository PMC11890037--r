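# Seasonal height-curve machinery. Grass height rises through the wet season
# to a peak, declines exponentially through the dry season to a trough
# (minFrac of peak), then rises linearly once the next rains start. The curve
# is periodic with a 364-day cycle so surveys may extend beyond the model
# window on both sides.
.heightShape <- function(day, peakDay, declineRate, minFrac, riseStartDay) {
  phase <- (day - peakDay) %% 364
  riseAt <- (riseStartDay - peakDay) %% 364
  v0 <- max(minFrac, exp(-declineRate * riseAt))
  ifelse(phase <= riseAt,
         pmax(minFrac, exp(-declineRate * phase)),
         v0 + (1 - v0) * (phase - riseAt) / (364 - riseAt))
}

.unitGreenHeight <- function(units, u, day) {
  i <- match(u, units$unit)
  units$peak_height_cm[i] *
    .heightShape(day, units$peak_day[i], units$decline_rate[i],
                 units$min_frac[i], units$rise_start_day[i])
}

.unitDryHeight <- function(units, u, day, dryBase, dryAmp) {
  i <- match(u, units$unit)
  sh <- .heightShape(day, units$peak_day[i], units$decline_rate[i],
                     units$min_frac[i], units$rise_start_day[i])
  units$peak_height_cm[i] * (dryBase + dryAmp * (1 - sh))
}

.unitForbHeight <- function(units, u, day, forbPeakFrac) {
  i <- match(u, units$unit)
  sh <- .heightShape(day, units$peak_day[i], 1.3 * units$decline_rate[i],
                     units$min_frac[i] * 0.8, units$rise_start_day[i])
  forbPeakFrac * units$peak_height_cm[i] * sh
}

# Canopy greenness as a ramp: fully green until 0.75*ramp before the
# senescence day, linear decline crossing exactly 0.25 on the senescence day,
# bare until the regreen day, then a 30-day ramp back to fully green.
.greennessFraction <- function(day, senescenceDay, regreenDay, rampDays) {
  down0 <- senescenceDay - 0.75 * rampDays
  down <- pmin(pmax((senescenceDay + 0.25 * rampDays - day) / rampDays, 0), 1)
  up <- pmin(pmax((day - regreenDay) / 30, 0), 1)
  ifelse(day <= down0, 1, pmax(down, up))
}

.dirichletCover <- function(k, shape = 2) {
  g <- stats::rgamma(k, shape = shape)
  g / sum(g)
}

#' Sample tuft circumferences selected by a group or the community
#'
#' Draws circumferences from the community lognormal law of the ceiling
#' target species. For \code{group = "bull"} or \code{"herd"} the community
#' draws are thinned by scaling so that the sample mean approximates the
#' group's selection ceiling (the shape and coefficient of variation of the
#' community law are preserved); \code{group = "community"} returns raw
#' community draws.
#'
#' @param params a \code{\linkS4class{TrunkloadParams}}.
#' @param group \code{"bull"}, \code{"herd"} or \code{"community"}.
#' @param n sample size, >= 1.
#' @param seed optional seed; defaults to a seed derived from the params
#'   master seed and the group.
#' @return numeric vector of circumferences (cm).
#' @export
tuftSelectionSample <- function(params, group, n, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (!group %in% c("bull", "herd", "community"))
    stop("unknown group '", group, "'; expected bull, herd or community")
  k <- match(group, c("bull", "herd", "community"))
  set.seed(if (is.null(seed)) .tableSeed(params@seed, 900 + k) else seed)
  draws <- .rlnormMeanCV(n, params@communityCircMean, params@communityCircCV)
  if (group == "community") return(draws)
  draws * params@ceilings[[group]] / params@communityCircMean
}

# Cover/density tables must arrive normalized; problems are reported by
# table name rather than silently renormalized.
.validateStudyTables <- function(tables, tol = 1e-9) {
  msg <- character()
  sumsToOne <- function(df, by, col, name) {
    s <- tapply(df[[col]], df[[by]], sum)
    bad <- names(s)[abs(s - 1) > tol]
    if (length(bad))
      paste0("table '", name, "': ", col, " does not sum to 1 for ", by,
             " ", paste(bad, collapse = ", "))
    else character()
  }
  g <- tables$grass_cover
  msg <- c(msg, sumsToOne(g, "unit", "cover", "grass_cover"))
  msg <- c(msg, sumsToOne(tables$forb_cover, "unit", "cover", "forb_cover"))
  w <- tables$woody_cover
  w$key <- paste(w$unit, w$group)
  msg <- c(msg, sumsToOne(w, "key", "rel_density", "woody_cover"))
  units <- tables$units$unit
  for (nm in c("grass_cover", "forb_cover", "woody_cover", "height_surveys")) {
    bad <- setdiff(unique(tables[[nm]]$unit), units)
    if (length(bad))
      msg <- c(msg, paste0("table '", nm, "': undeclared unit id ",
                           paste(bad, collapse = ", ")))
  }
  badSp <- setdiff(unique(tables$woody_cover$species),
                   tables$woody_species$species)
  if (length(badSp))
    msg <- c(msg, paste0("table 'woody_cover': undeclared species ",
                         paste(badSp, collapse = ", ")))
  msg
}

.newStudy <- function(tables, raster, params) {
  msg <- .validateStudyTables(tables)
  if (length(msg)) stop(paste(msg, collapse = "\n"))
  new("SyntheticStudy", tables = tables, raster = raster, params = params)
}

#' Generate a complete synthetic field study
#'
#' Builds a landscape of \code{nUnits} units (each assigned a vegetation
#' type, a herbaceous-layer kind and a seasonal height curve), species
#' communities per unit, and all the field-sample tables the fitting
#' pipeline consumes: tuft samples (mass = a H B times multiplicative
#' lognormal noise), community tuft-circumference samples, tuft-selection
#' samples per group, quarterly quadrat height surveys (noisy evaluations
#' of the unit's seasonal curve, truncated at 0), leaf-trunkload
#' observations (group linear law plus noise), branch bark samples
#' (quadratic law plus noise), debarked-branch records and daily canopy
#' greenness trajectories. With all noise scales zero, every sampled mass
#' equals its model value exactly.
#'
#' @param params a \code{\linkS4class{TrunkloadParams}}; all randomness
#'   derives from \code{params@seed} through a per-table seed sequence.
#' @param nUnits number of landscape units, >= 1.
#' @param nDays length of the model window in days, >= 2.
#' @param startDate first day of the model window.
#' @param nTuftsPerSpecies tuft samples per (vegetation type, species).
#' @param nCircPerSpecies community circumference samples per grass species.
#' @param nSelection tuft-selection sample size per group.
#' @param nLeafObs named numeric, leaf-trunkload observations per group.
#' @param nBranchSamples branch bark samples per species.
#' @param branchLengthRange,branchDiameterRange uniform sampling ranges for
#'   branch length (cm) and mean diameter (mm) of the bark calibration
#'   branches.
#' @param annualFraction fraction of units whose herbaceous layer is
#'   annual grass.
#' @return a \code{\linkS4class{SyntheticStudy}}.
#' @examples
#' study <- simulateStudy(trunkloadParams(seed = 1), nUnits = 5, nDays = 30)
#' study
#' @export
simulateStudy <- function(params, nUnits = 65, nDays = 364,
                          startDate = as.Date("2002-03-12"),
                          nTuftsPerSpecies = 25, nCircPerSpecies = 100,
                          nSelection = 100,
                          nLeafObs = c(bull = 17, herd = 18),
                          nBranchSamples = 12,
                          branchLengthRange = c(2, 60),
                          branchDiameterRange = c(1, 6),
                          annualFraction = 0.2) {
  stopifnot(nUnits >= 1, nDays >= 2)
  validObject(params)
  ph <- params@phenology
  noise <- params@noise
  vegtypes <- names(params@grassCoef)

  # -- landscape units and their seasonal curves ------------------------------
  set.seed(.tableSeed(params@seed, 1))
  herb <- rep("perennial", nUnits)
  if (annualFraction > 0 && nUnits > 1)
    herb[seq(1, nUnits, length.out = max(1, round(annualFraction * nUnits)))] <-
      "annual"
  units <- data.frame(
    unit = seq_len(nUnits),
    vegtype = rep(vegtypes, length.out = nUnits),
    herb_layer = herb,
    peak_height_cm = runif(nUnits, ph$peakHeightRange[1], ph$peakHeightRange[2]),
    peak_day = runif(nUnits, ph$peakDayRange[1], ph$peakDayRange[2]),
    min_frac = runif(nUnits, ph$minFracRange[1], ph$minFracRange[2]),
    rise_start_day = rep(ph$riseStartDay, nUnits))
  riseAt <- (units$rise_start_day - units$peak_day) %% 364
  units$decline_rate <- -log(units$min_frac) / (0.6 * riseAt)

  # raster: each unit occupies a variable number of grid cells
  cells <- sample(3:10, nUnits, replace = TRUE)
  ids <- rep(units$unit, cells)
  side <- ceiling(sqrt(length(ids)))
  grid <- integer(side * side)
  grid[seq_along(ids)] <- ids
  raster <- matrix(grid, nrow = side, byrow = TRUE)

  # -- community composition --------------------------------------------------
  set.seed(.tableSeed(params@seed, 2))
  # dominant perennial species per vegetation type (3 each, cycling)
  nsp <- nrow(params@grassSpecies)
  domIdx <- lapply(seq_along(vegtypes), function(v)
    sort(unique((((v - 1) * 2) + 0:2) %% nsp + 1)))
  names(domIdx) <- vegtypes
  grassCover <- do.call(rbind, lapply(seq_len(nUnits), function(u) {
    if (units$herb_layer[u] == "perennial") {
      sp <- params@grassSpecies$species[domIdx[[units$vegtype[u]]]]
    } else {
      sp <- params@annualGrass$species
    }
    data.frame(unit = u, species = sp, cover = .dirichletCover(length(sp)))
  }))

  set.seed(.tableSeed(params@seed, 3))
  forbCover <- do.call(rbind, lapply(seq_len(nUnits), function(u) {
    k <- sample(5:10, 1)
    sp <- sample(params@forbSpecies$species, k)
    data.frame(unit = u, species = sp, cover = .dirichletCover(k))
  }))

  set.seed(.tableSeed(params@seed, 4))
  woodyCover <- do.call(rbind, lapply(seq_len(nUnits), function(u) {
    k <- sample(4:min(8, nrow(params@woodySpecies)), 1)
    sp <- sample(params@woodySpecies$species, k)
    dens <- stats::rgamma(k, 2)                    # abundance per species
    # height-class profile is drawn at unit level and shared across species,
    # so the groups' relative accessible densities coincide and group
    # differences in leaf/bark surfaces stem from the harvest models alone
    f4 <- runif(1, 0.3, 0.9)                       # canopy below 4 m
    f6 <- f4 + runif(1, 0.05, 0.95) * (1 - f4)     # canopy below 6 m
    rbind(
      data.frame(unit = u, species = sp, group = "bull",
                 rel_density = dens * f6 / sum(dens * f6)),
      data.frame(unit = u, species = sp, group = "herd",
                 rel_density = dens * f4 / sum(dens * f4)))
  }))

  # daily canopy greenness per woody species
  greenness <- do.call(rbind, lapply(seq_len(nrow(params@woodySpecies)),
                                     function(i) {
    ws <- params@woodySpecies[i, ]
    data.frame(species = ws$species, day = seq_len(nDays),
               green_fraction = .greennessFraction(
                 seq_len(nDays), ws$senescence_day, ws$regreen_day,
                 ws$ramp_days))
  }))

  # -- grass tuft samples (allometry calibration) -----------------------------
  set.seed(.tableSeed(params@seed, 5))
  tuftSamples <- do.call(rbind, lapply(vegtypes, function(v) {
    sp <- params@grassSpecies[domIdx[[v]], ]
    do.call(rbind, lapply(seq_len(nrow(sp)), function(i) {
      H <- runif(nTuftsPerSpecies, 5, ph$peakHeightRange[2])
      C <- .rlnormMeanCV(nTuftsPerSpecies, sp$mean_circumference_cm[i],
                         sp$cv_circumference[i])
      B <- basalAreaFromCircumference(C)
      data.frame(species = sp$species[i], vegtype = v, height_cm = H,
                 circumference_cm = C,
                 mass_g = params@grassCoef[[v]] * H * B *
                   .noiseFactor(nTuftsPerSpecies, noise[["tuft_mass_cv"]]))
    }))
  }))

  # community circumference samples per perennial species (for mean basal area)
  set.seed(.tableSeed(params@seed, 6))
  tuftCirc <- do.call(rbind, lapply(seq_len(nsp), function(i) {
    sp <- params@grassSpecies[i, ]
    data.frame(species = sp$species,
               circumference_cm = .rlnormMeanCV(
                 nCircPerSpecies, sp$mean_circumference_cm,
                 sp$cv_circumference))
  }))

  # tuft-selection samples (ceiling estimation)
  tuftSelection <- do.call(rbind, lapply(c("bull", "herd", "community"),
                                         function(g) {
    data.frame(group = g,
               circumference_cm = tuftSelectionSample(params, g, nSelection))
  }))

  # -- quarterly height surveys ----------------------------------------------
  set.seed(.tableSeed(params@seed, 7))
  surveyDays <- seq(1 - ph$surveyPadDays, nDays + ph$surveyPadDays,
                    by = ph$surveyIntervalDays)
  nq <- ph$pointsPerSurvey * ph$quadratsPerPoint
  sdH <- noise[["survey_height_sd"]]
  heightSurveys <- do.call(rbind, lapply(seq_len(nUnits), function(u) {
    do.call(rbind, lapply(surveyDays, function(d) {
      data.frame(
        unit = u, date = startDate + (d - 1),
        point = rep(seq_len(ph$pointsPerSurvey), each = ph$quadratsPerPoint),
        quadrat = rep(seq_len(ph$quadratsPerPoint), ph$pointsPerSurvey),
        h_green_cm = pmax(0, .unitGreenHeight(units, u, d) + rnorm(nq, 0, sdH)),
        h_dry_cm = pmax(0, .unitDryHeight(units, u, d, ph$dryBase, ph$dryAmp) +
                          rnorm(nq, 0, sdH)),
        h_forb_cm = pmax(0, .unitForbHeight(units, u, d, ph$forbPeakFrac) +
                           rnorm(nq, 0, sdH)))
    }))
  }))

  # -- leaf-trunkload observations -------------------------------------------
  set.seed(.tableSeed(params@seed, 8))
  leafObs <- do.call(rbind, lapply(c("bull", "herd"), function(g) {
    n <- nLeafObs[[g]]
    x <- sample(params@woodySpecies$leaf_unit_mass_g, n, replace = TRUE) *
      runif(n, 0.8, 1.2)
    data.frame(group = g, leaf_unit_mass_g = x,
               trunkload_g = (params@leafSlope[[g]] * x +
                                params@leafIntercept[[g]]) *
                 .noiseFactor(n, noise[["leaf_obs_cv"]]))
  }))

  # -- branch bark samples (quadratic bark model calibration) -----------------
  set.seed(.tableSeed(params@seed, 9))
  branchSamples <- do.call(rbind, lapply(seq_len(nrow(params@barkCoef)),
                                         function(i) {
    bc <- params@barkCoef[i, ]
    n <- nBranchSamples
    L <- runif(n, branchLengthRange[1], branchLengthRange[2])
    D <- runif(n, branchDiameterRange[1], branchDiameterRange[2])
    X <- L * D
    data.frame(species = bc$species, length_cm = L, diameter_mm = D,
               bark_mass_g = (bc$a * X + bc$b * X^2) *
                 .noiseFactor(n, noise[["bark_mass_cv"]]))
  }))

  # -- debarked-branch records (group-specific branch size selection) ---------
  set.seed(.tableSeed(params@seed, 10))
  db <- params@debarking
  debarked <- do.call(rbind, lapply(c("bull", "herd"), function(g) {
    do.call(rbind, lapply(params@barkCoef$species, function(sp) {
      n <- db$nBranches
      LD <- .rlnormMeanCV(n, db$meanLD[[g]], db$cvLD)
      forked <- runif(n) < db$forkProb
      do.call(rbind, lapply(seq_len(n), function(b) {
        parts <- if (forked[b]) {
          w <- runif(1, 0.3, 0.7); c(w, 1 - w) * LD[b]
        } else LD[b]
        D <- runif(length(parts), 3, 8)
        data.frame(group = g, species = sp, branch_id = paste0(g, "_", sp,
                                                               "_", b),
                   fork_length_cm = parts / D, fork_diameter_mm = D)
      }))
    }))
  }))

  # -- observed species attribute tables --------------------------------------
  set.seed(.tableSeed(params@seed, 11))
  annualGrass <- transform(params@annualGrass,
                           mass_g = mass_g * .noiseFactor(
                             nrow(params@annualGrass),
                             noise[["tuft_mass_cv"]] / sqrt(25)))
  forbSpecies <- transform(params@forbSpecies,
                           mass_g = mass_g * .noiseFactor(
                             nrow(params@forbSpecies),
                             noise[["tuft_mass_cv"]] / sqrt(5)))
  woodySpecies <- params@woodySpecies[, c("species", "leaf_unit_mass_g")]

  tables <- list(
    window = data.frame(start_date = startDate, n_days = as.integer(nDays)),
    units = units, grass_cover = grassCover, annual_grass = annualGrass,
    forb_species = forbSpecies, forb_cover = forbCover,
    woody_species = woodySpecies, woody_cover = woodyCover,
    greenness = greenness, tuft_samples = tuftSamples,
    tuft_circumference = tuftCirc, tuft_selection = tuftSelection,
    height_surveys = heightSurveys, leaf_observations = leafObs,
    branch_samples = branchSamples, debarked_branches = debarked)
  tables <- lapply(tables, function(d) { rownames(d) <- NULL; d })
  .newStudy(tables, raster, params)
}
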