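#' Fit every trunkload model from a study's field tables
#'
#' Runs the full model-parameterisation stage: the zero-intercept grass
#' tuft-mass coefficient per vegetation type, the tuft-selection ceilings
#' with their rank-based group contrasts, the per-unit cover-weighted
#' ceiling-capped mean tuft basal area for each group, the group-specific
#' leaf-trunkload regressions with the ANCOVA group test, the quadratic
#' bark-mass models and the group x species mean bark mass per debarked
#' branch with its aligned-rank ANOVA.
#'
#' @param study a \code{\linkS4class{SyntheticStudy}} (or any object with
#'   the same tables read from disk via \code{\link{readStudy}}).
#' @param ceilingOverride optional named numeric (\code{bull}, \code{herd})
#'   replacing the estimated tuft-selection ceilings (cm).
#' @return a \code{\linkS4class{TrunkloadModels}}.
#' @export
fitTrunkloadModels <- function(study, ceilingOverride = NULL) {
  tab <- study@tables
  grass <- fitGrassMassCoefficient(tab$tuft_samples)

  sel <- tab$tuft_selection
  ceilingFit <- estimateTuftCeiling(
    selected = list(
      bull = sel$circumference_cm[sel$group == "bull"],
      herd = sel$circumference_cm[sel$group == "herd"]),
    community = sel$circumference_cm[sel$group == "community"])
  ceilings <- ceilingFit$ceilings
  for (g in names(ceilingOverride))
    ceilings[[.checkGroup(g)]]@ceiling <- ceilingOverride[[g]]

  # per-species ceiling-capped mean basal area, then cover-weighted per unit
  circ <- tab$tuft_circumference
  speciesB <- lapply(elephantGroups(), function(g) {
    vapply(split(circ$circumference_cm, circ$species), cappedMeanBasalArea,
           numeric(1), ceiling = ceilings[[g]]@ceiling)
  })
  names(speciesB) <- elephantGroups()
  units <- tab$units
  unitB <- do.call(rbind, lapply(units$unit, function(u) {
    if (units$herb_layer[units$unit == u] != "perennial")
      return(data.frame(unit = u, bull = NA_real_, herd = NA_real_))
    gc <- tab$grass_cover[tab$grass_cover$unit == u, ]
    data.frame(
      unit = u,
      bull = sum(speciesB$bull[gc$species] * gc$cover),
      herd = sum(speciesB$herd[gc$species] * gc$cover))
  }))

  leafFit <- fitLeafTrunkloadModel(tab$leaf_observations)
  bark <- fitBarkMassModel(tab$branch_samples)
  barkFit <- meanBarkMass(tab$debarked_branches, bark)

  new("TrunkloadModels",
      grass = grass, ceilings = ceilings, leaf = leafFit$models,
      bark = bark, barkMeans = barkFit$means, unitBasalArea = unitB,
      reports = list(tuftSelection = ceilingFit$test,
                     leafAncova = leafFit$ancova,
                     barkArtAnova = barkFit$test))
}

#' Unit-level trunkload operations
#'
#' The four forage-type building blocks evaluated by
#' \code{\link{runDailyModel}}; exposed so single cells can be computed and
#' checked directly.
#'
#' \code{grassTrunkload} is the perennial grass model
#' \eqn{S = a H B}: coefficient times daily grass height (green or mixed)
#' times the group's capped cover-weighted mean tuft basal area.
#' \code{annualGrassTrunkload} is the annual-unit alternative, the
#' cover-weighted mean whole-plant mass (constant over the season and
#' identical for the two variants and groups).
#' \code{forbTrunkload} is the cover-weighted end-of-season forb mass
#' scaled by the relative forb height of the day (identical for both
#' groups). \code{leafTrunkload} averages per-species leaf trunkloads over
#' the species available that day (canopy more than 25 percent green),
#' weighted by the group's relative accessible density renormalised over
#' the available species; no available species yields 0.
#' \code{barkTrunkload} is the relative-density-weighted mean of
#' group-specific mean bark masses, constant over the annual cycle;
#' species without a bark record contribute zero mass.
#'
#' @param model a \code{GrassMassModel}.
#' @param height daily grass height (cm).
#' @param basalArea group mean tuft basal area (cm^2).
#' @param masses species mean dry masses (g); for \code{barkTrunkload} a
#'   named vector of mean bark mass per species.
#' @param covers,weights species proportional covers / relative densities;
#'   must sum to 1.
#' @param forbHeightRel relative forb height in [0, 1].
#' @param trunkloads per-species predicted leaf trunkload masses (g).
#' @param greenFraction per-species fraction of canopy that is green.
#' @param threshold greenness availability threshold (default 0.25).
#' @return trunkload mass (g).
#' @examples
#' annualGrassTrunkload(c(10, 30), c(0.5, 0.5))   # 20
#' forbTrunkload(c(100, 20), c(0.25, 0.75), 0.5)  # 20
#' leafTrunkload(c(36.8, 22.8), c(0.5, 0.5), c(0.9, 0.8))  # 29.8
#' @name trunkload-operations
NULL

#' @rdname trunkload-operations
#' @export
grassTrunkload <- function(model, height, basalArea) {
  if (!is(model, "GrassMassModel")) stop("missing or invalid grass model")
  predict(model, height, basalArea)
}

#' @rdname trunkload-operations
#' @export
annualGrassTrunkload <- function(masses, covers) {
  if (abs(sum(covers) - 1) > 1e-9) stop("annual grass covers must sum to 1")
  sum(masses * covers)
}

#' @rdname trunkload-operations
#' @export
forbTrunkload <- function(masses, covers, forbHeightRel) {
  if (abs(sum(covers) - 1) > 1e-9) stop("forb covers must sum to 1")
  sum(masses * covers) * forbHeightRel
}

#' @rdname trunkload-operations
#' @export
leafTrunkload <- function(trunkloads, weights, greenFraction,
                          threshold = 0.25) {
  if (abs(sum(weights) - 1) > 1e-9)
    stop("relative woody densities must sum to 1")
  avail <- greenFraction > threshold
  if (!any(avail)) return(0)
  w <- weights[avail] / sum(weights[avail])
  sum(trunkloads[avail] * w)
}

#' @rdname trunkload-operations
#' @export
barkTrunkload <- function(masses, weights) {
  if (!length(weights)) {
    warning("empty woody layer; bark trunkload set to 0")
    return(0)
  }
  if (abs(sum(weights) - 1) > 1e-9)
    stop("relative woody densities must sum to 1")
  m <- masses[names(weights)]
  m[is.na(m)] <- 0  # species never recorded as a bark source
  sum(m * weights)
}

# named vector of mean bark mass for one group
.barkMeanVector <- function(barkMeans, group) {
  bm <- barkMeans[barkMeans$group == group, ]
  setNames(bm$mean_bark_g, bm$species)
}

#' Run the daily trunkload model over the landscape
#'
#' Evaluates every forage-type model for every landscape unit and day of
#' the model window, for adult bulls and members of breeding herds,
#' producing ten unit x day surfaces (5 forage types x 2 groups).
#' Quarterly height surveys are first interpolated to daily series per
#' unit; woody-species availability follows the daily canopy greenness
#' (threshold 25 percent green); bark surfaces are constant over the
#' annual cycle. The run is deterministic given its inputs.
#'
#' @param study a \code{\linkS4class{SyntheticStudy}}.
#' @param models a \code{\linkS4class{TrunkloadModels}}; fitted from the
#'   study if omitted.
#' @param window optional Date vector of length 2; defaults to the study's
#'   model window.
#' @param smoothing passed to \code{\link{interpolateDailyHeights}}.
#' @return a \code{\linkS4class{TrunkloadSurfaces}}.
#' @export
runDailyModel <- function(study, models = NULL, window = NULL,
                          smoothing = c("gcv", "off")) {
  smoothing <- match.arg(smoothing)
  if (is.null(models)) models <- fitTrunkloadModels(study)
  tab <- study@tables
  units <- tab$units
  startDate <- as.Date(tab$window$start_date[1])
  nDays <- tab$window$n_days[1]
  if (is.null(window)) window <- c(startDate, startDate + nDays - 1)
  window <- as.Date(window)
  dates <- seq(window[1], window[2], by = 1)
  dayIdx <- as.integer(dates - startDate) + 1L
  nU <- nrow(units); nD <- length(dates)

  # greenness matrix: species x day (of the study window)
  gr <- tab$greenness
  spLev <- unique(gr$species)
  green <- matrix(NA_real_, length(spLev), max(gr$day),
                  dimnames = list(spLev, NULL))
  green[cbind(match(gr$species, spLev), gr$day)] <- gr$green_fraction
  if (any(dayIdx < 1L) || any(dayIdx > ncol(green)))
    stop("window extends beyond the study's daily greenness records")

  mk <- function() matrix(0, nU, nD, dimnames = list(units$unit, as.character(dates)))
  surf <- setNames(
    lapply(seq_len(10), function(i) mk()),
    as.vector(outer(forageTypes(), elephantGroups(), paste, sep = "_")))

  forbMass <- setNames(tab$forb_species$mass_g, tab$forb_species$species)
  annualMass <- setNames(tab$annual_grass$mass_g, tab$annual_grass$species)
  leafUnit <- setNames(tab$woody_species$leaf_unit_mass_g,
                       tab$woody_species$species)

  for (ui in seq_len(nU)) {
    u <- units$unit[ui]
    sv <- tab$height_surveys[tab$height_surveys$unit == u, ]
    if (!nrow(sv)) stop("no height surveys for unit ", u)
    daily <- interpolateDailyHeights(sv, window, smoothing = smoothing)

    gc <- tab$grass_cover[tab$grass_cover$unit == u, ]
    if (!nrow(gc)) stop("no grass community for unit ", u)
    if (units$herb_layer[ui] == "perennial") {
      for (g in elephantGroups()) {
        B <- models@unitBasalArea[[g]][models@unitBasalArea$unit == u]
        if (!length(B) || is.na(B))
          stop("no mean basal area for unit ", u, " (forage green_grass)")
        gm <- models@grass[[as.character(units$vegtype[ui])]]
        if (is.null(gm))
          stop("no grass model for vegetation type ", units$vegtype[ui],
               " (unit ", u, ")")
        surf[[.assayName("green_grass", g)]][ui, ] <-
          grassTrunkload(gm, daily$h_green, B)
        surf[[.assayName("mixed_grass", g)]][ui, ] <-
          grassTrunkload(gm, daily$h_mixed, B)
      }
    } else {
      if (!all(gc$species %in% names(annualMass)))
        stop("missing annual grass mass for unit ", u)
      const <- annualGrassTrunkload(annualMass[gc$species], gc$cover)
      for (g in elephantGroups()) {
        surf[[.assayName("green_grass", g)]][ui, ] <- const
        surf[[.assayName("mixed_grass", g)]][ui, ] <- const
      }
    }

    fc <- tab$forb_cover[tab$forb_cover$unit == u, ]
    if (!nrow(fc)) stop("no forb community for unit ", u)
    forbBase <- sum(forbMass[fc$species] * fc$cover)
    for (g in elephantGroups())
      surf[[.assayName("forb", g)]][ui, ] <- forbBase * daily$h_forb_rel

    wc <- tab$woody_cover[tab$woody_cover$unit == u, ]
    for (g in elephantGroups()) {
      wg <- wc[wc$group == g, ]
      if (!nrow(wg)) {
        warning("empty woody layer for unit ", u, ", group ", g)
        next
      }
      miss <- setdiff(wg$species, names(leafUnit))
      if (length(miss))
        stop("missing leaf-unit mass for species: ",
             paste(miss, collapse = ", "))
      sLeaf <- predict(models@leaf[[g]], leafUnit[wg$species])
      gmat <- green[wg$species, dayIdx, drop = FALSE]
      surf[[.assayName("leaf", g)]][ui, ] <- vapply(
        seq_len(nD), function(d)
          leafTrunkload(sLeaf, wg$rel_density, gmat[, d]),
        numeric(1))
      surf[[.assayName("bark", g)]][ui, ] <- barkTrunkload(
        .barkMeanVector(models@barkMeans, g),
        setNames(wg$rel_density, wg$species))
    }
  }

  rd <- units
  cellCount <- table(factor(study@raster[study@raster > 0L],
                            levels = units$unit))
  rd$n_cells <- as.integer(cellCount)
  se <- SummarizedExperiment(
    assays = surf,
    rowData = DataFrame(rd, row.names = units$unit),
    colData = DataFrame(date = dates, day = dayIdx,
                        row.names = as.character(dates)))
  out <- new("TrunkloadSurfaces", se)
  metadata(out)$raster <- study@raster
  out
}

#' @describeIn landscapeSummary area-weighted summary over raster cells
#' @export
setMethod("landscapeSummary", "TrunkloadSurfaces", function(x, raster = NULL) {
  if (is.null(raster)) raster <- metadata(x)$raster
  if (is.null(raster)) stop("no raster supplied or stored with the surfaces")
  ids <- raster[raster > 0L]
  unitsPresent <- as.character(sort(unique(ids)))
  orphan <- setdiff(unitsPresent, rownames(x))
  if (length(orphan))
    stop("raster contains unit ids absent from the surfaces: ",
         paste(orphan, collapse = ", "))
  w <- as.numeric(table(factor(as.character(ids), levels = unitsPresent)))
  dates <- colData(x)$date
  out <- lapply(forageTypes(), function(f) lapply(elephantGroups(),
                                                  function(g) {
    m <- assay(x, .assayName(f, g))[unitsPresent, , drop = FALSE]
    data.frame(date = dates, day = colData(x)$day, forage = f, group = g,
               mean = as.numeric(crossprod(m, w) / sum(w)),
               min = apply(m, 2, min), max = apply(m, 2, max),
               row.names = NULL)
  }))
  do.call(rbind, unlist(out, recursive = FALSE))
})
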