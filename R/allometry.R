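#' Basal area of a grass tuft from its circumference
#'
#' Field crews measure the circumference of a tuft's base; the grass
#' trunkload model works with basal area. Assuming a circular base, a
#' circumference \eqn{C} encloses an area \eqn{B = C^2 / (4\pi)}.
#'
#' @param circumference numeric vector of basal circumferences (cm),
#'   all \eqn{\ge 0}.
#' @return basal areas (cm^2).
#' @examples
#' basalAreaFromCircumference(2 * pi)   # pi
#' basalAreaFromCircumference(35.5)     # ~100.28 cm^2
#' @export
basalAreaFromCircumference <- function(circumference) {
  if (any(circumference < 0))
    stop("circumference must be >= 0")
  circumference^2 / (4 * pi)
}

.sampleBasalArea <- function(samples) {
  if ("basal_area_cm2" %in% names(samples)) return(samples$basal_area_cm2)
  if ("circumference_cm" %in% names(samples))
    return(basalAreaFromCircumference(samples$circumference_cm))
  stop("tuft samples need a 'basal_area_cm2' or 'circumference_cm' column")
}

#' Fit the zero-intercept grass tuft-mass coefficient per vegetation type
#'
#' Fits \eqn{mass = a \cdot H B} (no intercept) by least squares to tuft
#' samples pooled per vegetation type, where \eqn{H} is the height of the
#' tallest leaf (cm) and \eqn{B} the basal area (cm^2). The zero-intercept
#' form means a tuft of vanishing size has vanishing mass; the fitted slope
#' equals the closed form \eqn{\sum m x / \sum x^2} with \eqn{x = H B}.
#'
#' @param samples data.frame of tuft samples with columns \code{vegtype},
#'   \code{height_cm}, \code{mass_g} and either \code{basal_area_cm2} or
#'   \code{circumference_cm}.
#' @return named list of \code{\linkS4class{GrassMassModel}}, one per
#'   vegetation type present.
#' @examples
#' s <- data.frame(vegtype = "21", height_cm = 10, basal_area_cm2 = 2,
#'                 mass_g = 1)
#' coef(fitGrassMassCoefficient(s)[["21"]])  # a = 0.05
#' @export
fitGrassMassCoefficient <- function(samples) {
  B <- .sampleBasalArea(samples)
  x <- samples$height_cm * B
  if (any(x < 0)) stop("height x basal area must be >= 0")
  out <- lapply(split(seq_len(nrow(samples)), as.character(samples$vegtype)),
                function(idx) {
    xv <- x[idx]; mv <- samples$mass_g[idx]
    if (all(xv == 0))
      stop("cannot fit grass mass model: all height x basal area are zero")
    fit <- lm(mv ~ 0 + xv)
    ar2 <- suppressWarnings(summary(fit)$adj.r.squared)
    new("GrassMassModel",
        vegtype = as.character(samples$vegtype[idx[1]]),
        coefficient = unname(coef(fit)[1]),
        adjR2 = if (is.finite(ar2)) ar2 else NA_real_,
        n = length(idx))
  })
  out
}

#' @describeIn fitGrassMassCoefficient predicted trunkload mass (g) of green
#'   or mixed grass: \code{coefficient * height * basalArea}.
#' @param object a \code{GrassMassModel}.
#' @param height grass height (cm).
#' @param basalArea mean tuft basal area (cm^2).
#' @param ... ignored.
#' @export
setMethod("predict", "GrassMassModel", function(object, height, basalArea, ...) {
  object@coefficient * height * basalArea
})

#' Tuft-selection ceilings and their group contrasts
#'
#' Elephants will not uproot arbitrarily large tufts in a single trunkload.
#' The mean circumference of tufts actually selected by each group is used
#' as a ceiling when averaging tuft basal area. Group differences are
#' tested with a Kruskal-Wallis omnibus over the selected-by-bull,
#' selected-by-herd and whole-community samples, followed by Dunn's post
#' hoc pairwise contrasts (rank-based, because circumference samples are
#' non-normal and heteroscedastic).
#'
#' @param selected named list of numeric circumference vectors (cm), one
#'   per elephant group (\code{bull}, \code{herd}).
#' @param community numeric vector of circumferences of tufts in the plant
#'   community at large.
#' @return list with \code{ceilings} (named list of
#'   \code{\linkS4class{TuftCeiling}}), \code{communityMean}, and
#'   \code{test} (the \code{kruskal.test} result plus a data.frame of Dunn
#'   contrasts).
#' @export
estimateTuftCeiling <- function(selected, community) {
  if (!length(community)) stop("community circumference sample is empty")
  for (g in names(selected)) {
    .checkGroup(g)
    if (!length(selected[[g]]))
      stop("selected circumference sample for group '", g, "' is empty")
  }
  ceilings <- lapply(names(selected), function(g)
    new("TuftCeiling", group = g, ceiling = mean(selected[[g]]),
        n = length(selected[[g]])))
  names(ceilings) <- names(selected)
  values <- c(unlist(selected, use.names = FALSE), community)
  groups <- c(rep(names(selected), lengths(selected)),
              rep("community", length(community)))
  kw <- suppressWarnings(kruskal.test(values, factor(groups)))
  dunn <- .dunnTest(values, groups)
  list(ceilings = ceilings, communityMean = mean(community),
       test = list(kruskal = kw, dunn = dunn))
}

#' Mean tuft basal area under a selection ceiling
#'
#' Tufts whose basal circumference exceeds the group's selection ceiling
#' are excluded (the ceiling limits the size of tufts selected, so
#' over-ceiling tufts do not enter the average); the mean basal area of the
#' retained tufts is returned. If no tuft falls below the ceiling the mean
#' is 0 with a warning.
#'
#' @param circumferences numeric vector of tuft circumferences (cm).
#' @param ceiling selection ceiling (cm), > 0.
#' @return mean basal area (cm^2) of tufts at or below the ceiling.
#' @examples
#' cappedMeanBasalArea(c(10, 20, 100), ceiling = 25)
#' @export
cappedMeanBasalArea <- function(circumferences, ceiling) {
  if (ceiling <= 0) stop("ceiling must be > 0")
  keep <- circumferences[circumferences <= ceiling]
  if (!length(keep)) {
    warning("no tufts at or below the ceiling; mean basal area set to 0")
    return(0)
  }
  mean(basalAreaFromCircumference(keep))
}

#' Fit the linear leaf-trunkload regression per elephant group
#'
#' The mass of leaves gathered per trunkload from a woody plant scales with
#' the mass of an individual leaf unit (usually a leaflet): small leaves
#' are hard to handle and many fall from the trunk's grasp. An ordinary
#' least-squares line with intercept is fitted per group, and the group
#' difference is tested by analysis of covariance with leaf-unit mass as
#' the covariate.
#'
#' @param observations data.frame with columns \code{group},
#'   \code{leaf_unit_mass_g} and \code{trunkload_g}; at least 3
#'   observations per group.
#' @return list with \code{models} (named list of
#'   \code{\linkS4class{LeafTrunkloadModel}}) and \code{ancova}
#'   (data.frame with the covariate-adjusted group-effect F test).
#' @export
fitLeafTrunkloadModel <- function(observations) {
  observations$group <- as.character(observations$group)
  for (g in unique(observations$group)) .checkGroup(g)
  counts <- table(observations$group)
  if (any(counts < 3))
    stop("need at least 3 leaf-trunkload observations per group; got ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  models <- lapply(split(observations, observations$group), function(d) {
    fit <- lm(trunkload_g ~ leaf_unit_mass_g, data = d)
    ar2 <- suppressWarnings(summary(fit)$adj.r.squared)
    new("LeafTrunkloadModel", group = d$group[1],
        slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
        adjR2 = if (is.finite(ar2)) ar2 else NA_real_, n = nrow(d))
  })
  ancova <- NULL
  if (length(unique(observations$group)) > 1) {
    m0 <- lm(trunkload_g ~ leaf_unit_mass_g, data = observations)
    m1 <- lm(trunkload_g ~ leaf_unit_mass_g + group, data = observations)
    a <- anova(m0, m1)
    ancova <- data.frame(effect = "group", df1 = a$Df[2], df2 = a$Res.Df[2],
                         F = a$F[2], p = a$`Pr(>F)`[2])
  }
  list(models = models, ancova = ancova)
}

#' @describeIn fitLeafTrunkloadModel predicted leaf trunkload mass (g) at a
#'   given leaf-unit mass: \code{slope * leafMass + intercept}.
#' @param object a \code{LeafTrunkloadModel}.
#' @param leafMass dry mass of a leaf unit (g).
#' @param ... ignored.
#' @export
setMethod("predict", "LeafTrunkloadModel", function(object, leafMass, ...) {
  object@slope * leafMass + object@intercept
})

#' Fit the quadratic bark-mass model per woody species
#'
#' Elephants chew bark off a broken branch along its length; the harvested
#' bark mass is modelled as \eqn{W = a X + b X^2} with no intercept, where
#' \eqn{X = L D} is the branch length (cm) times its mean diameter (mm).
#' The predictor multiplies centimetres by millimetres without unit
#' conversion, as the fitted coefficients assume.
#'
#' @param samples data.frame with columns \code{species}, \code{length_cm},
#'   \code{diameter_mm} and \code{bark_mass_g}; at least 3 branches per
#'   species with at least 2 distinct positive \eqn{X}.
#' @return named list of \code{\linkS4class{BarkMassModel}}, one per
#'   species.
#' @export
fitBarkMassModel <- function(samples) {
  out <- lapply(split(samples, as.character(samples$species)), function(d) {
    if (nrow(d) < 3)
      stop("need at least 3 branch samples for species '", d$species[1], "'")
    X <- d$length_cm * d$diameter_mm
    if (sum(unique(X) > 0) < 2)
      stop("degenerate design for species '", d$species[1],
           "': need at least 2 distinct positive length x diameter values")
    fit <- lm(bark_mass_g ~ 0 + X + I(X^2), data = data.frame(
      bark_mass_g = d$bark_mass_g, X = X))
    ar2 <- suppressWarnings(summary(fit)$adj.r.squared)
    cf <- unname(coef(fit))
    xs <- seq(min(X), max(X), length.out = 200)
    if (any(cf[1] * xs + cf[2] * xs^2 < 0))
      warning("bark-mass fit for species '", d$species[1],
              "' predicts negative mass within the fitted range; ",
              "the branch sample may not identify both coefficients")
    new("BarkMassModel", species = as.character(d$species[1]),
        a = cf[1], b = cf[2],
        adjR2 = if (is.finite(ar2)) ar2 else NA_real_, n = nrow(d))
  })
  out
}

#' @describeIn fitBarkMassModel predicted bark mass (g) for a debarked
#'   portion of size \eqn{X = L D} (cm mm): \code{a * X + b * X^2}.
#' @param object a \code{BarkMassModel}.
#' @param lengthDiameter branch length x mean diameter (cm mm).
#' @param ... ignored.
#' @export
setMethod("predict", "BarkMassModel", function(object, lengthDiameter, ...) {
  object@a * lengthDiameter + object@b * lengthDiameter^2
})

#' Mean bark mass stripped per branch, by group and species
#'
#' Applies the fitted bark-mass models to field records of debarked
#' branches. Each record gives the length and mean diameter of the debarked
#' portion, per fork when a forked branch was debarked; the branch's bark
#' mass is the sum of the model predictions over its forks. Group x species
#' differences in per-branch bark mass are tested with an aligned-rank-
#' transform two-way ANOVA (rank-based, for non-normal heteroscedastic
#' masses).
#'
#' @param records data.frame with columns \code{group}, \code{species},
#'   \code{branch_id}, \code{fork_length_cm}, \code{fork_diameter_mm}; one
#'   row per fork.
#' @param models named list of \code{\linkS4class{BarkMassModel}} as
#'   returned by \code{\link{fitBarkMassModel}}; must cover every species
#'   in \code{records}.
#' @return list with \code{means} (data.frame \code{group},
#'   \code{species}, \code{mean_bark_g}, \code{n_branches}),
#'   \code{perBranch} (per-branch predicted masses) and \code{test} (the
#'   aligned-rank ANOVA table, \code{NULL} when a factor has one level).
#' @export
meanBarkMass <- function(records, models) {
  records$species <- as.character(records$species)
  records$group <- as.character(records$group)
  missing <- setdiff(unique(records$species), names(models))
  if (length(missing))
    stop("no bark-mass model for species: ", paste(missing, collapse = ", "))
  if (any(records$fork_length_cm <= 0) || any(records$fork_diameter_mm <= 0))
    stop("fork dimensions must be > 0")
  X <- records$fork_length_cm * records$fork_diameter_mm
  a <- vapply(models[records$species], slot, numeric(1), "a")
  b <- vapply(models[records$species], slot, numeric(1), "b")
  forkMass <- a * X + b * X^2
  key <- interaction(records$group, records$species, records$branch_id,
                     drop = TRUE)
  perBranch <- data.frame(
    group = tapply(records$group, key, `[`, 1),
    species = tapply(records$species, key, `[`, 1),
    branch_id = tapply(records$branch_id, key, `[`, 1),
    bark_g = as.numeric(tapply(forkMass, key, sum)),
    row.names = NULL)
  agg <- aggregate(bark_g ~ group + species, perBranch, mean)
  nbr <- aggregate(bark_g ~ group + species, perBranch, length)
  means <- data.frame(group = agg$group, species = agg$species,
                      mean_bark_g = agg$bark_g, n_branches = nbr$bark_g)
  test <- NULL
  if (length(unique(perBranch$group)) > 1 &&
      length(unique(perBranch$species)) > 1) {
    test <- .artAnova(perBranch$bark_g, perBranch$group, perBranch$species,
                      names = c("group", "species"))
  }
  list(means = means, perBranch = perBranch, test = test)
}
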