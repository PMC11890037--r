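#' Ground-truth parameters for the synthetic study generator
#'
#' An S4 container holding every parameter the synthetic field-data
#' generator needs: the harvest allometry coefficients used as ground truth,
#' species tables (grasses, annual grasses, forbs, woody plants), the
#' tuft-selection ceilings, seasonal phenology settings and noise scales.
#' Construct with \code{\link{trunkloadParams}}.
#'
#' @slot seed integer; master seed from which per-table seeds are derived.
#' @slot grassCoef named numeric; ground-truth tuft-mass coefficient
#'   \eqn{a} (g cm^-3) per vegetation type (names are vegetation-type ids).
#' @slot grassSpecies data.frame with columns \code{species},
#'   \code{mean_circumference_cm}, \code{cv_circumference}; perennial grass
#'   species and the lognormal law of their basal circumference.
#' @slot annualGrass data.frame with columns \code{species}, \code{mass_g};
#'   mean dry mass of a whole annual grass plant.
#' @slot forbSpecies data.frame with columns \code{species}, \code{mass_g};
#'   end-of-season dry mass of a whole forb plant.
#' @slot woodySpecies data.frame with columns \code{species},
#'   \code{leaf_unit_mass_g}, \code{senescence_day}, \code{regreen_day},
#'   \code{ramp_days}; leaf-unit mass and canopy greenness phenology.
#' @slot leafSlope,leafIntercept named numeric (\code{bull}, \code{herd});
#'   ground-truth leaf-trunkload regression coefficients (g per g; g).
#' @slot barkCoef data.frame with columns \code{species}, \code{a},
#'   \code{b}; ground-truth quadratic bark-mass coefficients.
#' @slot ceilings named numeric (\code{bull}, \code{herd}); mean selected
#'   tuft circumference (cm) used as the tuft-size ceiling per group.
#' @slot communityCircMean,communityCircCV numeric; mean (cm) and CV of the
#'   community tuft-circumference distribution of the ceiling target species.
#' @slot phenology list of seasonal height-curve settings (see
#'   \code{\link{trunkloadParams}}).
#' @slot noise named numeric noise scales: \code{tuft_mass_cv},
#'   \code{leaf_obs_cv}, \code{bark_mass_cv} (multiplicative lognormal CVs)
#'   and \code{survey_height_sd} (additive cm, truncated at zero).
#' @slot debarking list; lognormal law of debarked-branch size per group.
#' @export
setClass("TrunkloadParams", representation(
  seed = "integer",
  grassCoef = "numeric",
  grassSpecies = "data.frame",
  annualGrass = "data.frame",
  forbSpecies = "data.frame",
  woodySpecies = "data.frame",
  leafSlope = "numeric",
  leafIntercept = "numeric",
  barkCoef = "data.frame",
  ceilings = "numeric",
  communityCircMean = "numeric",
  communityCircCV = "numeric",
  phenology = "list",
  noise = "numeric",
  debarking = "list"
))

setValidity("TrunkloadParams", function(object) {
  msg <- character()
  if (any(object@grassCoef <= 0)) msg <- c(msg, "grassCoef must be > 0")
  if (is.null(names(object@grassCoef)) || anyDuplicated(names(object@grassCoef)))
    msg <- c(msg, "grassCoef must be uniquely named by vegetation type")
  for (s in c("leafSlope", "leafIntercept", "ceilings")) {
    v <- slot(object, s)
    if (!all(c("bull", "herd") %in% names(v)))
      msg <- c(msg, paste0(s, " must be named with 'bull' and 'herd'"))
  }
  if (all(c("bull", "herd") %in% names(object@ceilings)) &&
      object@ceilings[["bull"]] <= object@ceilings[["herd"]])
    msg <- c(msg, "bull tuft ceiling must exceed the breeding-herd ceiling")
  if (any(object@ceilings <= 0)) msg <- c(msg, "ceilings must be > 0")
  if (any(object@leafSlope < 0)) msg <- c(msg, "leafSlope must be >= 0")
  if (any(object@noise < 0)) msg <- c(msg, "noise scales must be >= 0")
  if (any(object@forbSpecies$mass_g < 0)) msg <- c(msg, "forb masses must be >= 0")
  if (any(object@woodySpecies$leaf_unit_mass_g < 0))
    msg <- c(msg, "leaf-unit masses must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A complete synthetic field study
#'
#' Holds the landscape-unit raster, all field-sample and community tables,
#' and the \code{\linkS4class{TrunkloadParams}} ground truth that generated
#' them. Created by \code{\link{simulateStudy}} or read back from disk with
#' \code{\link{readStudy}}.
#'
#' @slot tables named list of data.frames (see \code{\link{studyTable}} for
#'   the table names and schemas).
#' @slot raster integer matrix of landscape-unit ids (0 = nodata).
#' @slot params the generating \code{\linkS4class{TrunkloadParams}}.
#' @export
setClass("SyntheticStudy", representation(
  tables = "list",
  raster = "matrix",
  params = "TrunkloadParams"
))

#' Fitted harvest-allometry models
#'
#' Small S4 value classes returned by the fitting functions:
#' \code{GrassMassModel} (zero-intercept tuft mass on height x basal area),
#' \code{TuftCeiling} (mean selected tuft circumference per group),
#' \code{LeafTrunkloadModel} (linear leaf trunkload on leaf-unit mass) and
#' \code{BarkMassModel} (zero-intercept quadratic bark mass on branch
#' length x diameter). All expose \code{coef} and, where meaningful,
#' \code{predict} methods.
#'
#' @slot vegtype,species,group identifier of the fitted stratum.
#' @slot coefficient,slope,intercept,a,b fitted coefficients.
#' @slot adjR2 adjusted R-squared of the fit.
#' @slot n number of observations used.
#' @slot ceiling mean selected circumference (cm).
#' @name trunkload-models
#' @aliases GrassMassModel-class TuftCeiling-class LeafTrunkloadModel-class
#'   BarkMassModel-class
NULL

#' @rdname trunkload-models
#' @export
setClass("GrassMassModel", representation(
  vegtype = "character", coefficient = "numeric",
  adjR2 = "numeric", n = "integer"
))

setValidity("GrassMassModel", function(object) {
  if (object@n > 0L && object@coefficient <= 0)
    "coefficient must be > 0 for a nonempty fit" else TRUE
})

#' @rdname trunkload-models
#' @export
setClass("TuftCeiling", representation(
  group = "character", ceiling = "numeric", n = "integer"
))

setValidity("TuftCeiling", function(object) {
  if (object@ceiling <= 0) "ceiling must be > 0" else TRUE
})

#' @rdname trunkload-models
#' @export
setClass("LeafTrunkloadModel", representation(
  group = "character", slope = "numeric", intercept = "numeric",
  adjR2 = "numeric", n = "integer"
))

setValidity("LeafTrunkloadModel", function(object) {
  if (object@slope < 0) "slope must be >= 0" else TRUE
})

#' @rdname trunkload-models
#' @export
setClass("BarkMassModel", representation(
  species = "character", a = "numeric", b = "numeric",
  adjR2 = "numeric", n = "integer"
))

#' Bundle of all fitted trunkload models for a study
#'
#' Returned by \code{\link{fitTrunkloadModels}}; consumed by
#' \code{\link{runDailyModel}}.
#'
#' @slot grass named list of \code{GrassMassModel}, one per vegetation type.
#' @slot ceilings named list of \code{TuftCeiling} (bull, herd).
#' @slot leaf named list of \code{LeafTrunkloadModel} (bull, herd).
#' @slot bark named list of \code{BarkMassModel}, one per species.
#' @slot barkMeans data.frame (group, species, mean_bark_g) of mean bark
#'   mass stripped per branch, from debarked-branch records.
#' @slot unitBasalArea data.frame (unit, bull, herd) of the cover-weighted,
#'   ceiling-capped mean tuft basal area (cm^2) per landscape unit.
#' @slot reports list of statistical test reports (tuft-selection omnibus
#'   and post hoc contrasts, leaf ANCOVA, bark aligned-rank ANOVA).
#' @export
setClass("TrunkloadModels", representation(
  grass = "list", ceilings = "list", leaf = "list", bark = "list",
  barkMeans = "data.frame", unitBasalArea = "data.frame", reports = "list"
))

#' Daily trunkload surfaces as a SummarizedExperiment
#'
#' The result of \code{\link{runDailyModel}}: one assay per forage type and
#' elephant group (e.g. \code{"green_grass_bull"}), each a landscape-unit x
#' day matrix of predicted trunkload dry mass (g). Rows are landscape units
#' (rowData carries unit attributes and raster cell counts), columns are
#' days (colData carries the date). The unit-id raster is stored in
#' \code{metadata(x)$raster}.
#'
#' @seealso \code{\link{getSurface}}, \code{\link{landscapeSummary}},
#'   \code{\link{groupDifferenceReport}}
#' @export
setClass("TrunkloadSurfaces", contains = "SummarizedExperiment")

setValidity("TrunkloadSurfaces", function(object) {
  msg <- character()
  expected <- as.vector(outer(forageTypes(), elephantGroups(), paste, sep = "_"))
  miss <- setdiff(expected, assayNames(object))
  if (length(miss))
    msg <- c(msg, paste("missing assays:", paste(miss, collapse = ", ")))
  for (nm in assayNames(object)) {
    if (any(assay(object, nm) < 0, na.rm = TRUE))
      msg <- c(msg, paste("negative trunkload mass in assay", nm))
  }
  if (length(msg)) msg else TRUE
})
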