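#' Access a study table
#'
#' @param x a \code{\linkS4class{SyntheticStudy}}.
#' @param name table name; one of
#'   \code{"units"}, \code{"grass_cover"}, \code{"annual_grass"},
#'   \code{"forb_species"}, \code{"forb_cover"}, \code{"woody_species"},
#'   \code{"woody_cover"}, \code{"greenness"}, \code{"tuft_samples"},
#'   \code{"tuft_circumference"}, \code{"tuft_selection"},
#'   \code{"height_surveys"}, \code{"leaf_observations"},
#'   \code{"branch_samples"}, \code{"debarked_branches"}.
#' @return the requested \code{data.frame}.
#' @export
setGeneric("studyTable", function(x, name) standardGeneric("studyTable"))

#' @describeIn studyTable table accessor
setMethod("studyTable", "SyntheticStudy", function(x, name) {
  if (!name %in% names(x@tables))
    stop("no study table named '", name, "'")
  x@tables[[name]]
})

#' Landscape-unit raster of a study
#'
#' @param x a \code{\linkS4class{SyntheticStudy}}.
#' @return integer matrix of unit ids (0 = nodata).
#' @export
setGeneric("studyRaster", function(x) standardGeneric("studyRaster"))

#' @describeIn studyRaster raster accessor
setMethod("studyRaster", "SyntheticStudy", function(x) x@raster)

#' Ground-truth parameters of a study
#'
#' @param x a \code{\linkS4class{SyntheticStudy}}.
#' @return the generating \code{\linkS4class{TrunkloadParams}}.
#' @export
setGeneric("trueParams", function(x) standardGeneric("trueParams"))

#' @describeIn trueParams parameter accessor
setMethod("trueParams", "SyntheticStudy", function(x) x@params)

#' Extract one trunkload surface
#'
#' Returns the landscape-unit x day matrix of predicted trunkload mass (g)
#' for one forage type and elephant group.
#'
#' @param x a \code{\linkS4class{TrunkloadSurfaces}}.
#' @param forage one of \code{forageTypes()}.
#' @param group one of \code{elephantGroups()}.
#' @return numeric matrix (units x days).
#' @export
setGeneric("getSurface", function(x, forage, group) standardGeneric("getSurface"))

#' @describeIn getSurface assay lookup by forage type and group
setMethod("getSurface", "TrunkloadSurfaces", function(x, forage, group) {
  .checkForage(forage); .checkGroup(group)
  assay(x, .assayName(forage, group))
})

#' Area-weighted daily landscape summary of trunkload surfaces
#'
#' For each day, forage type and elephant group, computes the mean, minimum
#' and maximum trunkload mass over the raster cells of the study area. The
#' mean is area-weighted by the number of raster cells each landscape unit
#' occupies; the minimum and maximum are taken over the units present in
#' the raster.
#'
#' @param x a \code{\linkS4class{TrunkloadSurfaces}}.
#' @param raster optional integer matrix of unit ids; defaults to the
#'   raster stored in \code{metadata(x)}. Every nonzero cell id must be a
#'   unit of the surface.
#' @return data.frame with columns \code{date}, \code{day}, \code{forage},
#'   \code{group}, \code{mean}, \code{min}, \code{max} (grams).
#' @export
setGeneric("landscapeSummary", function(x, raster = NULL)
  standardGeneric("landscapeSummary"))

# -- fitted-model accessors ---------------------------------------------------

#' @describeIn trunkload-models fitted coefficient(s)
#' @param object a fitted model object.
#' @param ... ignored.
#' @export
setMethod("coef", "GrassMassModel", function(object, ...)
  c(a = object@coefficient))

#' @rdname trunkload-models
#' @export
setMethod("coef", "LeafTrunkloadModel", function(object, ...)
  c(intercept = object@intercept, slope = object@slope))

#' @rdname trunkload-models
#' @export
setMethod("coef", "BarkMassModel", function(object, ...)
  c(a = object@a, b = object@b))

#' @rdname trunkload-models
#' @export
setMethod("coef", "TuftCeiling", function(object, ...)
  c(ceiling = object@ceiling))

# -- show methods -------------------------------------------------------------

setMethod("show", "TrunkloadParams", function(object) {
  cat("TrunkloadParams (synthetic-study ground truth)\n")
  cat("  seed:", object@seed, "\n")
  cat("  vegetation types:", length(object@grassCoef),
      " (a = ", paste(signif(object@grassCoef, 4), collapse = ", "), ")\n",
      sep = "")
  cat("  species: ", nrow(object@grassSpecies), " perennial grasses, ",
      nrow(object@annualGrass), " annual grasses, ",
      nrow(object@forbSpecies), " forbs, ",
      nrow(object@woodySpecies), " woody\n", sep = "")
  cat("  tuft ceilings (cm): bull ", object@ceilings[["bull"]],
      ", herd ", object@ceilings[["herd"]], "\n", sep = "")
})

setMethod("show", "SyntheticStudy", function(object) {
  un <- object@tables$units
  cat("SyntheticStudy:", nrow(un), "landscape units,",
      sum(object@raster > 0L), "raster cells\n")
  cat("  tables:", paste(names(object@tables), collapse = ", "), "\n")
})

setMethod("show", "GrassMassModel", function(object) {
  cat(sprintf(
    "GrassMassModel [vegtype %s]: mass = %.6f (height x basal area), adj R2 = %.2f, n = %d\n",
    object@vegtype, object@coefficient, object@adjR2, object@n))
})

setMethod("show", "TuftCeiling", function(object) {
  cat(sprintf("TuftCeiling [%s]: mean selected circumference = %.1f cm (n = %d)\n",
              object@group, object@ceiling, object@n))
})

setMethod("show", "LeafTrunkloadModel", function(object) {
  cat(sprintf("LeafTrunkloadModel [%s]: Y = %.3f X + %.3f, adj R2 = %.2f, n = %d\n",
              object@group, object@slope, object@intercept, object@adjR2,
              object@n))
})

setMethod("show", "BarkMassModel", function(object) {
  cat(sprintf("BarkMassModel [%s]: W = %.6f X + %.6f X^2, adj R2 = %.2f, n = %d\n",
              object@species, object@a, object@b, object@adjR2, object@n))
})

setMethod("show", "TrunkloadModels", function(object) {
  cat("TrunkloadModels:\n")
  for (m in object@grass) show(m)
  for (m in object@ceilings) show(m)
  for (m in object@leaf) show(m)
  for (m in object@bark) show(m)
})
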