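#' Construct synthetic-study ground-truth parameters
#'
#' Builds a \code{\linkS4class{TrunkloadParams}} object. The defaults are
#' calibrated to the study conditions the models were developed under:
#' tuft-mass coefficients of 0.050541, 0.050016, 0.072608 and 0.050897
#' g cm^-3 for four vegetation types; leaf-trunkload regressions
#' Y = 72.902 X + 14.196 (adult bulls) and Y = 67.669 X + 9.001 (breeding
#' herds); quadratic bark-mass models for Colophospermum mopane and two
#' Grewia species; tuft-selection ceilings of 35.5 cm (bulls) and 22.3 cm
#' (herds) against a community mean circumference of 52.7 cm; forb plant
#' masses spanning 2--418 g; and a seasonal grass-height curve that rises
#' to a late-wet-season peak and declines exponentially through the dry
#' season.
#'
#' @param seed integer master seed. Each generated table uses a seed derived
#'   deterministically from it, so tables can be regenerated independently.
#' @param grassCoef named numeric, ground-truth tuft-mass coefficient per
#'   vegetation type (g cm^-3).
#' @param grassSpecies,annualGrass,forbSpecies,woodySpecies species tables;
#'   see \code{\linkS4class{TrunkloadParams}} for the columns.
#' @param leafSlope,leafIntercept named numeric (\code{bull}, \code{herd}).
#' @param barkCoef data.frame (\code{species}, \code{a}, \code{b}).
#' @param ceilings named numeric (\code{bull}, \code{herd}), cm.
#' @param communityCircMean,communityCircCV lognormal law (mean cm, CV) of
#'   community tuft circumference for the ceiling target species.
#' @param phenology list of seasonal-curve settings: \code{peakHeightRange}
#'   (cm), \code{peakDayRange} (day of model window at which green grass
#'   peaks), \code{minFracRange} (dry-season trough as a fraction of peak),
#'   \code{riseStartDay} (day the next wet-season rise begins),
#'   \code{dryBase}/\code{dryAmp} (dry-leaf height as a fraction of peak),
#'   \code{forbPeakFrac} (forb peak height relative to grass),
#'   \code{surveyIntervalDays}, \code{surveyPadDays} (surveys extend this
#'   many days beyond both window ends), \code{pointsPerSurvey} and
#'   \code{quadratsPerPoint}.
#' @param noise named numeric noise scales (\code{tuft_mass_cv},
#'   \code{leaf_obs_cv}, \code{bark_mass_cv} multiplicative lognormal CVs;
#'   \code{survey_height_sd} additive cm truncated at zero). Setting all to
#'   zero gives exact, noise-free field samples.
#' @param debarking list: \code{meanLD} named numeric (mean
#'   length x diameter, cm mm, of debarked branches per group),
#'   \code{cvLD}, \code{nBranches} per group and species, \code{forkProb}
#'   (probability a debarked branch is forked).
#' @return a validated \code{\linkS4class{TrunkloadParams}}.
#' @examples
#' p <- trunkloadParams(seed = 1)
#' p
#' @export
trunkloadParams <- function(
    seed = 1L,
    grassCoef = c("27" = 0.050541, "23" = 0.050016,
                  "21" = 0.072608, "38" = 0.050897),
    grassSpecies = data.frame(
      species = c("Setaria incrassata", "Panicum maximum",
                  "Digitaria eriantha", "Heteropogon contortus",
                  "Urochloa mosambicensis", "Themeda triandra"),
      mean_circumference_cm = c(52.7, 34, 26, 21, 18, 24),
      cv_circumference = c(0.60, 0.40, 0.40, 0.35, 0.35, 0.40)),
    annualGrass = data.frame(
      species = c("Aristida adscensionis", "Tragus berteronianus",
                  "Brachiaria deflexa"),
      mass_g = c(6, 3, 9)),
    forbSpecies = data.frame(
      species = sprintf("forb_%02d", 1:20),
      mass_g = c(2, 3, 4, 6, 8, 11, 14, 18, 22, 26, 31, 37, 44, 52,
                 62, 75, 92, 115, 160, 418)),
    woodySpecies = data.frame(
      species = c("Colophospermum mopane", "Grewia bicolor",
                  "Grewia monticola", "Combretum apiculatum",
                  "Acacia nigrescens", "Dichrostachys cinerea",
                  "Terminalia prunioides", "Strychnos madagascariensis"),
      leaf_unit_mass_g = c(0.65, 0.12, 0.10, 0.35, 0.08, 0.05, 0.30, 1.80),
      # drought-tolerant, smaller-leaved species keep >25% green canopy
      # through the dry season; broad-leaved species senesce early, so green
      # leaf remains available year-round while its trunkload mass declines
      senescence_day = c(380, 150, 160, 140, 320, 155, 290, 130),
      regreen_day = c(255, 260, 260, 265, 250, 250, 265, 270),
      ramp_days = rep(60, 8)),
    leafSlope = c(bull = 72.902, herd = 67.669),
    leafIntercept = c(bull = 14.196, herd = 9.001),
    barkCoef = data.frame(
      species = c("Colophospermum mopane", "Grewia bicolor",
                  "Grewia monticola"),
      a = c(0.164715, 0.299728, 0.156027),
      b = c(0.001772, 0.000467, 0.001769)),
    ceilings = c(bull = 35.5, herd = 22.3),
    communityCircMean = 52.7,
    communityCircCV = 0.35,
    phenology = list(
      peakHeightRange = c(40, 120),
      peakDayRange = c(10, 45),
      minFracRange = c(0.25, 0.40),
      riseStartDay = 250,
      dryBase = 0.15, dryAmp = 0.55,
      forbPeakFrac = 0.4,
      surveyIntervalDays = 91,
      surveyPadDays = 120,
      pointsPerSurvey = 5,
      quadratsPerPoint = 25),
    noise = c(tuft_mass_cv = 0.15, leaf_obs_cv = 0.10,
              bark_mass_cv = 0.08, survey_height_sd = 6),
    debarking = list(meanLD = c(bull = 100, herd = 70), cvLD = 0.4,
                     nBranches = 100, forkProb = 0.3)) {
  new("TrunkloadParams",
      seed = as.integer(seed), grassCoef = grassCoef,
      grassSpecies = grassSpecies, annualGrass = annualGrass,
      forbSpecies = forbSpecies, woodySpecies = woodySpecies,
      leafSlope = leafSlope, leafIntercept = leafIntercept,
      barkCoef = barkCoef, ceilings = ceilings,
      communityCircMean = communityCircMean,
      communityCircCV = communityCircCV,
      phenology = phenology, noise = noise, debarking = debarking)
}

# deterministic per-table seed sequence derived from the master seed, so any
# table can be regenerated on its own; kept below 2^31
.tableSeed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 65521) * 32452 + k * 10007 + 17)
}

# lognormal draw parameterised by mean and coefficient of variation;
# cv = 0 degenerates to the mean (noise-free limit)
.rlnormMeanCV <- function(n, mean, cv) {
  if (length(mean) == 1L) mean <- rep(mean, n)
  if (all(cv == 0)) return(mean)
  sdlog <- sqrt(log(1 + cv^2))
  mean * rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# multiplicative lognormal noise factor with unit mean
.noiseFactor <- function(n, cv) .rlnormMeanCV(n, 1, cv)
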