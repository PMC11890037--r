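# Shared fixtures, built in code.

# parameters whose field samples are exact evaluations of the ground truth
zeroNoiseParams <- function(seed = 1) {
  trunkloadParams(seed = seed,
                  noise = c(tuft_mass_cv = 0, leaf_obs_cv = 0,
                            bark_mass_cv = 0, survey_height_sd = 0))
}

# construct a TrunkloadSurfaces directly from matrices; assays not supplied
# are zero-filled. Used to feed hand-built surfaces to the comparison and
# summary operations.
makeSurfaces <- function(mats, raster = NULL) {
  base <- mats[[1]]
  if (is.null(rownames(base)))
    stop("helper surfaces need unit rownames")
  all <- as.vector(outer(forageTypes(), elephantGroups(), paste, sep = "_"))
  assays <- lapply(stats::setNames(all, all), function(nm) {
    if (!is.null(mats[[nm]])) mats[[nm]]
    else matrix(0, nrow(base), ncol(base), dimnames = dimnames(base))
  })
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    colData = S4Vectors::DataFrame(
      date = seq(as.Date("2002-03-12"), by = 1, length.out = ncol(base)),
      day = seq_len(ncol(base))))
  out <- methods::new("TrunkloadSurfaces", se)
  if (!is.null(raster)) S4Vectors::metadata(out)$raster <- raster
  out
}

# quadrat survey table for a single unit with given per-date mean heights
surveyTable <- function(dates, green, dry = green, forb = green,
                        unit = 1L, nQuadrats = 4) {
  do.call(rbind, lapply(seq_along(dates), function(i) {
    data.frame(unit = unit, date = as.Date(dates[i]),
               point = 1L, quadrat = seq_len(nQuadrats),
               h_green_cm = green[i], h_dry_cm = dry[i],
               h_forb_cm = forb[i])
  }))
}
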