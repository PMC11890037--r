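# Column dictionaries for every study table. CSVs are written with full
# float precision (%.17g) so a write/read round trip is lossless.
.studySchemas <- list(
  window = c(start_date = "Date", n_days = "integer"),
  units = c(unit = "integer", vegtype = "character", herb_layer = "character",
            peak_height_cm = "numeric", peak_day = "numeric",
            min_frac = "numeric", rise_start_day = "numeric",
            decline_rate = "numeric"),
  grass_cover = c(unit = "integer", species = "character", cover = "numeric"),
  annual_grass = c(species = "character", mass_g = "numeric"),
  forb_species = c(species = "character", mass_g = "numeric"),
  forb_cover = c(unit = "integer", species = "character", cover = "numeric"),
  woody_species = c(species = "character", leaf_unit_mass_g = "numeric"),
  woody_cover = c(unit = "integer", species = "character",
                  group = "character", rel_density = "numeric"),
  greenness = c(species = "character", day = "integer",
                green_fraction = "numeric"),
  tuft_samples = c(species = "character", vegtype = "character",
                   height_cm = "numeric", circumference_cm = "numeric",
                   mass_g = "numeric"),
  tuft_circumference = c(species = "character", circumference_cm = "numeric"),
  tuft_selection = c(group = "character", circumference_cm = "numeric"),
  height_surveys = c(unit = "integer", date = "Date", point = "integer",
                     quadrat = "integer", h_green_cm = "numeric",
                     h_dry_cm = "numeric", h_forb_cm = "numeric"),
  leaf_observations = c(group = "character", leaf_unit_mass_g = "numeric",
                        trunkload_g = "numeric"),
  branch_samples = c(species = "character", length_cm = "numeric",
                     diameter_mm = "numeric", bark_mass_g = "numeric"),
  debarked_branches = c(group = "character", species = "character",
                        branch_id = "character", fork_length_cm = "numeric",
                        fork_diameter_mm = "numeric"))

.writeTableCSV <- function(df, path) {
  out <- df
  for (j in names(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE)
}

.readTableCSV <- function(path, schema, name) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(names(schema), names(df))
  if (length(miss))
    stop("file '", basename(path), "' (table '", name,
         "') is missing column(s): ", paste(miss, collapse = ", "))
  for (j in names(schema)) {
    df[[j]] <- switch(schema[[j]],
                      integer = as.integer(df[[j]]),
                      numeric = as.numeric(df[[j]]),
                      Date = as.Date(df[[j]]),
                      character = as.character(df[[j]]))
  }
  df[names(schema)]
}

#' Read and write a landscape-unit raster as an ESRI ASCII grid
#'
#' Plain-text grid of integer unit ids (0 or the declared
#' \code{NODATA_value} marks cells outside the study area).
#'
#' @param path file path (conventionally \code{.asc}).
#' @param raster integer matrix of unit ids.
#' @return \code{readAsciiGrid} returns an integer matrix;
#'   \code{writeAsciiGrid} returns \code{path} invisibly.
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  header <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    header[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(as.integer(vals), nrow = header$nrows,
              ncol = header$ncols, byrow = TRUE)
  nod <- header[["nodata_value"]]
  if (!is.null(nod)) m[m == as.integer(nod)] <- 0L
  m
}

#' @rdname readAsciiGrid
#' @export
writeAsciiGrid <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(raster)),
               paste("nrows", nrow(raster)),
               "xllcorner 0", "yllcorner 0", "cellsize 1",
               "NODATA_value 0"), con)
  writeLines(apply(raster, 1, paste, collapse = " "), con)
  invisible(path)
}

# yaml serialises named atomic vectors as plain sequences, losing the names;
# turn them into maps recursively first
.namedToList <- function(v) {
  if (is.list(v) && !is.data.frame(v)) return(lapply(v, .namedToList))
  if (is.atomic(v) && !is.null(names(v))) return(as.list(v))
  v
}

.paramsToList <- function(params) {
  slots <- slotNames("TrunkloadParams")
  out <- lapply(slots, function(s) {
    v <- slot(params, s)
    if (is.data.frame(v)) lapply(as.list(v), I) else .namedToList(v)
  })
  names(out) <- slots
  out
}

.paramsFromList <- function(x) {
  dfSlots <- c("grassSpecies", "annualGrass", "forbSpecies", "woodySpecies",
               "barkCoef")
  args <- lapply(names(x), function(s) {
    v <- x[[s]]
    if (s %in% dfSlots) as.data.frame(lapply(v, unlist),
                                      stringsAsFactors = FALSE)
    else if (s %in% c("grassCoef", "leafSlope", "leafIntercept", "ceilings",
                      "noise")) unlist(v)
    else if (s == "debarking") {
      v$meanLD <- unlist(v$meanLD); v
    }
    else if (s == "phenology") lapply(v, unlist)
    else if (s == "seed") as.integer(v)
    else unlist(v)
  })
  names(args) <- names(x)
  do.call(trunkloadParams, args)
}

#' Write a study to disk / read it back
#'
#' \code{writeStudy} writes every table as a CSV, the landscape raster as
#' an ESRI ASCII grid and the ground-truth parameters as a YAML manifest;
#' \code{readStudy} reconstructs the \code{\linkS4class{SyntheticStudy}},
#' validating each file against its column dictionary (a missing column is
#' rejected with a message naming the file and column) and re-checking the
#' cover/density normalisation invariants.
#'
#' @param study a \code{\linkS4class{SyntheticStudy}}.
#' @param dir directory to write to / read from.
#' @return \code{writeStudy} returns \code{dir} invisibly;
#'   \code{readStudy} returns the study.
#' @export
writeStudy <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(study@tables)) {
    df <- study@tables[[nm]]
    if ("date" %in% names(df)) df$date <- as.character(df$date)
    if ("start_date" %in% names(df))
      df$start_date <- as.character(df$start_date)
    .writeTableCSV(df, file.path(dir, paste0(nm, ".csv")))
  }
  writeAsciiGrid(study@raster, file.path(dir, "landscape_units.asc"))
  yaml::write_yaml(.paramsToList(study@params),
                   file.path(dir, "manifest.yml"), precision = 17)
  invisible(dir)
}

#' @rdname writeStudy
#' @export
readStudy <- function(dir) {
  tables <- lapply(names(.studySchemas), function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) stop("missing study file: ", path)
    .readTableCSV(path, .studySchemas[[nm]], nm)
  })
  names(tables) <- names(.studySchemas)
  raster <- readAsciiGrid(file.path(dir, "landscape_units.asc"))
  params <- .paramsFromList(yaml::read_yaml(file.path(dir, "manifest.yml")))
  .newStudy(tables, raster, params)
}

.asConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config
}

#' Generate a synthetic study and write it to disk
#'
#' Declarative entry point: takes a configuration (YAML path or list) with
#' fields \code{seed}, \code{n_units}, \code{n_days}, \code{start_date}
#' and \code{study_dir}, builds the study deterministically and writes it.
#'
#' @param config YAML file path or list.
#' @return the study directory, invisibly.
#' @export
simulateStudyFiles <- function(config) {
  config <- .asConfig(config)
  params <- trunkloadParams(seed = config$seed %||% 1L)
  study <- simulateStudy(
    params,
    nUnits = config$n_units %||% 65,
    nDays = config$n_days %||% 364,
    startDate = as.Date(config$start_date %||% "2002-03-12"))
  writeStudy(study, config$study_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline from a study directory
#'
#' Reads a study from disk, fits all trunkload models, runs the daily
#' landscape model, and writes the tidy surface table
#' (\code{surfaces.csv}: date, unit, forage, group, mass), the daily
#' area-weighted landscape summaries (\code{summaries.csv}), the
#' bull-versus-herd comparison report (\code{group_comparisons.csv}) and a
#' run log recording the fitted coefficients.
#'
#' @param config YAML file path or list with fields \code{study_dir},
#'   \code{output_dir}, and optionally \code{alpha} (default 0.01),
#'   \code{smoothing} (\code{"gcv"}/\code{"off"}), \code{window}
#'   (\code{start}, \code{end}) and \code{ceiling_override} (named list
#'   \code{bull}/\code{herd}).
#' @return invisibly, a list with \code{models}, \code{surfaces},
#'   \code{summary} and \code{comparisons}.
#' @export
runPipeline <- function(config) {
  config <- .asConfig(config)
  study <- readStudy(config$study_dir)
  models <- fitTrunkloadModels(
    study, ceilingOverride = unlist(config$ceiling_override))
  window <- if (!is.null(config$window))
    as.Date(c(config$window$start, config$window$end)) else NULL
  surfaces <- runDailyModel(study, models, window = window,
                            smoothing = config$smoothing %||% "gcv")
  summ <- landscapeSummary(surfaces)
  comp <- groupDifferenceReport(surfaces, alpha = config$alpha %||% 0.01)

  outDir <- config$output_dir
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    tidy <- do.call(rbind, lapply(assayNames(surfaces), function(nm) {
      m <- assay(surfaces, nm)
      fg <- sub("_(bull|herd)$", "", nm)
      data.frame(date = rep(as.character(colData(surfaces)$date),
                            each = nrow(m)),
                 unit = rep(rownames(m), ncol(m)),
                 forage = fg, group = sub(paste0("^", fg, "_"), "", nm),
                 mass_g = as.vector(m))
    }))
    .writeTableCSV(tidy, file.path(outDir, "surfaces.csv"))
    .writeTableCSV(summ, file.path(outDir, "summaries.csv"))
    .writeTableCSV(comp, file.path(outDir, "group_comparisons.csv"))
    log <- c("trunkload pipeline run",
             paste0("study_dir: ", config$study_dir),
             vapply(models@grass, function(m) sprintf(
               "grass vegtype %s: a = %.6f (adj R2 %.3f, n %d)",
               m@vegtype, m@coefficient, m@adjR2, m@n), character(1)),
             vapply(models@ceilings, function(m) sprintf(
               "tuft ceiling %s: %.2f cm (n %d)", m@group, m@ceiling, m@n),
               character(1)),
             vapply(models@leaf, function(m) sprintf(
               "leaf %s: Y = %.3f X + %.3f (adj R2 %.3f, n %d)",
               m@group, m@slope, m@intercept, m@adjR2, m@n), character(1)),
             vapply(models@bark, function(m) sprintf(
               "bark %s: W = %.6f X + %.6f X^2 (adj R2 %.3f, n %d)",
               m@species, m@a, m@b, m@adjR2, m@n), character(1)))
    writeLines(log, file.path(outDir, "run.log"))
  }
  invisible(list(models = models, surfaces = surfaces, summary = summ,
                 comparisons = comp))
}
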