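#' Daily paired signed-rank comparison of two trunkload surfaces
#'
#' For every day, the per-unit paired differences between the two surfaces
#' are tested with a Wilcoxon signed-rank test; the significance mask marks
#' days with p below \code{alpha}. Zero differences are excluded (the
#' signed-rank zero-exclusion convention); a day on which every unit's
#' difference is zero gets p = 1. The exact small-sample null distribution
#' is used when fewer than 26 nonzero differences remain (and their
#' absolute values are untied); otherwise the normal approximation applies.
#' The sampling frame is landscape units, not raster cells, so equal units
#' are not pseudo-replicated by their map extent.
#'
#' @param a,b numeric unit x day matrices sharing dimensions and dimnames
#'   (as returned by \code{\link{getSurface}}).
#' @param alpha significance level in (0, 1); default 0.01.
#' @param pair label for the comparison.
#' @return data.frame with columns \code{pair}, \code{day} (column name,
#'   usually the date), \code{p} and \code{significant}.
#' @export
dailyPairwiseTest <- function(a, b, alpha = 0.01, pair = "A vs B") {
  if (!all(dim(a) == dim(b)))
    stop("surfaces have mismatched dimensions: ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b)))
    stop("surfaces have mismatched unit ids")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  p <- vapply(seq_len(ncol(a)), function(j) {
    d <- a[, j] - b[, j]
    d <- d[d != 0]
    if (!length(d)) return(1)
    suppressWarnings(
      wilcox.test(d, exact = length(d) < 26)$p.value)
  }, numeric(1))
  data.frame(pair = pair,
             day = if (is.null(colnames(a))) as.character(seq_len(ncol(a)))
                   else colnames(a),
             p = p, significant = p < alpha, row.names = NULL)
}

#' Seasonal maximum-to-minimum ratio of a daily series
#'
#' How many times heavier is the seasonal peak trunkload than the seasonal
#' trough: the maximum daily value divided by the minimum. Always at least
#' 1; exactly 1 for a constant series (e.g. canopy bark).
#'
#' @param dailyMeans numeric vector of strictly positive daily means (g).
#' @return max/min ratio.
#' @examples
#' seasonalExtremesRatio(c(93.3, 50, 29.4))  # 3.17
#' @export
seasonalExtremesRatio <- function(dailyMeans) {
  if (!length(dailyMeans)) stop("empty daily series")
  if (min(dailyMeans) <= 0)
    stop("seasonal ratio undefined: the daily series reaches zero")
  max(dailyMeans) / min(dailyMeans)
}

#' Built-in reference trunkload and bite-mass values
#'
#' Loads the package's versioned plain-text reference tables: the maximum
#' and minimum average trunkload mass per forage type and elephant group
#' reported by a field study in a semi-arid savanna in south-eastern
#' Zimbabwe; single-bite masses reported in the literature for other
#' grazing and browsing herbivores; and the bite masses predicted for
#' elephants from body-size allometry (bulls 4,850 kg, cows 3,500 kg).
#'
#' @return list with data.frames \code{trunkloads} (\code{forage},
#'   \code{group}, \code{max_g}, \code{min_g}), \code{biteMasses}
#'   (\code{class}, \code{species}, \code{mass_g}) and \code{predictedBite}
#'   (\code{class}, \code{group}, \code{mass_g}, \code{body_mass_kg}).
#' @export
referenceTrunkloads <- function() {
  path <- function(f) system.file("extdata", f, package = "trunkload",
                                  mustWork = TRUE)
  list(trunkloads = read.csv(path("reference_trunkloads.csv"),
                             stringsAsFactors = FALSE),
       biteMasses = read.csv(path("reference_bite_masses.csv"),
                             stringsAsFactors = FALSE),
       predictedBite = read.csv(path("reference_predicted_bite.csv"),
                                stringsAsFactors = FALSE))
}

#' Elephant trunkload mass relative to other herbivores' bite mass
#'
#' Divides the maximum average trunkload mass (green grass for the grazing
#' class, green leaves for the browsing class) by the largest single-bite
#' mass reported in the literature for that feeding class, and by the bite
#' mass predicted for an elephant of that body size from bite-mass/body-size
#' allometry.
#'
#' @param reference a reference list as returned by
#'   \code{\link{referenceTrunkloads}} (the default), optionally with the
#'   trunkload maxima replaced by values from a model run.
#' @param forageClass \code{"grazing"} or \code{"browsing"}.
#' @param groups elephant groups to report.
#' @return data.frame with columns \code{class}, \code{group},
#'   \code{trunkload_g}, \code{literature_bite_g},
#'   \code{literature_ratio}, \code{predicted_bite_g},
#'   \code{predicted_ratio}.
#' @export
literatureBiteRatio <- function(reference = referenceTrunkloads(),
                                forageClass = c("grazing", "browsing"),
                                groups = elephantGroups()) {
  forageClass <- match.arg(forageClass)
  forage <- switch(forageClass, grazing = "green_grass", browsing = "leaf")
  lit <- reference$biteMasses
  lit <- lit[lit$class == forageClass, ]
  if (!nrow(lit)) stop("unknown feeding class '", forageClass, "'")
  litMax <- max(lit$mass_g)
  out <- lapply(groups, function(g) {
    tl <- reference$trunkloads
    v <- tl$max_g[tl$forage == forage & tl$group == g]
    if (!length(v)) stop("no reference trunkload for ", forage, "/", g)
    pb <- reference$predictedBite
    pred <- pb$mass_g[pb$class == forageClass & pb$group == g]
    data.frame(class = forageClass, group = g, trunkload_g = v,
               literature_bite_g = litMax, literature_ratio = v / litMax,
               predicted_bite_g = pred, predicted_ratio = v / pred)
  })
  do.call(rbind, out)
}

#' Daily bull-versus-herd comparison for every forage type
#'
#' Runs \code{\link{dailyPairwiseTest}} between the adult-bull and
#' breeding-herd surface of each forage type. The forb surfaces are shared
#' between the groups by construction, so their comparison reports exact
#' equality on every day (p = 1).
#'
#' @param surfaces a \code{\linkS4class{TrunkloadSurfaces}}.
#' @param alpha significance level; default 0.01.
#' @param forages forage types to compare.
#' @return data.frame as \code{\link{dailyPairwiseTest}}, rows stacked over
#'   forage types, with an extra column \code{forage} and a logical
#'   \code{all_equal} flagging days of exact group equality.
#' @export
groupDifferenceReport <- function(surfaces, alpha = 0.01,
                                  forages = forageTypes()) {
  miss <- setdiff(forages, forageTypes())
  if (length(miss)) stop("unknown forage type: ", paste(miss, collapse = ", "))
  out <- lapply(forages, function(f) {
    a <- getSurface(surfaces, f, "bull")
    b <- getSurface(surfaces, f, "herd")
    r <- dailyPairwiseTest(a, b, alpha = alpha,
                           pair = paste0(f, ": bull vs herd"))
    r$forage <- f
    r$all_equal <- vapply(seq_len(ncol(a)), function(j)
      all(a[, j] == b[, j]), logical(1))
    r
  })
  do.call(rbind, out)
}
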