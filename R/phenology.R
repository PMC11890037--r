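#' Interpolate quarterly height surveys to a daily series
#'
#' Converts the quarterly quadrat surveys of one landscape unit into daily
#' series of green grass height, dry grass height, mixed grass height and
#' green forb height. Survey-date means are computed per variable over all
#' quadrats; the mixed-grass height is the mean of the green and dry
#' heights at each survey date (averaged before interpolation, i.e. per
#' sample point); each variable is then interpolated to daily resolution
#' with a smoothing spline. Negative spline excursions are clamped to zero.
#'
#' With \code{smoothing = "gcv"} (default) the smoothing parameter is
#' chosen by generalised cross-validation
#' (\code{\link[stats]{smooth.spline}}), which is stable at the small
#' number of survey dates a quarterly design yields;
#' \code{smoothing = "off"} uses an exact natural cubic interpolating
#' spline, which reproduces the survey-date means exactly. Fewer than four
#' survey dates always use exact interpolation (two dates degenerate to a
#' straight line).
#'
#' @param surveys data.frame of quadrat records for a single unit, with
#'   columns \code{date} (Date or ISO-8601 string), \code{h_green_cm},
#'   \code{h_dry_cm}, \code{h_forb_cm}. Quadrats with no plant of a
#'   category carry 0 cm and are included in the mean.
#' @param window Date vector of length 2, the first and last day of the
#'   required daily series. Must lie within the survey date range;
#'   extrapolation beyond the surveys is refused.
#' @param smoothing \code{"gcv"} or \code{"off"}.
#' @param spar optional smoothing parameter forwarded to
#'   \code{smooth.spline}, overriding cross-validation.
#' @return data.frame with one row per day: \code{date}, \code{day} (1-based
#'   index into the window), \code{h_green}, \code{h_dry}, \code{h_mixed},
#'   \code{h_forb} (cm) and \code{h_forb_rel} (the forb series scaled by
#'   its maximum; see \code{\link{relativeForbHeight}}).
#' @export
interpolateDailyHeights <- function(surveys, window,
                                    smoothing = c("gcv", "off"),
                                    spar = NULL) {
  smoothing <- match.arg(smoothing)
  surveys$date <- as.Date(surveys$date)
  window <- as.Date(window)
  dates <- sort(unique(surveys$date))
  if (length(dates) < 2)
    stop("need at least 2 survey dates to interpolate")
  if (any(diff(as.numeric(surveys$date[order(surveys$date)])) < 0))
    stop("survey dates must be sortable")  # unreachable after sort; guard
  if (window[1] < dates[1] || window[2] > dates[length(dates)])
    stop("window [", window[1], ", ", window[2],
         "] extends beyond the survey dates [", dates[1], ", ",
         dates[length(dates)], "]; extrapolation is refused")
  if (window[2] < window[1]) stop("window end precedes window start")

  meanBy <- function(v) as.numeric(tapply(v, surveys$date, mean))
  sm <- data.frame(date = dates,
                   h_green = meanBy(surveys$h_green_cm),
                   h_dry = meanBy(surveys$h_dry_cm),
                   h_forb = meanBy(surveys$h_forb_cm))
  sm$h_mixed <- (sm$h_green + sm$h_dry) / 2

  x <- as.numeric(sm$date)
  xout <- as.numeric(seq(window[1], window[2], by = 1))
  interp <- function(y) {
    if (smoothing == "off" || length(x) < 4) {
      f <- splinefun(x, y, method = "natural")
      out <- f(xout)
    } else {
      fit <- if (is.null(spar)) smooth.spline(x, y, cv = FALSE)
             else smooth.spline(x, y, spar = spar)
      out <- predict(fit, xout)$y
    }
    pmax(out, 0)  # clamp spline undershoot
  }
  daily <- data.frame(date = seq(window[1], window[2], by = 1),
                      day = seq_along(xout),
                      h_green = interp(sm$h_green),
                      h_dry = interp(sm$h_dry),
                      h_mixed = interp(sm$h_mixed),
                      h_forb = interp(sm$h_forb))
  daily$h_forb_rel <- relativeForbHeight(daily$h_forb)
  daily
}

#' Forb height relative to the unit's seasonal maximum
#'
#' The forb trunkload model scales the end-of-season plant mass by the
#' current average forb height relative to the maximum average height
#' observed for the landscape unit, so the relative series peaks at exactly
#' 1. An all-zero series (no forbs ever observed) maps to all zeros with a
#' warning.
#'
#' @param series numeric vector of daily mean forb heights (cm).
#' @return the series divided by its maximum, in [0, 1].
#' @examples
#' relativeForbHeight(c(10, 20, 40))  # 0.25 0.50 1.00
#' @export
relativeForbHeight <- function(series) {
  if (!length(series)) stop("forb height series is empty")
  m <- max(series)
  if (m == 0) {
    warning("forb height series is all zero; relative heights set to 0")
    return(rep(0, length(series)))
  }
  series / m
}
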