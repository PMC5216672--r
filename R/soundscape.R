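# Ambient-noise characterization per site-night and the inverse-square
# noise-vs-distance model.

#' Ambient-noise profile for a site-night
#'
#' Computes the windowed band-limited SPL series over one or more timestamped
#' recordings and takes the median of the windows whose start time falls in
#' the evaluation interval (default 16:00-17:00 local standard time, before
#' evening chorusing starts). Both analysis bands are supported: the frog
#' masking band (1,000-4,500 Hz) and the low-frequency traffic band
#' (nominally 0-1,000 Hz, realized as 10-1,000 Hz).
#'
#' @param clips List of `audio_clip`s (digital or Pa units).
#' @param starts `POSIXct` start time of each clip, in local standard time
#'   (recorders do not track daylight-saving shifts).
#' @param calib A [calibration_spec()] (needed for digital clips).
#' @param site,date Identifiers stored in the profile.
#' @param band Band edges in Hz.
#' @param window_s Analysis window length in s (15 min in field deployments;
#'   shorter for tests).
#' @param eval_interval Character `c("HH:MM", "HH:MM")` clock interval
#'   (start-inclusive, end-exclusive) over which the median is taken.
#' @return Object of class `noise_profile`: list with `site`, `date`, `band`,
#'   `window_s`, `spl_series` (data.frame `time`, `spl_db`), and
#'   `median_ambient_db` (`NA` with a warning when no window starts in the
#'   interval).
#' @export
ambient_profile <- function(clips, starts, calib = NULL, site = NA, date = NA,
                            band = c(1000, 4500), window_s = 900,
                            eval_interval = c("16:00", "17:00")) {
  if (inherits(clips, "audio_clip")) clips <- list(clips)
  stopifnot(length(clips) == length(starts), inherits(starts, "POSIXct"))
  series <- do.call(rbind, lapply(seq_along(clips), function(i) {
    s <- band_rms_spl(clips[[i]], calib, band, window_s)
    if (nrow(s) == 0) return(NULL)
    data.frame(time = starts[i] + s$window_start_s, spl_db = s$spl_db)
  }))
  if (is.null(series))
    series <- data.frame(time = as.POSIXct(character(0)),
                         spl_db = numeric(0))
  tod <- function(t) as.numeric(format(t, "%H")) * 3600 +
    as.numeric(format(t, "%M")) * 60 + as.numeric(format(t, "%S"))
  lim <- vapply(strsplit(eval_interval, ":"), function(p)
    as.numeric(p[1]) * 3600 + as.numeric(p[2]) * 60, numeric(1))
  inwin <- nrow(series) > 0 & tod(series$time) >= lim[1] &
    tod(series$time) < lim[2]
  med <- if (!any(inwin)) {
    warning("no analysis windows start inside the evaluation interval")
    NA_real_
  } else stats::median(series$spl_db[inwin])
  structure(list(site = site, date = date, band = band, window_s = window_s,
                 spl_series = series, median_ambient_db = med),
            class = "noise_profile")
}

#' @export
print.noise_profile <- function(x, ...) {
  cat(sprintf("<noise_profile> site=%s date=%s band=%g-%g Hz: median %s dB re 20 uPa (%d windows)\n",
              x$site, x$date, x$band[1], x$band[2],
              formatC(x$median_ambient_db, digits = 4, format = "fg"),
              nrow(x$spl_series)))
  invisible(x)
}

#' Regress site noise levels on the inverse-square distance term
#'
#' Ordinary least squares of median ambient noise on `A = 1 / d_km^2`, the
#' linearizing regressor predicted by the inverse-square law for outdoor
#' sound propagation. Reports the slope t-statistic on `n - 2` df.
#'
#' @param medians Median ambient noise per site, dB re 20 uPa.
#' @param distances_m Distance to the nearest busy road per site, m.
#' @return List: `intercept`, `slope`, `t_value`, `p_value`, `r_squared`,
#'   `df`, and the underlying `lm` fit.
#' @export
fit_inverse_square <- function(medians, distances_m) {
  if (length(medians) < 3) stop("need at least 3 sites")
  if (length(unique(distances_m)) < 2) stop("distances must be distinct")
  if (any(distances_m <= 0)) stop("distances must be > 0")
  A <- 1 / (distances_m / 1000)^2
  fit <- stats::lm(medians ~ A)
  co <- summary(fit)$coefficients
  list(intercept = co[1, 1], slope = co[2, 1], t_value = co[2, 3],
       p_value = co[2, 4], r_squared = summary(fit)$r.squared,
       df = fit$df.residual, fit = fit)
}
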