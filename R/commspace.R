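# Spatiotemporal communication-space model. Received level under spherical
# spreading plus linear excess attenuation:
#     RL(r) = s - 20 log10(r) - A_e r - alpha r
# masking radius r* solves RL(r*) = n + threshold, communication volume is a
# hemisphere (2/3) pi r^3, and the per-minute time-volume is
# d * rate * (2/3) pi r^3.

#' Propagation parameters for the active-space model
#'
#' @param excess_attenuation Excess attenuation A_e in dB/m beyond spherical
#'   spreading; default 0.2 dB/m (median over open field and deciduous forest
#'   conditions in the 1-4.5 kHz band).
#' @param atmospheric_absorption Optional linear atmospheric absorption in
#'   dB/m; negligible at frog-call range, default 0.
#' @param reference_distance Distance (m) at which source level is referenced;
#'   1 m by convention.
#' @param detection_threshold Level in dB by which a call must exceed the
#'   background noise to count as detected. Default 0 dB (a conservative
#'   masking threshold); hylid psychoacoustics suggest values up to ~30 dB.
#' @return Object of class `propagation_params`.
#' @export
propagation_params <- function(excess_attenuation = 0.2,
                               atmospheric_absorption = 0,
                               reference_distance = 1,
                               detection_threshold = 0) {
  if (excess_attenuation < 0) stop("excess_attenuation must be >= 0")
  if (atmospheric_absorption < 0) stop("atmospheric_absorption must be >= 0")
  if (detection_threshold < 0) stop("detection_threshold must be >= 0")
  stopifnot(reference_distance > 0)
  structure(list(excess_attenuation = excess_attenuation,
                 atmospheric_absorption = atmospheric_absorption,
                 reference_distance = reference_distance,
                 detection_threshold = detection_threshold),
            class = "propagation_params")
}

#' Received level at distance r
#'
#' `RL = s - 20 log10(r) - (A_e + alpha) r`, strictly decreasing in r.
#'
#' @param s Source level in dB re 20 uPa at 1 m (vectorized).
#' @param r Distance in m (> 0, vectorized).
#' @param params A [propagation_params()].
#' @return Received level in dB re 20 uPa.
#' @examples
#' received_level(90, 10)  # 90 - 20 - 2 = 68 dB
#' @export
received_level <- function(s, r, params = propagation_params()) {
  if (any(r <= 0)) stop("distance must be > 0")
  a <- params$excess_attenuation + params$atmospheric_absorption
  s - 20 * log10(r) - a * r
}

# Principal-branch Lambert W for x >= 0 (Halley iteration, ~1e-15 accuracy).
.lambert_w0 <- function(x) {
  stopifnot(all(x >= 0))
  w <- ifelse(x < exp(1), x / (1 + x), log(pmax(x, 1)) - log(pmax(log(pmax(x, exp(1))), 1)))
  for (i in 1:50) {
    e <- exp(w)
    f <- w * e - x
    wn <- w - f / (e * (w + 1) - (w + 2) * f / (2 * w + 2))
    if (all(abs(wn - w) <= 1e-15 * pmax(abs(wn), 1))) { w <- wn; break }
    w <- wn
  }
  w
}

#' Masking radius: distance at which a call drops to the noise floor
#'
#' Solves `received_level(s, r) = n + detection_threshold` for the unique
#' positive root. With `a = A_e + alpha > 0` the solution is closed-form via
#' the principal Lambert W branch: writing `delta = (s - n - threshold) / 20`,
#' `k = a ln(10) / 20`, then `r = W(k 10^delta) / k`; with `a = 0` it reduces
#' to the spherical-spreading limit `r = 10^delta`. Since RL diverges to
#' +Inf as r -> 0+, a root always exists for finite inputs. Radii below the
#' 1 m reference are returned as-is, flagged via attribute `sub_reference`.
#'
#' @param s Source level dB re 20 uPa at 1 m (vectorized).
#' @param n Background noise level dB re 20 uPa (vectorized).
#' @param params A [propagation_params()].
#' @return Radius in m; attribute `sub_reference` is a logical vector marking
#'   radii < reference distance.
#' @examples
#' masking_radius(90, 50, propagation_params(excess_attenuation = 0))  # 100 m
#' @export
masking_radius <- function(s, n, params = propagation_params()) {
  if (any(!is.finite(s)) || any(!is.finite(n)))
    stop("s and n must be finite")
  a <- params$excess_attenuation + params$atmospheric_absorption
  delta <- (s - n - params$detection_threshold) / 20
  if (a == 0) {
    r <- 10^delta
  } else {
    k <- a * log(10) / 20
    r <- .lambert_w0(k * 10^delta) / k
  }
  attr(r, "sub_reference") <- r < params$reference_distance
  r
}

#' Hemispherical communication volume
#'
#' `(2/3) pi r^3`: the half-space dome around a frog calling at the water
#' surface.
#'
#' @param r Radius in m (>= 0, vectorized).
#' @return Volume in m^3.
#' @export
hemisphere_volume <- function(r) {
  if (any(r < 0)) stop("radius must be >= 0")
  (2 / 3) * pi * r^3
}

#' Per-minute spatiotemporal communication time-volume
#'
#' `time_volume = d * rate * (2/3) pi r^3` in m^3 s per minute of calling:
#' the volume insonified by each call, weighted by how long and how often the
#' animal calls in a minute.
#'
#' @param d Call duration in s (>= 0).
#' @param rate Call rate in calls/min (>= 0).
#' @param r Masking radius in m.
#' @return Time-volume in m^3 s / min.
#' @examples
#' time_volume(0.2, 30, 1)  # 12.566
#' @export
time_volume <- function(d, rate, r) {
  if (any(d < 0) || any(rate < 0)) stop("duration and rate must be >= 0")
  d * rate * hemisphere_volume(r)
}

#' Communication space summary for one or more frogs
#'
#' @param s Source level(s) dB re 20 uPa at 1 m.
#' @param n Noise level(s) dB re 20 uPa.
#' @param d Call duration(s) s.
#' @param rate Call rate(s) calls/min.
#' @param params A [propagation_params()].
#' @return `data.frame` with columns `s, n, radius_m, volume_m3,
#'   time_volume`, one row per frog.
#' @export
comm_space <- function(s, n, d, rate, params = propagation_params()) {
  r <- masking_radius(s, n, params)
  data.frame(s = s, n = n, radius_m = as.numeric(r),
             volume_m3 = hemisphere_volume(as.numeric(r)),
             time_volume = time_volume(d, rate, as.numeric(r)))
}

#' Acoustic-barrier specification
#'
#' A roadside barrier is modeled as a single insertion loss subtracted from
#' the ambient noise level. The distance-based description (e.g. vegetative
#' barriers attenuating ~5 dB per 30.48 m from the barrier) is retained as
#' metadata only.
#'
#' @param insertion_loss Noise reduction in dB (>= 0).
#' @param per_distance_db,per_distance_m Descriptive basis: dB per metres of
#'   distance from the barrier (default 5 dB per 30.48 m).
#' @return Object of class `barrier_spec`.
#' @export
barrier_spec <- function(insertion_loss, per_distance_db = 5,
                         per_distance_m = 30.48) {
  if (insertion_loss < 0) stop("insertion_loss must be >= 0")
  structure(list(insertion_loss = insertion_loss,
                 per_distance_db = per_distance_db,
                 per_distance_m = per_distance_m),
            class = "barrier_spec")
}

#' Barrier scenario: change in masking radius from a noise barrier
#'
#' Computes the masking radius before and after reducing the ambient noise
#' by the barrier's insertion loss.
#'
#' @param s Source level dB re 20 uPa at 1 m.
#' @param n Ambient noise dB re 20 uPa (pre-barrier).
#' @param barrier A [barrier_spec()].
#' @param params A [propagation_params()].
#' @return `data.frame` with `radius_before_m`, `radius_after_m`, `delta_m`.
#' @export
barrier_scenario <- function(s, n, barrier, params = propagation_params()) {
  stopifnot(inherits(barrier, "barrier_spec"))
  before <- as.numeric(masking_radius(s, n, params))
  after <- as.numeric(masking_radius(s, n - barrier$insertion_loss, params))
  data.frame(radius_before_m = before, radius_after_m = after,
             delta_m = after - before)
}
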