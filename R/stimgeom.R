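# Stimulus geometry for the object-motion detection design: observer
# trajectory, the motion-parallax/disparity cue-conflict split around a
# pedestal depth, the canonical condition table, and the ray-trace of the
# dynamic object onto the disparity-defined depth plane.

#' Standard cue-conflict values (deg of equivalent disparity)
#'
#' The seven depth-conflict (`delta depth = d_MP - d_BD`) values used in the
#' detection task, the nine-depth grid for stationary objects, and the fixed
#' pedestal depth about which the conflict is applied.
#'
#' @return Numeric vector (or scalar for the pedestal).
#' @export
standard_delta_set <- function() c(-1.53, -0.57, -0.21, 0, 0.21, 0.57, 1.53)

#' @rdname standard_delta_set
#' @export
standard_stationary_depths <- function() seq(-1.6, 1.6, by = 0.4)

#' @rdname standard_delta_set
#' @export
standard_pedestal <- function() -0.45

#' Self-motion envelope specification
#'
#' The lateral platform trajectory is a sinusoid multiplied by a flat-topped
#' Gaussian envelope `G(t) = exp(-(t - t0)^n / sigma^n)` with a large even
#' exponent `n`, which smooths stimulus onset and offset while leaving the
#' middle of the trajectory essentially unattenuated.
#'
#' @param t0 Envelope center (s).
#' @param sigma Envelope width (s), positive.
#' @param n Even integer exponent, at least 2.
#' @param amplitude_cm Peak lateral displacement (cm).
#' @param frequency_hz Sinusoid frequency (Hz).
#' @param phase_deg Starting phase, 0 or 180; phase 180 negates the trace.
#' @param duration_s Stimulus duration (s).
#' @return A list of class `"motion_envelope"`.
#' @export
motion_envelope_spec <- function(t0 = 1.0, sigma = 0.92, n = 22,
                                 amplitude_cm = 2.8, frequency_hz = 0.5,
                                 phase_deg = 0, duration_s = 2.1) {
  stop_if_not_scalar(t0, "t0")
  stop_if_not_scalar(sigma, "sigma")
  stop_if_not_scalar(n, "n")
  if (sigma <= 0) stop("`sigma` must be positive")
  if (n < 2 || n %% 2 != 0) stop("`n` must be an even integer >= 2")
  if (!phase_deg %in% c(0, 180)) stop("`phase_deg` must be 0 or 180")
  if (duration_s <= 0) stop("`duration_s` must be positive")
  structure(
    list(t0 = t0, sigma = sigma, n = as.integer(n),
         amplitude_cm = amplitude_cm, frequency_hz = frequency_hz,
         phase_deg = phase_deg, duration_s = duration_s),
    class = "motion_envelope"
  )
}

#' Evaluate the flat-topped Gaussian envelope
#'
#' @param t Time(s) in seconds; vectorized.
#' @param env A [motion_envelope_spec()].
#' @return `exp(-(t - t0)^n / sigma^n)`, in (0, 1]; exactly 1 at `t = t0`.
#' @export
motion_envelope <- function(t, env = motion_envelope_spec()) {
  stopifnot(inherits(env, "motion_envelope"))
  exp(-(abs(t - env$t0) / env$sigma)^env$n)
}

#' Platform position and velocity over time
#'
#' Position is `amplitude * sin(2*pi*f*t + phase) * G(t)`; velocity is the
#' analytic derivative of that product.
#'
#' @param times Sample times (s), within `[0, duration_s]`.
#' @param env A [motion_envelope_spec()].
#' @return Data frame with `time_s`, `position_cm`, `velocity_cm_s`.
#' @export
platform_trajectory <- function(times, env = motion_envelope_spec()) {
  stopifnot(inherits(env, "motion_envelope"))
  if (any(times < 0 - 1e-12 | times > env$duration_s + 1e-12)) {
    stop("`times` must lie within [0, duration_s]")
  }
  w <- 2 * pi * env$frequency_hz
  ph <- env$phase_deg * pi / 180
  g <- motion_envelope(times, env)
  u <- (times - env$t0) / env$sigma
  gprime <- -(env$n / env$sigma) * u^(env$n - 1L) * g
  s <- sin(w * times + ph)
  pos <- env$amplitude_cm * s * g
  vel <- env$amplitude_cm * (w * cos(w * times + ph) * g + s * gprime)
  data.frame(time_s = times, position_cm = pos, velocity_cm_s = vel)
}

#' Split a pedestal depth into cue-specific depths
#'
#' The depth conflict is applied symmetrically about the pedestal:
#' `d_MP = pedestal + delta/2`, `d_BD = pedestal - delta/2`, so that
#' `d_MP - d_BD` equals the requested conflict exactly.
#'
#' @param pedestal Pedestal depth (deg equivalent disparity), `|pedestal| <= 2`.
#' @param delta_depth Depth conflict `d_MP - d_BD` (deg); vectorized.
#' @return List with numeric `d_mp` and `d_bd`.
#' @export
split_pedestal <- function(pedestal, delta_depth) {
  stop_if_not_scalar(pedestal, "pedestal")
  if (abs(pedestal) > 2) stop("`pedestal` must lie within [-2, 2] deg")
  list(d_mp = pedestal + delta_depth / 2,
       d_bd = pedestal - delta_depth / 2)
}

#' Build the canonical in-RF condition table
#'
#' One dynamic-object condition per depth-conflict value (split symmetrically
#' about the pedestal) plus one stationary-object condition per stationary
#' depth. With the standard design (7 conflict values, 9 stationary depths)
#' this yields the 16 unique in-receptive-field stimulus conditions.
#'
#' @param delta_set Depth-conflict values (deg), no duplicates.
#' @param stationary_depths Stationary-object depths (deg), no duplicates.
#' @param pedestal Pedestal depth (deg).
#' @return Data frame with columns `condition_id`, `kind`
#'   (`"dynamic"`/`"stationary"`), `d_bd_deg`, `d_mp_deg`, `delta_depth_deg`,
#'   `pedestal_deg`; dynamic rows first in ascending conflict, then stationary
#'   rows in ascending depth.
#' @export
build_condition_table <- function(delta_set = standard_delta_set(),
                                  stationary_depths = standard_stationary_depths(),
                                  pedestal = standard_pedestal()) {
  if (length(delta_set) == 0L || length(stationary_depths) == 0L) {
    stop("`delta_set` and `stationary_depths` must be non-empty")
  }
  if (anyDuplicated(delta_set)) stop("duplicate values in `delta_set`")
  if (anyDuplicated(stationary_depths)) stop("duplicate values in `stationary_depths`")
  delta_set <- sort(delta_set)
  stationary_depths <- sort(stationary_depths)
  sp <- split_pedestal(pedestal, delta_set)
  if (any(abs(c(sp$d_mp, sp$d_bd, stationary_depths)) > 2 + 1e-12)) {
    stop("all depths must lie within [-2, 2] deg")
  }
  dyn <- data.frame(
    condition_id = sprintf("dyn_%+.2f", delta_set),
    kind = "dynamic",
    d_bd_deg = sp$d_bd,
    d_mp_deg = sp$d_mp,
    delta_depth_deg = delta_set,
    pedestal_deg = pedestal,
    stringsAsFactors = FALSE
  )
  sta <- data.frame(
    condition_id = sprintf("sta_%+.2f", stationary_depths),
    kind = "stationary",
    d_bd_deg = stationary_depths,
    d_mp_deg = stationary_depths,
    delta_depth_deg = 0,
    pedestal_deg = pedestal,
    stringsAsFactors = FALSE
  )
  out <- rbind(dyn, sta)
  rownames(out) <- NULL
  out
}

#' Viewing geometry
#'
#' @param distance_cm Viewing distance to the screen (cm), positive.
#' @param interocular_cm Interocular separation (cm).
#' @param screen_size_deg Display extent (deg), informational.
#' @param object_eccentricity_deg Initial screen eccentricity of the object
#'   along the translation axis (deg).
#' @return A list of class `"viewing_geometry"`.
#' @export
viewing_geometry <- function(distance_cm = 30, interocular_cm = 3.0,
                             screen_size_deg = 90, object_eccentricity_deg = 0) {
  if (distance_cm <= 0) stop("`distance_cm` must be positive")
  if (interocular_cm <= 0) stop("`interocular_cm` must be positive")
  structure(
    list(distance_cm = distance_cm, interocular_cm = interocular_cm,
         screen_size_deg = screen_size_deg,
         object_eccentricity_deg = object_eccentricity_deg),
    class = "viewing_geometry"
  )
}

#' Convert between equivalent disparity and viewing distance
#'
#' Small-angle binocular geometry: an equivalent disparity `d` (deg, negative =
#' nearer than fixation) corresponds to a distance `Z` along the line of sight
#' with `d = I * (1/D - 1/Z)` (radians), where `D` is the fixation distance and
#' `I` the interocular separation.
#'
#' @param disparity_deg Equivalent disparity (deg); vectorized.
#' @param distance_cm Distance (cm); vectorized.
#' @param geom A [viewing_geometry()].
#' @return Distance in cm, or disparity in deg.
#' @export
disparity_to_distance <- function(disparity_deg, geom = viewing_geometry()) {
  stopifnot(inherits(geom, "viewing_geometry"))
  d_rad <- disparity_deg * pi / 180
  denom <- 1 / geom$distance_cm - d_rad / geom$interocular_cm
  if (any(denom <= 0)) {
    stop("disparity implies a point at or behind the eye (Z <= 0)")
  }
  1 / denom
}

#' @rdname disparity_to_distance
#' @export
distance_to_disparity <- function(distance_cm, geom = viewing_geometry()) {
  stopifnot(inherits(geom, "viewing_geometry"))
  if (any(distance_cm <= 0)) stop("`distance_cm` must be positive")
  geom$interocular_cm * (1 / geom$distance_cm - 1 / distance_cm) * 180 / pi
}

# perspective projection of a world point (lateral X at distance Z) onto the
# screen plane, viewed from a camera at lateral position `cam`; returns the
# lateral screen-intersection coordinate in cm
.project_to_screen <- function(x_world, z_world, cam, distance_cm) {
  cam + (x_world - cam) * distance_cm / z_world
}

#' Project a world-stationary object
#'
#' Screen trace of a world-fixed object at a given equivalent-disparity depth,
#' seen from each camera (eye) position of the translation trajectory.
#'
#' @param depth_deg Object depth (deg equivalent disparity).
#' @param camera_positions_cm Lateral camera positions (cm), e.g. the
#'   `position_cm` column from [platform_trajectory()].
#' @param geom A [viewing_geometry()].
#' @return Data frame with `frame`, `camera_cm`, `screen_x_cm`,
#'   `screen_x_deg` (angular position relative to the current eye), and
#'   `disparity_deg`.
#' @export
project_stationary_object <- function(depth_deg, camera_positions_cm,
                                      geom = viewing_geometry()) {
  z <- disparity_to_distance(depth_deg, geom)
  x0 <- tan(geom$object_eccentricity_deg * pi / 180) * geom$distance_cm
  x_world <- x0 * z / geom$distance_cm # world point projecting to x0 from cam 0
  sx <- .project_to_screen(x_world, z, camera_positions_cm, geom$distance_cm)
  data.frame(
    frame = seq_along(camera_positions_cm),
    camera_cm = camera_positions_cm,
    screen_x_cm = sx,
    screen_x_deg = atan2(sx - camera_positions_cm, geom$distance_cm) * 180 / pi,
    disparity_deg = depth_deg
  )
}

#' Ray-trace the dynamic object onto the disparity-defined depth plane
#'
#' The dynamic object's image motion is that of a world-fixed object at the
#' motion-parallax depth `d_MP`: on each frame, the world point at `d_MP` is
#' projected from the current camera position, and that screen position is
#' re-projected onto the plane at the disparity-defined depth `d_BD`, where the
#' object is rendered (so its binocular disparity equals `d_BD` on every
#' frame). Monocularly, the trace is indistinguishable from a stationary
#' object at `d_MP`; when `d_MP == d_BD` it is identical to a stationary
#' object at that depth.
#'
#' @param d_mp Motion-parallax depth (deg equivalent disparity).
#' @param d_bd Binocular-disparity depth (deg equivalent disparity).
#' @param camera_positions_cm Lateral camera positions (cm).
#' @param geom A [viewing_geometry()].
#' @return Data frame with `frame`, `camera_cm`, `screen_x_cm`, `screen_x_deg`,
#'   `world_x_cm` (the rendered point on the `d_BD` plane, which moves in the
#'   world when `d_MP != d_BD`), and `disparity_deg` (constant `d_BD`).
#' @export
raytrace_dynamic_object <- function(d_mp, d_bd, camera_positions_cm,
                                    geom = viewing_geometry()) {
  z_bd <- disparity_to_distance(d_bd, geom)
  proj <- project_stationary_object(d_mp, camera_positions_cm, geom)
  world_x <- camera_positions_cm +
    (proj$screen_x_cm - camera_positions_cm) * z_bd / geom$distance_cm
  data.frame(
    frame = proj$frame,
    camera_cm = proj$camera_cm,
    screen_x_cm = proj$screen_x_cm,
    screen_x_deg = proj$screen_x_deg,
    world_x_cm = world_x,
    disparity_deg = d_bd
  )
}
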