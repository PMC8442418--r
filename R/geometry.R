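# Closed-form scattering and path-length geometry for a pencil beam through
# a spherical object. Conventions used package-wide:
#   * theta is the HALF scattering angle; the full scattering angle is 2*theta.
#   * lengths (object radii, distances, chords) are in cm; wavelength in nm;
#     scattering vectors q in nm^-1. tan/sin of angles are dimensionless so
#     the cm/nm mix never crosses an equation.

#' Photon wavelength from beam energy
#'
#' Converts a monoenergetic X-ray beam energy to its photon wavelength via
#' lambda = hc / E with hc = 1.23984193 keV nm.
#'
#' @param energy_keV beam energy in keV (> 0).
#' @return wavelength in nm.
#' @examples
#' wavelength_from_energy(60) # ~0.0207 nm
#' @export
wavelength_from_energy <- function(energy_keV) {
  if (any(!is.finite(energy_keV)) || any(energy_keV <= 0)) {
    stop("energy_keV must be finite and > 0")
  }
  1.23984193 / energy_keV
}

#' Beam geometry for one candidate pencil-beam path
#'
#' Bundles the beam parameters that define a single candidate path: photon
#' wavelength (or energy), mean target-to-detector distance `L0`, the
#' incidence angle used by elliptical targets, and the impact parameter
#' (perpendicular offset of the beam line from the object's center).
#'
#' @param L0 mean target-to-detector distance in cm (> 0).
#' @param energy_keV beam energy in keV; exactly one of `energy_keV` and
#'   `wavelength` must be given.
#' @param wavelength photon wavelength in nm.
#' @param incidence_angle beam incidence angle in radians (polar angle of the
#'   beam relative to a target's own axes).
#' @param impact_parameter perpendicular distance of the beam line from the
#'   object center, cm (>= 0).
#' @return an object of class `beam_geometry`.
#' @examples
#' beam_geometry(L0 = 20, energy_keV = 60)
#' @export
beam_geometry <- function(L0, energy_keV = NULL, wavelength = NULL,
                          incidence_angle = 0, impact_parameter = 0) {
  if (is.null(wavelength) == is.null(energy_keV)) {
    stop("give exactly one of 'energy_keV' or 'wavelength'")
  }
  if (is.null(wavelength)) wavelength <- wavelength_from_energy(energy_keV)
  stopifnot(is.finite(wavelength), wavelength > 0,
            is.finite(L0), L0 > 0,
            is.finite(incidence_angle),
            is.finite(impact_parameter), impact_parameter >= 0)
  structure(
    list(wavelength = wavelength, L0 = L0,
         incidence_angle = incidence_angle,
         impact_parameter = impact_parameter),
    class = "beam_geometry"
  )
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf(
    "<beam_geometry> lambda = %.6g nm, L0 = %g cm, phi = %g rad, b = %g cm\n",
    x$wavelength, x$L0, x$incidence_angle, x$impact_parameter))
  invisible(x)
}

#' Spherical object (attenuating medium container)
#'
#' @param R_o object radius in cm (> 0).
#' @return an object of class `spherical_object`.
#' @export
spherical_object <- function(R_o) {
  stopifnot(is.finite(R_o), R_o > 0)
  structure(list(R_o = R_o), class = "spherical_object")
}

#' Spherical target embedded in an object
#'
#' @param r_t target radius in cm (> 0).
#' @param center_offset signed distance of the target center from the object
#'   center along the beam axis, cm. When embedded in a `spherical_object` of
#'   radius `R_o`, `abs(center_offset) + r_t <= R_o` must hold.
#' @return an object of class `spherical_target`.
#' @export
spherical_target <- function(r_t, center_offset = 0) {
  stopifnot(is.finite(r_t), r_t > 0, is.finite(center_offset))
  structure(list(r_t = r_t, center_offset = center_offset),
            class = c("spherical_target", "scatter_target"))
}

#' Elliptical target
#'
#' An elliptical (2D section of an ellipsoidal) target whose radius seen by
#' the beam depends on the incidence angle through the polar form of the
#' ellipse equation (see [ellipse_radius()]).
#'
#' @param a minor semi-axis, cm (0 < a <= b).
#' @param b major semi-axis, cm.
#' @param orientation rotation of the ellipse's own axes in radians.
#' @return an object of class `elliptical_target`.
#' @export
elliptical_target <- function(a, b, orientation = 0) {
  stopifnot(is.finite(a), is.finite(b), a > 0, b > 0, a <= b,
            is.finite(orientation))
  structure(list(a = a, b = b, orientation = orientation),
            class = c("elliptical_target", "scatter_target"))
}

#' Effective target radius seen by a beam
#'
#' For a spherical target this is its radius; for an elliptical target it is
#' the polar ellipse radius at the beam's incidence angle relative to the
#' ellipse orientation.
#'
#' @param target a `spherical_target` or `elliptical_target`.
#' @param incidence_angle beam incidence angle, radians.
#' @return effective radius in cm.
#' @export
effective_radius <- function(target, incidence_angle = 0) {
  UseMethod("effective_radius")
}

#' @export
effective_radius.spherical_target <- function(target, incidence_angle = 0) {
  target$r_t
}

#' @export
effective_radius.elliptical_target <- function(target, incidence_angle = 0) {
  ellipse_radius(target$a, target$b, incidence_angle - target$orientation)
}

#' Scattering vector magnitude
#'
#' q = 4 pi sin(theta) / lambda, with `theta_half` the half scattering angle
#' (the full scattering angle is `2 * theta_half`).
#'
#' @param theta_half half scattering angle in radians, in `[0, pi/2]`.
#' @param wavelength photon wavelength in nm (> 0).
#' @return q in nm^-1.
#' @examples
#' scattering_vector(0.022, wavelength_from_energy(60))
#' @export
scattering_vector <- function(theta_half, wavelength) {
  if (any(!is.finite(wavelength)) || any(wavelength <= 0)) {
    stop("wavelength must be finite and > 0")
  }
  if (any(theta_half < 0) || any(theta_half > pi / 2)) {
    stop("theta_half must lie in [0, pi/2]")
  }
  4 * pi * sin(theta_half) / wavelength
}

#' Half scattering angle from a scattering vector
#'
#' Inverse of [scattering_vector()]: theta = asin(q lambda / (4 pi)).
#'
#' @param q scattering vector in nm^-1 (>= 0, within the physical range).
#' @param wavelength photon wavelength in nm.
#' @return half scattering angle in radians.
#' @export
half_angle_from_q <- function(q, wavelength) {
  stopifnot(all(q >= 0), all(wavelength > 0))
  s <- q * wavelength / (4 * pi)
  if (any(s > 1)) stop("q is beyond the physical maximum 4*pi/lambda")
  asin(s)
}

#' Relative scattering-vector spread from target size
#'
#' Geometric relative uncertainty in q caused by the spread of scatter-event
#' distances to the detector across a target of radius `r_t` centered at mean
#' target-to-detector distance `L0`:
#'
#' Delta q / q = 2 - 2 / ( sin(theta) * sqrt( ((L0 + r_t) / (L0 tan(theta)))^2 + 1 ) )
#'
#' It vanishes exactly for a point target and grows with `r_t` (wider targets
#' smear more) and with decreasing `L0` (targets closer to the detector smear
#' more).
#'
#' @param theta_half half scattering angle in radians, in (0, pi/2).
#' @param L0 mean target-to-detector distance, cm (> 0).
#' @param r_t target radius, cm (>= 0).
#' @return dimensionless Delta q / q (>= 0).
#' @examples
#' relative_q_spread(0.022, L0 = 20, r_t = 2) # ~ 2*2/22
#' @export
relative_q_spread <- function(theta_half, L0, r_t) {
  stopifnot(all(L0 > 0), all(r_t >= 0))
  if (any(theta_half <= 0) || any(theta_half >= pi / 2)) {
    stop("theta_half must lie strictly inside (0, pi/2)")
  }
  2 - 2 / (sin(theta_half) *
             sqrt(((L0 + r_t) / (L0 * tan(theta_half)))^2 + 1))
}

#' Chord length of a circle from the subtended central angle
#'
#' d = 2 R_o sin(C / 2), the path length across a spherical object when the
#' entry and exit points subtend an angle `C` at the center.
#'
#' @param R_o object radius, cm (> 0).
#' @param C subtended central angle, radians, in `[0, 2*pi]`.
#' @return chord length in cm.
#' @export
chord_length_subtended <- function(R_o, C) {
  stopifnot(all(R_o > 0))
  if (any(C < 0) || any(C > 2 * pi)) stop("C must lie in [0, 2*pi]")
  2 * R_o * sin(C / 2)
}

#' Chord length of a circle from the beam impact parameter
#'
#' Equivalent parametrization of the same chord: a beam line at perpendicular
#' distance `impact_parameter` from the center crosses the circle along
#' d = 2 sqrt(R_o^2 - b^2). A beam with `impact_parameter > R_o` misses the
#' object; the returned length is then 0 and carries attribute
#' `misses_object = TRUE`.
#'
#' @param R_o object radius, cm (> 0).
#' @param impact_parameter perpendicular beam offset, cm (>= 0).
#' @return chord length in cm, with logical attribute `misses_object`.
#' @export
chord_length_impact <- function(R_o, impact_parameter) {
  stopifnot(all(R_o > 0), all(impact_parameter >= 0))
  misses <- impact_parameter > R_o
  d <- ifelse(misses, 0, 2 * sqrt(pmax(R_o^2 - impact_parameter^2, 0)))
  attr(d, "misses_object") <- misses
  d
}

#' Polar radius of an ellipse
#'
#' r_e^2 = (a b)^2 / (b^2 cos(phi)^2 + a^2 sin(phi)^2): the radius of an
#' ellipse with semi-axes `a` (along phi = 0) and `b` (along phi = pi/2) seen
#' from its center at polar angle `phi`. This is the effective radius of an
#' elliptical target for a beam at incidence angle `phi`.
#'
#' @param a semi-axis along phi = 0, cm (> 0).
#' @param b semi-axis along phi = pi/2, cm (> 0).
#' @param phi polar angle, radians.
#' @return ellipse radius in cm, between `min(a, b)` and `max(a, b)`.
#' @export
ellipse_radius <- function(a, b, phi) {
  stopifnot(all(a > 0), all(b > 0))
  sqrt((a * b)^2 / (b^2 * cos(phi)^2 + a^2 * sin(phi)^2))
}

#' Total path length for a single scatter event in a spherical object
#'
#' An incoming ray enters the object along a chord with the given impact
#' parameter, travels `entry_depth` before scattering, and is deflected by
#' the full scattering angle `two_theta`. The exit segment from the scatter
#' point to the object boundary is solved with the law of sines in the
#' triangle formed by the scatter point, the object center, and the exit
#' point. The total path length is `entry_depth + exit segment`.
#'
#' Because SAXS angles are small, this total stays within a fraction of a
#' percent of the straight chord for any scatter location, which justifies
#' using the unscattered-beam path length in the attenuation model.
#'
#' @param entry_depth distance traveled into the object before scattering,
#'   cm; must lie within `[0, chord]`.
#' @param two_theta full scattering angle, radians (small, < ~0.2).
#' @param R_o object radius, cm.
#' @param impact_parameter perpendicular beam offset, cm (in `[0, R_o]`).
#' @return total path length in cm.
#' @export
scatter_event_path_length <- function(entry_depth, two_theta, R_o,
                                      impact_parameter = 0) {
  stopifnot(R_o > 0, impact_parameter >= 0, impact_parameter <= R_o,
            two_theta >= 0)
  chord <- 2 * sqrt(R_o^2 - impact_parameter^2)
  if (entry_depth < 0 || entry_depth > chord) {
    stop("entry_depth must lie within [0, chord]; scatter point outside object")
  }
  # beam travels along +x at height y = impact_parameter; object center at origin
  half <- chord / 2
  p <- c(-half + entry_depth, impact_parameter)   # scatter point
  d <- sqrt(sum(p^2))                             # scatter point to center
  u <- c(cos(two_theta), sin(two_theta))          # deflected ray direction
  if (d < 1e-15) return(entry_depth + R_o)        # scatter at the very center
  to_center <- -p / d
  cos_alpha <- max(-1, min(1, sum(u * to_center)))
  sin_alpha <- sqrt(max(0, 1 - cos_alpha^2))
  if (sin_alpha < 1e-12) {
    exit_seg <- if (cos_alpha > 0) d + R_o else R_o - d
  } else {
    # law of sines in triangle (scatter point, center, exit point):
    # sin(angle at exit)/d = sin(alpha)/R_o; third angle closes the triangle
    sin_exit <- d * sin_alpha / R_o
    angle_center <- pi - acos(cos_alpha) - asin(min(1, sin_exit))
    exit_seg <- R_o * sin(angle_center) / sin_alpha
  }
  entry_depth + exit_seg
}

#' Apparent scattering vector for a displaced scatter event
#'
#' A scatter event at true distance `L_event` from the detector produces a
#' ring of radius `L_event * tan(2 theta_true)`. A detector that assumes all
#' scatter originated at the mean distance `L0` assigns that ring the
#' apparent half-angle `atan(ring / L0) / 2` and hence an apparent q. Events
#' closer to the detector (`L_event < L0`) are pushed to smaller apparent q,
#' events farther away to larger apparent q; at `L_event = L0` the mapping is
#' the identity. This is the per-slice mechanism behind the q smearing of an
#' extended target.
#'
#' @param L_event true scatter-event-to-detector distance, cm (> 0).
#' @param q_true true scattering vector, nm^-1.
#' @param L0 assumed (mean) target-to-detector distance, cm (> 0).
#' @param wavelength photon wavelength, nm.
#' @return apparent scattering vector, nm^-1.
#' @export
apparent_q <- function(L_event, q_true, L0, wavelength) {
  stopifnot(all(L_event > 0), all(L0 > 0))
  theta_true <- half_angle_from_q(q_true, wavelength)
  ring <- L_event * tan(2 * theta_true)
  theta_apparent <- atan(ring / L0) / 2
  scattering_vector(theta_apparent, wavelength)
}

# inverse of apparent_q in L_event: the event distance whose ring lands at
# q_apparent on a detector calibrated for L0 (used to invert the slice-to-q
# mapping when accumulating the step profile)
event_distance_for_q <- function(q_apparent, q_true, L0, wavelength) {
  theta_apparent <- half_angle_from_q(q_apparent, wavelength)
  theta_true <- half_angle_from_q(q_true, wavelength)
  L0 * tan(2 * theta_apparent) / tan(2 * theta_true)
}
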