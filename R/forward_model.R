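# Forward model: unsmeared step scattering profile from the attenuated
# scatterer-density integral, then triangular detector-blur convolution.

#' Medium and target scattering properties
#'
#' @param mu linear attenuation coefficient of the object (and target), cm^-1.
#' @param rho_t volumetric number density of scatterers inside the target,
#'   cm^-3.
#' @param sigma differential scattering cross-section per scatterer, cm^2.
#' @return an object of class `medium_properties`.
#' @examples
#' medium_properties(mu = 0.30, rho_t = 5.5e5, sigma = 5e-23)
#' @export
medium_properties <- function(mu, rho_t, sigma) {
  vals <- c(mu = mu, rho_t = rho_t, sigma = sigma)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("mu, rho_t and sigma must be finite and >= 0")
  }
  structure(list(mu = mu, rho_t = rho_t, sigma = sigma),
            class = "medium_properties")
}

#' Scatterer density sampled along the beam within the target
#'
#' Positions are measured along the beam relative to the target center
#' (negative = source side, positive = detector side).
#'
#' @param positions strictly increasing sample points, cm.
#' @param densities scatterer number density at each point, cm^-3 (>= 0).
#' @return an object of class `density_profile`.
#' @export
density_profile <- function(positions, densities) {
  stopifnot(length(positions) == length(densities), length(positions) >= 2,
            all(is.finite(positions)), all(is.finite(densities)))
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  if (any(densities < 0)) stop("densities must be >= 0")
  structure(list(positions = positions, densities = densities),
            class = "density_profile")
}

#' Relative scattered intensity of a target along a beam path
#'
#' Attenuated scatterer-density integral
#' `I/I0 = sigma * exp(-mu * l) * integral(rho_t(x) dx)`,
#' where `l` is the total path length of the beam through the object.
#' Because scattering angles are small, the scattered ray's path length is
#' within a fraction of a percent of the unscattered beam's, so a single
#' exponential with the straight-through `l` is used. For a uniform target of
#' radius `r_t` the density integral is `rho_t * 2 * r_t`; a non-uniform
#' target is integrated by trapezoidal quadrature over `density`.
#'
#' @param medium a [medium_properties()].
#' @param path_length total beam path length through the object, cm; must be
#'   at least the extent of the target along the beam.
#' @param r_t target radius for the uniform-density case, cm.
#' @param density optional [density_profile()] overriding the uniform case.
#' @return dimensionless relative intensity I/I0.
#' @examples
#' m <- medium_properties(0.30, 5.5e5, 5e-23)
#' relative_intensity(m, path_length = 20, r_t = 0.5)
#' @export
relative_intensity <- function(medium, path_length, r_t = NULL, density = NULL) {
  stopifnot(inherits(medium, "medium_properties"),
            is.finite(path_length), path_length >= 0)
  if (is.null(density)) {
    if (is.null(r_t)) stop("give either 'r_t' (uniform density) or 'density'")
    stopifnot(r_t >= 0)
    if (path_length < 2 * r_t - 1e-12) {
      stop("path_length must cover the target extent (>= 2*r_t)")
    }
    dens_integral <- medium$rho_t * 2 * r_t
  } else {
    stopifnot(inherits(density, "density_profile"))
    extent <- diff(range(density$positions))
    if (path_length < extent - 1e-12) {
      stop("path_length must cover the density support")
    }
    dens_integral <- pracma::trapz(density$positions, density$densities)
  }
  medium$sigma * exp(-medium$mu * path_length) * dens_integral
}

#' Scattering profile container
#'
#' Relative intensity sampled on a strictly increasing scattering-vector grid.
#'
#' @param q_grid strictly increasing q samples, nm^-1.
#' @param intensity non-negative relative intensity at each q.
#' @return an object of class `scattering_profile`.
#' @export
scattering_profile <- function(q_grid, intensity) {
  stopifnot(length(q_grid) == length(intensity), length(q_grid) >= 2,
            all(is.finite(q_grid)), all(is.finite(intensity)))
  if (any(diff(q_grid) <= 0)) stop("q_grid must be strictly increasing")
  if (any(intensity < 0)) stop("intensity must be >= 0")
  structure(list(q_grid = q_grid, intensity = intensity),
            class = "scattering_profile")
}

#' @export
print.scattering_profile <- function(x, ...) {
  cat(sprintf("<scattering_profile> %d samples, q in [%.4g, %.4g] nm^-1, peak %.4g\n",
              length(x$q_grid), min(x$q_grid), max(x$q_grid), max(x$intensity)))
  invisible(x)
}

#' @export
plot.scattering_profile <- function(x, ...,
                                    xlab = expression(q ~ (nm^-1)),
                                    ylab = "relative intensity", type = "l") {
  graphics::plot(x$q_grid, x$intensity, type = type, xlab = xlab, ylab = ylab,
                 ...)
  invisible(x)
}

q_step_of <- function(profile, tol = 1e-9) {
  dq <- diff(profile$q_grid)
  if (diff(range(dq)) > tol * mean(dq)) {
    stop("profile q_grid must be uniform")
  }
  mean(dq)
}

#' Uniform q grid around a central scattering vector
#'
#' @param q_center central q, nm^-1.
#' @param q_spread full geometric q spread to cover, nm^-1.
#' @param n number of samples (default 2048).
#' @param span_factor half-span of the grid in units of `q_spread`
#'   (default 1.5, leaving margin for the smearing kernel).
#' @return numeric vector of q values.
#' @export
default_q_grid <- function(q_center, q_spread, n = 2048, span_factor = 1.5) {
  stopifnot(q_center > 0, q_spread > 0, n >= 16, span_factor > 0.5)
  lo <- max(q_center - span_factor * q_spread, q_center * 1e-6)
  hi <- q_center + span_factor * q_spread
  seq(lo, hi, length.out = n)
}

#' Unsmeared step scattering profile of an extended target
#'
#' Distributes the target's scattered intensity over apparent q. Each slice of
#' the target at signed position `u` along the beam (u > 0 toward the source,
#' i.e. farther from the detector) scatters at the true `q_center` but is
#' recorded by the detector at the apparent q of its distance `L0 + u`
#' ([apparent_q()]). For a uniform (or given) density the per-bin deposited
#' intensity is computed exactly by inverting the slice-to-q mapping at the
#' bin edges, which yields a near-rectangular step whose total q extent agrees
#' with the geometric relative q spread to first order in `r_t / L0`. The
#' profile is normalized so its trapezoidal integral over q equals
#' [relative_intensity()], making the total intensity grid-independent.
#'
#' @param medium a [medium_properties()].
#' @param r_t effective target radius along the beam, cm.
#' @param beam a [beam_geometry()].
#' @param q_center central (true) scattering vector of the target material,
#'   nm^-1.
#' @param q_grid uniform q grid that must contain the step support; see
#'   [default_q_grid()].
#' @param path_length total beam path length through the object, cm
#'   (default `2 * r_t`: a bare target with no surrounding object).
#' @param density optional [density_profile()] for a non-uniform target.
#' @return a [scattering_profile()].
#' @export
build_step_profile <- function(medium, r_t, beam, q_center, q_grid,
                               path_length = NULL, density = NULL) {
  stopifnot(inherits(medium, "medium_properties"),
            inherits(beam, "beam_geometry"),
            r_t > 0, q_center > 0)
  if (is.null(path_length)) path_length <- 2 * r_t
  total <- relative_intensity(medium, path_length, r_t = r_t, density = density)

  n <- length(q_grid)
  dq <- diff(q_grid)
  if (any(dq <= 0) || diff(range(dq)) > 1e-9 * mean(dq)) {
    stop("q_grid must be strictly increasing and uniform")
  }
  step <- mean(dq)
  L0 <- beam$L0
  lambda <- beam$wavelength

  # support of the step in apparent q
  q_lo <- apparent_q(L0 - r_t, q_center, L0, lambda)
  q_hi <- apparent_q(L0 + r_t, q_center, L0, lambda)
  if (q_lo < q_grid[1] || q_hi > q_grid[n]) {
    stop(sprintf(
      "q_grid too narrow: step support is [%.6g, %.6g] nm^-1, grid spans [%.6g, %.6g]",
      q_lo, q_hi, q_grid[1], q_grid[n]))
  }

  # exact per-bin mass: invert the apparent-q mapping at the bin edges to get
  # the slice positions u(q) they correspond to, then difference the
  # cumulative scatterer line integral M(u)
  edges <- c(q_grid - step / 2, q_grid[n] + step / 2)
  edges_cl <- pmin(pmax(edges, q_lo), q_hi)
  u_edges <- event_distance_for_q(edges_cl, q_center, L0, lambda) - L0
  u_edges <- pmin(pmax(u_edges, -r_t), r_t)

  if (is.null(density)) {
    m_cum <- medium$rho_t * (u_edges + r_t)
  } else {
    pos <- density$positions
    cum <- pracma::cumtrapz(pos, density$densities)[, 1]
    m_cum <- stats::approx(pos, cum, xout = pmin(pmax(u_edges, min(pos)), max(pos)),
                           rule = 2)$y
  }
  mass <- diff(m_cum) * medium$sigma * exp(-medium$mu * path_length)
  intensity <- mass / step

  prof <- scattering_profile(q_grid, intensity)
  area <- pracma::trapz(q_grid, intensity)
  if (area <= 0) stop("step profile has zero area; check inputs")
  prof$intensity <- prof$intensity * (total / area)
  prof
}

#' Unit-area triangular detector-smearing kernel
#'
#' Symmetric triangular kernel whose base (full support) spans
#' `width_factor * q_spread`, discretized on the profile's q step and
#' normalized to unit discrete area (`sum(samples) * q_step == 1`). The
#' default width factor 0.35 models the blur a photon-counting detector adds
#' to an ideal step profile.
#'
#' @param q_spread geometric spread of q of the profile to be smeared, nm^-1.
#'   A value of 0 yields the identity (delta) kernel.
#' @param q_step uniform q-grid step, nm^-1; must resolve the kernel
#'   (`q_step < width_factor * q_spread / 4`).
#' @param width_factor kernel base width as a fraction of `q_spread`.
#' @return an object of class `triangular_kernel` with fields `base_width`,
#'   `q_step`, `samples`.
#' @export
make_triangular_kernel <- function(q_spread, q_step, width_factor = 0.35) {
  stopifnot(q_spread >= 0, q_step > 0, width_factor > 0)
  if (q_spread == 0) {
    return(structure(list(base_width = 0, q_step = q_step, samples = 1 / q_step),
                     class = "triangular_kernel"))
  }
  base_width <- width_factor * q_spread
  if (q_step >= base_width / 4) {
    stop(sprintf(
      "q_step (%.4g) too coarse for kernel base width %.4g; need q_step < base/4",
      q_step, base_width))
  }
  half <- base_width / 2
  m <- floor(half / q_step)
  offsets <- (-m:m) * q_step
  vals <- pmax(0, 1 - abs(offsets) / half)
  vals <- vals / (sum(vals) * q_step)
  structure(list(base_width = base_width, q_step = q_step, samples = vals),
            class = "triangular_kernel")
}

#' Smear a scattering profile with a triangular kernel
#'
#' Discrete convolution of the profile with a unit-area [triangular kernel]
#' [make_triangular_kernel()]; the output grid is extended by the kernel
#' half-width on each side and the profile area is conserved.
#'
#' @param profile a [scattering_profile()] on a uniform grid.
#' @param kernel a `triangular_kernel` built on the same q step.
#' @return a smeared [scattering_profile()].
#' @export
smear_profile <- function(profile, kernel) {
  stopifnot(inherits(profile, "scattering_profile"),
            inherits(kernel, "triangular_kernel"))
  step <- q_step_of(profile)
  if (abs(step - kernel$q_step) > 1e-9 * step) {
    stop("kernel q_step does not match the profile grid")
  }
  k <- kernel$samples
  if (length(k) == 1L) return(profile)
  m <- (length(k) - 1L) / 2L
  n <- length(profile$intensity)
  sm <- stats::convolve(profile$intensity, rev(k * step), type = "open")
  q_out <- seq(profile$q_grid[1] - m * step,
               by = step, length.out = n + 2L * m)
  scattering_profile(q_out, pmax(sm, 0))
}

#' Scene description: target + beam + medium (+ optional object)
#'
#' Convenience container tying together the pieces [simulate_profile()] needs.
#' When `object` is `NULL` the beam traverses only the target itself
#' (attenuation path `2 * r_t_eff`); with a spherical object the attenuation
#' path is the chord at the beam's impact parameter.
#'
#' @param target a `spherical_target` or `elliptical_target`.
#' @param beam a [beam_geometry()].
#' @param medium a [medium_properties()].
#' @param object optional [spherical_object()].
#' @return an object of class `scatter_scene`.
#' @export
scatter_scene <- function(target, beam, medium, object = NULL) {
  stopifnot(inherits(target, "scatter_target"),
            inherits(beam, "beam_geometry"),
            inherits(medium, "medium_properties"))
  if (!is.null(object)) {
    stopifnot(inherits(object, "spherical_object"))
    r_eff <- effective_radius(target, beam$incidence_angle)
    off <- if (!is.null(target$center_offset)) target$center_offset else 0
    if (abs(off) + r_eff > object$R_o + 1e-9) {
      stop("target does not fit inside the object")
    }
  }
  structure(list(target = target, beam = beam, medium = medium,
                 object = object),
            class = "scatter_scene")
}

#' Simulate the smeared scattering profile of a scene
#'
#' End-to-end forward model: effective target radius from the incidence
#' angle, attenuation path length (object chord or bare-target diameter),
#' step profile in apparent q, and triangular detector smearing with a kernel
#' base width of `kernel_width_factor` times the geometric q spread.
#'
#' @param scene a [scatter_scene()].
#' @param q_center central scattering vector of the target material, nm^-1.
#'   The default 13.4 nm^-1 corresponds to the 4.7 Angstrom cross-beta sheet
#'   spacing of amyloid fibrils (q = 2*pi/d).
#' @param n_q number of q-grid samples.
#' @param span_factor grid half-span in units of the q spread.
#' @param kernel_width_factor triangular kernel base width relative to the q
#'   spread (default 0.35).
#' @param q_grid optional explicit uniform q grid.
#' @param density optional [density_profile()].
#' @return list with elements `profile` (smeared [scattering_profile()]),
#'   `step` (unsmeared), `summary` (one-row data.frame from
#'   [summarize_profile()]), `r_t_eff`, `path_length`, `q_spread`.
#' @examples
#' sc <- scatter_scene(spherical_target(2), beam_geometry(20, energy_keV = 60),
#'                     medium_properties(0.30, 5.5e5, 5e-23), spherical_object(10))
#' res <- simulate_profile(sc)
#' res$summary
#' @export
simulate_profile <- function(scene, q_center = 13.4, n_q = 2048,
                             span_factor = 1.5, kernel_width_factor = 0.35,
                             q_grid = NULL, density = NULL) {
  stopifnot(inherits(scene, "scatter_scene"))
  beam <- scene$beam
  r_eff <- effective_radius(scene$target, beam$incidence_angle)
  if (is.null(scene$object)) {
    path_length <- 2 * r_eff
  } else {
    path_length <- as.numeric(
      chord_length_impact(scene$object$R_o, beam$impact_parameter))
    if (path_length == 0) stop("beam misses the object")
  }
  model_profile(scene$medium, r_eff, path_length, beam, q_center,
                n_q = n_q, span_factor = span_factor,
                kernel_width_factor = kernel_width_factor, q_grid = q_grid,
                density = density)
}

#' Forward model from raw path measurements
#'
#' Same computation as [simulate_profile()] but parametrized directly by the
#' effective target radius and attenuation path length, as measured e.g. on a
#' segmented raster mask.
#'
#' @inheritParams simulate_profile
#' @param medium a [medium_properties()].
#' @param r_t_eff effective target radius along the beam, cm.
#' @param path_length total attenuation path length through the object, cm.
#' @param beam a [beam_geometry()].
#' @return same structure as [simulate_profile()].
#' @export
model_profile <- function(medium, r_t_eff, path_length, beam, q_center = 13.4,
                          n_q = 2048, span_factor = 1.5,
                          kernel_width_factor = 0.35, q_grid = NULL,
                          density = NULL) {
  theta_c <- half_angle_from_q(q_center, beam$wavelength)
  q_spread <- q_center * relative_q_spread(theta_c, beam$L0, r_t_eff)
  if (is.null(q_grid)) {
    q_grid <- default_q_grid(q_center, q_spread, n = n_q,
                             span_factor = span_factor)
  }
  step_prof <- build_step_profile(medium, r_t_eff, beam, q_center, q_grid,
                                  path_length = path_length, density = density)
  kernel <- make_triangular_kernel(q_spread, q_step_of(step_prof),
                                   width_factor = kernel_width_factor)
  smeared <- smear_profile(step_prof, kernel)
  list(profile = smeared, step = step_prof,
       summary = summarize_profile(smeared),
       r_t_eff = r_t_eff, path_length = path_length, q_spread = q_spread)
}

#' Write a scattering profile to a two-column TSV
#'
#' Columns `q_nm_inv` and `relative_intensity`, preceded by `#`-comment
#' header lines recording any scene parameters passed in `params`. Values are
#' printed with 9 significant digits so that a write/read cycle round-trips
#' on text.
#'
#' @param profile a [scattering_profile()].
#' @param path output file path.
#' @param params named list of scalar parameters to record in the header.
#' @export
write_profile <- function(profile, path, params = NULL) {
  stopifnot(inherits(profile, "scattering_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params) && length(params)) {
    for (nm in names(params)) {
      writeLines(sprintf("# %s: %s", nm, format(params[[nm]], digits = 9)), con)
    }
  }
  writeLines("q_nm_inv\trelative_intensity", con)
  writeLines(sprintf("%.8e\t%.8e", profile$q_grid, profile$intensity), con)
  invisible(path)
}

#' Read a scattering profile written by [write_profile()]
#'
#' @param path input file path.
#' @return a [scattering_profile()] with attribute `params` holding the
#'   header key-value comments (as character).
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  params <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    params[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  body <- lines[!grepl("^#", lines)]
  dat <- utils::read.delim(text = body, header = TRUE)
  prof <- scattering_profile(dat$q_nm_inv, dat$relative_intensity)
  attr(prof, "params") <- params
  prof
}
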