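# Synthetic inputs: labeled raster phantoms with known geometry (stand-ins
# for a manually segmented head scout image) and the analytic scene sweeps
# used to exercise the forward model.

#' Default medium properties for amyloid-in-brain scenes
#'
#' Linear attenuation coefficient 0.30 cm^-1 (gray/white matter at
#' diagnostic energies), amyloid scatterer number density 5.5e5 cm^-3 and
#' differential scattering cross-section 5e-23 cm^2.
#'
#' @return a [medium_properties()].
#' @export
default_medium <- function() {
  medium_properties(mu = 0.30, rho_t = 5.5e5, sigma = 5e-23)
}

in_ellipse <- function(x, y, center, semi_axes, orientation = 0) {
  dx <- x - center[1]
  dy <- y - center[2]
  if (orientation != 0) {
    c0 <- cos(orientation); s0 <- sin(orientation)
    rx <- c0 * dx + s0 * dy
    ry <- -s0 * dx + c0 * dy
    dx <- rx; dy <- ry
  }
  (dx / semi_axes[1])^2 + (dy / semi_axes[2])^2 <= 1
}

#' Phantom specification
#'
#' Describes a synthetic segmented head: an elliptical "head" (object), one
#' or more elliptical "lobes" (targets), and optional excluded
#' (radiosensitive) zones, on a raster grid with a physical pixel size.
#' Physical coordinates are in cm with the origin at the grid's top-left
#' corner; `x` runs along columns, `y` along rows, and the pixel `(i, j)`
#' center sits at `((j - 0.5) * pixel_size, (i - 0.5) * pixel_size)`.
#'
#' @param grid integer `c(rows, cols)`.
#' @param pixel_size physical pixel size, cm.
#' @param head list with `center = c(x, y)` and `semi_axes = c(a, b)` in cm.
#' @param lobes list of lists, each with `center`, `semi_axes` and optional
#'   `orientation` (radians). Must lie inside the head.
#' @param excluded_zones like `lobes`; elliptical radiosensitive regions.
#' @param noise probability of flipping an object/target boundary pixel
#'   (salt-and-pepper label noise), default 0.
#' @param seed integer seed for the optional noise.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid, pixel_size, head, lobes = list(),
                         excluded_zones = list(), noise = 0, seed = NULL) {
  stopifnot(length(grid) == 2L, all(grid >= 2), pixel_size > 0,
            is.list(head), length(head$center) == 2L,
            length(head$semi_axes) == 2L, all(head$semi_axes > 0),
            noise >= 0, noise < 1)
  extent <- c(grid[2], grid[1]) * pixel_size  # (x, y)
  if (any(head$center - head$semi_axes < 0) ||
      any(head$center + head$semi_axes > extent)) {
    stop("head geometry extends outside the grid")
  }
  structure(list(grid = as.integer(grid), pixel_size = pixel_size,
                 head = head, lobes = lobes,
                 excluded_zones = excluded_zones,
                 noise = noise, seed = seed),
            class = "phantom_spec")
}

#' Rasterize a phantom specification into a labeled mask
#'
#' Labels are assigned by a membership test at each pixel center (no
#' anti-aliasing), with priority target > excluded > object > background, so
#' the result is deterministic for a given spec (and seed, when label noise
#' is enabled). Lobes and excluded zones must rasterize inside the head.
#'
#' @param spec a [phantom_spec()].
#' @return a [labeled_mask()].
#' @examples
#' spec <- phantom_spec(grid = c(120, 120), pixel_size = 0.1,
#'                      head = list(center = c(6, 6), semi_axes = c(5, 5)),
#'                      lobes = list(list(center = c(4, 6), semi_axes = c(1.5, 1.5))))
#' mask <- make_embedded_disk_mask(spec)
#' @export
make_embedded_disk_mask <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$grid[1]; nc <- spec$grid[2]; ps <- spec$pixel_size
  xc <- (rep(seq_len(nc), each = nr) - 0.5) * ps
  yc <- (rep(seq_len(nr), times = nc) - 0.5) * ps

  head_in <- in_ellipse(xc, yc, spec$head$center, spec$head$semi_axes)
  lab <- ifelse(head_in, 1L, 0L)

  for (z in spec$excluded_zones) {
    ori <- if (is.null(z$orientation)) 0 else z$orientation
    zin <- in_ellipse(xc, yc, z$center, z$semi_axes, ori)
    if (any(zin & !head_in)) stop("excluded zone extends outside the head")
    lab[zin] <- 3L
  }
  for (lb in spec$lobes) {
    ori <- if (is.null(lb$orientation)) 0 else lb$orientation
    lin <- in_ellipse(xc, yc, lb$center, lb$semi_axes, ori)
    if (any(lin & !head_in)) stop("lobe extends outside the head")
    lab[lin] <- 2L
  }
  labels <- matrix(lab, nrow = nr, ncol = nc)

  if (spec$noise > 0) {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    # boundary pixels: object adjacent to target or vice versa
    tgt <- labels == 2L
    obj <- labels == 1L
    shift <- function(m, di, dj) {
      out <- matrix(FALSE, nr, nc)
      ri <- seq_len(nr) + di; cj <- seq_len(nc) + dj
      ok_i <- ri >= 1 & ri <= nr; ok_j <- cj >= 1 & cj <= nc
      out[ok_i, ok_j] <- m[ri[ok_i], cj[ok_j]]
      out
    }
    near_tgt <- shift(tgt, 1, 0) | shift(tgt, -1, 0) |
      shift(tgt, 0, 1) | shift(tgt, 0, -1)
    near_obj <- shift(obj, 1, 0) | shift(obj, -1, 0) |
      shift(obj, 0, 1) | shift(obj, 0, -1)
    boundary <- (obj & near_tgt) | (tgt & near_obj)
    flip <- boundary & (stats::runif(nr * nc) < spec$noise)
    labels[flip & obj] <- 2L
    labels[flip & tgt] <- 1L
  }
  labeled_mask(labels, ps, name = "synthetic phantom")
}

#' Analytic scene sweeps over the model's driving parameters
#'
#' Returns ready-made lists of [scatter_scene()]s sweeping one parameter at a
#' time, the scenarios used throughout the package's tests and examples:
#'
#' * `"object_size"`: spherical object radius 4 to 10 cm, target radius 2 cm,
#'   L0 = 20 cm. Larger heads attenuate more.
#' * `"target_location"`: object 10 cm, target 2 cm, target-to-detector
#'   distance L0 from 18 to 22 cm. Targets closer to the detector smear more.
#' * `"incidence_angle"`: object 10 cm, target 2 cm, L0 = 20 cm, beam impact
#'   parameter 0 to 6 cm. Oblique incidence on an off-center target shortens
#'   the chord and raises intensity.
#' * `"ellipse_angle"`: elliptical target a = 1, b = 3 cm centered in a 10 cm
#'   object, L0 = 20 cm, incidence angle 0 to pi/2. The effective radius (and
#'   hence smearing) changes with angle; attenuation does not.
#' * `"target_size"`: bare spherical target, radius 0.5 to 3 cm, L0 = 20 cm.
#'   Bigger targets scatter more in total but self-attenuate over a longer
#'   path and smear over a wider q range.
#' * `"medium"`: the single default scene (target 0.5 cm in a 10 cm object,
#'   L0 = 20 cm) at the default medium properties, the baseline for
#'   cross-section / density / attenuation linearity checks.
#'
#' @param name sweep name, see above.
#' @param medium a [medium_properties()]; defaults to [default_medium()].
#' @param energy_keV beam energy, keV.
#' @return list with elements `name`, `parameter` (name of the varied
#'   quantity), `values` (its values) and `scenes` (list of
#'   [scatter_scene()]).
#' @export
sweep_configs <- function(name = c("object_size", "target_location",
                                   "incidence_angle", "ellipse_angle",
                                   "target_size", "medium"),
                          medium = default_medium(), energy_keV = 60) {
  name <- match.arg(name)
  mk_beam <- function(L0, phi = 0, b = 0) {
    beam_geometry(L0, energy_keV = energy_keV, incidence_angle = phi,
                  impact_parameter = b)
  }
  sw <- switch(
    name,
    object_size = {
      vals <- 4:10
      list(parameter = "R_o", values = vals,
           scenes = lapply(vals, function(R) {
             scatter_scene(spherical_target(2), mk_beam(20), medium,
                           spherical_object(R))
           }))
    },
    target_location = {
      vals <- 18:22
      list(parameter = "L0", values = vals,
           scenes = lapply(vals, function(L0) {
             scatter_scene(spherical_target(2), mk_beam(L0), medium,
                           spherical_object(10))
           }))
    },
    incidence_angle = {
      vals <- c(0, 2, 4, 6)
      list(parameter = "impact_parameter", values = vals,
           scenes = lapply(vals, function(b) {
             scatter_scene(spherical_target(2, center_offset = 0),
                           mk_beam(20, b = b), medium, spherical_object(10))
           }))
    },
    ellipse_angle = {
      vals <- seq(0, pi / 2, length.out = 5)
      list(parameter = "incidence_angle", values = vals,
           scenes = lapply(vals, function(phi) {
             scatter_scene(elliptical_target(1, 3), mk_beam(20, phi = phi),
                           medium, spherical_object(10))
           }))
    },
    target_size = {
      vals <- c(0.5, 1, 1.5, 2, 2.5, 3)
      list(parameter = "r_t", values = vals,
           scenes = lapply(vals, function(r) {
             scatter_scene(spherical_target(r), mk_beam(20), medium)
           }))
    },
    medium = {
      list(parameter = "baseline", values = 1,
           scenes = list(
             scatter_scene(spherical_target(0.5), mk_beam(20), medium,
                           spherical_object(10))))
    }
  )
  c(list(name = name), sw)
}
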