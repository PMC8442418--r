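# Profile summaries consumed by the figure of merit: peak relative intensity
# I_p, total relative intensity I_t (area under the profile), and the q
# spread Delta q (half-width at half-maximum).

#' Peak relative intensity of a scattering profile
#'
#' @param profile a [scattering_profile()].
#' @return the maximum intensity sample (dimensionless).
#' @export
peak_intensity <- function(profile) {
  stopifnot(inherits(profile, "scattering_profile"))
  if (!length(profile$intensity)) stop("empty profile")
  max(profile$intensity)
}

#' Total relative intensity (area under the profile)
#'
#' Trapezoidal area over q; units nm^-1 times relative intensity.
#'
#' @param profile a [scattering_profile()] on a uniform grid.
#' @return the area under the intensity curve.
#' @export
total_intensity <- function(profile) {
  stopifnot(inherits(profile, "scattering_profile"))
  if (!length(profile$intensity)) stop("empty profile")
  q_step_of(profile) # validates uniformity
  pracma::trapz(profile$q_grid, profile$intensity)
}

#' Half-width at half-maximum q spread of a profile
#'
#' Half of the q distance between the outermost crossings of half the peak
#' intensity, with linear interpolation between grid samples. Outermost
#' crossings make the measure deterministic on the flat-topped profiles a
#' smeared step produces and recover `w/2` exactly in the ideal-rectangle
#' limit of full width `w`.
#'
#' @param profile a [scattering_profile()] whose half-maximum level is
#'   attained strictly inside the grid (otherwise the grid is too narrow and
#'   an error is raised).
#' @return Delta q in nm^-1.
#' @export
hwhm_spread <- function(profile) {
  stopifnot(inherits(profile, "scattering_profile"))
  q <- profile$q_grid
  y <- profile$intensity
  peak <- max(y)
  if (peak <= 0) stop("profile is identically zero; HWHM undefined")
  half <- peak / 2
  if (y[1] >= half || y[length(y)] >= half) {
    stop("profile does not fall below half-maximum at the grid edges; grid too narrow")
  }
  above <- which(y >= half)
  i_left <- above[1]
  i_right <- above[length(above)]
  # linear interpolation on the rising/falling flank
  interp <- function(i0, i1) {
    if (y[i1] == y[i0]) return(q[i1])
    q[i0] + (half - y[i0]) * (q[i1] - q[i0]) / (y[i1] - y[i0])
  }
  q_left <- interp(i_left - 1L, i_left)
  q_right <- interp(i_right + 1L, i_right)
  (q_right - q_left) / 2
}

#' Summarize a scattering profile for the figure of merit
#'
#' @param profile a [scattering_profile()].
#' @return a one-row data.frame with columns `I_p`, `I_t`, `delta_q`.
#' @export
summarize_profile <- function(profile) {
  data.frame(I_p = peak_intensity(profile),
             I_t = total_intensity(profile),
             delta_q = hwhm_spread(profile))
}
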