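# Independent numerical oracles used to cross-check the closed-form
# implementations, plus small fixture builders. These deliberately use a
# different construction than the package code.

# total path length via explicit ray-circle intersection: march the deflected
# ray from the scatter point and solve the quadratic for the circle exit
oracle_path_length <- function(entry_depth, two_theta, R_o, b = 0) {
  half <- sqrt(R_o^2 - b^2)
  p <- c(-half + entry_depth, b)
  u <- c(cos(two_theta), sin(two_theta))
  # |p + t u| = R_o  =>  t^2 + 2 t (p.u) + |p|^2 - R_o^2 = 0
  pu <- sum(p * u)
  disc <- pu^2 - (sum(p^2) - R_o^2)
  t_exit <- -pu + sqrt(disc)
  entry_depth + t_exit
}

# direct O(n*m) discrete convolution of a profile with a unit-area kernel
oracle_convolve <- function(intensity, kernel_samples, q_step) {
  n <- length(intensity)
  m <- length(kernel_samples)
  out <- numeric(n + m - 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      out[i + j - 1] <- out[i + j - 1] + intensity[i] * kernel_samples[j] * q_step
    }
  }
  out
}

# rectangular scattering profile on a uniform grid
rect_profile <- function(height = 2, from = 10, to = 11, q_min = 9, q_max = 12,
                         n = 601) {
  q <- seq(q_min, q_max, length.out = n)
  scattering_profile(q, ifelse(q >= from & q <= to, height, 0))
}

# standard test phantom: elliptical head with one off-center disk lobe
disk_phantom_spec <- function(pixel_size = 0.1, r_lobe = 1.5,
                              lobe_center = c(4.5, 9), noise = 0, seed = NULL,
                              excluded_zones = list()) {
  phantom_spec(
    grid = c(180, 180), pixel_size = pixel_size,
    head = list(center = c(9, 9), semi_axes = c(8, 7)),
    lobes = list(list(center = lobe_center, semi_axes = c(r_lobe, r_lobe))),
    excluded_zones = excluded_zones, noise = noise, seed = seed)
}

test_beam <- function(L0 = 20, ...) beam_geometry(L0, energy_keV = 60, ...)
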