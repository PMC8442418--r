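test_that("relative intensity follows the attenuated density integral", {
  m <- medium_properties(mu = 0.30, rho_t = 5.5e5, sigma = 5e-23)
  # no scatterers -> no signal
  m0 <- medium_properties(0.30, 0, 5e-23)
  expect_equal(relative_intensity(m0, 20, r_t = 0.5), 0)
  # attenuation-free closed form sigma * rho * 2 r_t
  m_nomu <- medium_properties(0, 5.5e5, 5e-23)
  expect_equal(relative_intensity(m_nomu, 10, r_t = 2), 5e-23 * 5.5e5 * 4)
  # default parameters against the closed form sigma*rho*2r*exp(-mu l)
  expect_equal(relative_intensity(m, 20, r_t = 0.5),
               5e-23 * 5.5e5 * 1 * exp(-0.30 * 20), tolerance = 1e-9)
  # quadrature path (explicit uniform density) matches the closed form
  dens <- density_profile(seq(-0.5, 0.5, length.out = 2001),
                          rep(5.5e5, 2001))
  expect_equal(relative_intensity(m, 20, density = dens),
               relative_intensity(m, 20, r_t = 0.5), tolerance = 1e-6)
  expect_error(relative_intensity(m, 0.5, r_t = 2), "path_length")
  expect_error(medium_properties(-0.1, 1, 1))
})

test_that("log intensity is affine in path length with slope -mu", {
  m <- default_medium()
  l_grid <- seq(5, 25, by = 5)
  vals <- vapply(l_grid, relative_intensity, numeric(1), medium = m, r_t = 0.5)
  slopes <- diff(log(vals)) / diff(l_grid)
  expect_equal(slopes, rep(-0.30, length(slopes)), tolerance = 1e-10)
  # linear in sigma and rho_t
  expect_equal(relative_intensity(medium_properties(0.3, 5.5e5, 1e-22), 20, r_t = 0.5),
               2 * relative_intensity(m, 20, r_t = 0.5))
  expect_equal(relative_intensity(medium_properties(0.3, 1.1e6, 5e-23), 20, r_t = 0.5),
               2 * relative_intensity(m, 20, r_t = 0.5))
})

test_that("step profile concentrates intensity at q_center and conserves area", {
  m <- default_medium()
  beam <- test_beam()
  q0 <- 13.4
  theta <- half_angle_from_q(q0, beam$wavelength)

  # near-point target: all intensity within a tiny band around q_center
  r_small <- 0.01
  qg <- default_q_grid(q0, q0 * relative_q_spread(theta, 20, r_small), n = 512)
  prof <- build_step_profile(m, r_small, beam, q0, qg, path_length = 20)
  support <- range(prof$q_grid[prof$intensity > 0])
  expect_lt(diff(support), 0.05)
  expect_lt(abs(mean(support) - q0), 0.01)

  # area equals the relative intensity regardless of grid resolution
  for (n in c(512, 2048)) {
    qg <- default_q_grid(q0, q0 * relative_q_spread(theta, 20, 2), n = n)
    prof <- build_step_profile(m, 2, beam, q0, qg, path_length = 20)
    expect_equal(pracma::trapz(prof$q_grid, prof$intensity),
                 relative_intensity(m, 20, r_t = 2), tolerance = 1e-9)
  }

  # support symmetric about q_center to first order and matching the spread
  qg <- default_q_grid(q0, q0 * relative_q_spread(theta, 20, 2), n = 4096)
  prof <- build_step_profile(m, 2, beam, q0, qg, path_length = 20)
  supp <- range(prof$q_grid[prof$intensity > max(prof$intensity) * 1e-9])
  geom_spread <- q0 * relative_q_spread(theta, 20, 2)
  expect_equal(diff(supp) / geom_spread, 1, tolerance = 2.5 * (2 / 20)^2 / 0.1)
  expect_lt(abs(mean(supp) - q0) / geom_spread, 0.06)

  # doubling rho_t doubles every sample
  m2 <- medium_properties(m$mu, 2 * m$rho_t, m$sigma)
  prof2 <- build_step_profile(m2, 2, beam, q0, qg, path_length = 20)
  expect_equal(prof2$intensity, 2 * prof$intensity)

  # grid that misses the support errors with the required span
  narrow <- seq(q0 - 0.1, q0 + 0.1, length.out = 64)
  expect_error(build_step_profile(m, 2, beam, q0, narrow, path_length = 20),
               "q_grid too narrow")
})

test_that("triangular kernel has the prescribed width and unit area", {
  k <- make_triangular_kernel(1, 0.01)
  expect_equal(k$base_width, 0.35)
  expect_lt(abs(sum(k$samples) * 0.01 - 1), 1e-9)
  # area invariant across valid inputs
  set.seed(3)
  for (i in 1:20) {
    spread <- runif(1, 0.1, 5)
    step <- 0.35 * spread / runif(1, 5, 200)
    k <- make_triangular_kernel(spread, step)
    expect_lt(abs(sum(k$samples) * step - 1), 1e-9)
    expect_equal(k$samples, rev(k$samples)) # symmetric
  }
  # continuum limit: peak -> 2 / base_width
  k_fine <- make_triangular_kernel(1, 1e-4)
  expect_equal(max(k_fine$samples), 2 / 0.35, tolerance = 1e-3)
  expect_error(make_triangular_kernel(1, 0.2), "too coarse")
})

test_that("smearing is a unit-area convolution: conserves area, softens edges", {
  prof <- rect_profile(height = 2, from = 10, to = 11, q_min = 9, q_max = 12)
  step <- diff(prof$q_grid)[1]
  kern <- make_triangular_kernel(1, step)

  sm <- smear_profile(prof, kern)
  # area conserved
  expect_equal(total_intensity(sm), total_intensity(prof), tolerance = 1e-6)
  # peak not raised; edges softened into a trapezoid with preserved plateau
  expect_lte(max(sm$intensity), max(prof$intensity) + 1e-9)
  mid <- abs(sm$q_grid - 10.5) < 0.2
  expect_equal(sm$intensity[mid], rep(2, sum(mid)), tolerance = 1e-9)
  # against the direct discrete convolution oracle
  direct <- oracle_convolve(prof$intensity, kern$samples, step)
  expect_equal(sm$intensity, direct, tolerance = 1e-9)
  # zero-width kernel is the identity
  ident <- smear_profile(prof, make_triangular_kernel(0, step))
  expect_identical(ident$intensity, prof$intensity)
  # non-uniform grids are rejected
  bad <- scattering_profile(c(1, 2, 4, 8), rep(1, 4))
  expect_error(smear_profile(bad, kern), "uniform")
})

test_that("profile TSV writer round-trips on text", {
  sc <- scatter_scene(spherical_target(2), test_beam(), default_medium(),
                      spherical_object(10))
  res <- simulate_profile(sc, n_q = 256)
  f <- tempfile(fileext = ".tsv")
  write_profile(res$profile, f, params = list(R_o = 10, r_t = 2))
  back <- read_profile(f)
  reread <- read_profile({
    write_profile(back, f, params = attr(back, "params")); f
  })
  expect_identical(back$q_grid, reread$q_grid)
  expect_identical(back$intensity, reread$intensity)
  expect_equal(attr(back, "params")$R_o, "10")
  expect_equal(res$profile$q_grid, back$q_grid, tolerance = 1e-8)
})

test_that("scene composition: bare targets attenuate over their own diameter", {
  m <- default_medium()
  bare <- simulate_profile(scatter_scene(spherical_target(1), test_beam(), m),
                           n_q = 512)
  expect_equal(bare$path_length, 2)
  embedded <- simulate_profile(
    scatter_scene(spherical_target(1), test_beam(), m, spherical_object(10)),
    n_q = 512)
  expect_equal(embedded$path_length, 20)
  expect_gt(total_intensity(bare$profile), total_intensity(embedded$profile))
  expect_error(
    scatter_scene(spherical_target(5, center_offset = 7), test_beam(), m,
                  spherical_object(10)),
    "fit inside")
})
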