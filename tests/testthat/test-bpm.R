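test_that("a plane wave crosses a homogeneous medium unchanged", {
  vol <- ri_volume(array(1.33, c(64, 64, 32)), 0.166)
  f <- propagate(vol)
  expect_lt(abs(f$power_out / f$power_in - 1), 1e-6)
  expect_lt(diff(range(Mod(f$amplitude))), 1e-9)
  sp <- angular_spectrum(f)
  expect_lt(large_angle_fraction(sp), 1e-4)
  # all power in the on-axis bin
  expect_gt(sp$power[1] / sum(sp$power), 1 - 1e-9)
})

test_that("a uniform slab imposes the analytic optical-path phase", {
  dn <- 0.01
  v <- array(1.33, c(64, 64, 40)); v[, , 11:30] <- 1.33 + dn
  f_slab <- propagate(ri_volume(v, 0.166, "slab"))
  f_ref <- propagate(ri_volume(array(1.33, c(64, 64, 40)), 0.166))
  expected <- (2 * pi * dn * (20 * 0.166) / 0.5) %% (2 * pi)
  got <- (Arg(f_slab$amplitude[32, 32]) - Arg(f_ref$amplitude[32, 32])) %% (2 * pi)
  expect_lt(min(abs(got - expected), abs(got - expected + 2 * pi),
                abs(got - expected - 2 * pi)), 1e-3)
})

test_that("a shallow sinusoidal phase grating diffracts at the grating angle", {
  n <- 128; dx <- 0.083
  f0 <- 1 / (16 * dx)  # 16-pixel period, cycles/um
  eps <- 0.05
  gr <- matrix(exp(1i * eps * sin(2 * pi * f0 * (1:n) * dx)), n, n)
  field <- structure(list(amplitude = gr, dx = c(dx, dx), wavelength = 500,
                          n0 = 1.33), class = "complex_field")
  sp <- angular_spectrum(field, dtheta = 0.5)
  theta_grating <- asin((0.5 / 1.33) * f0) * 180 / pi
  top <- sp[order(-sp$power), ][1:2, ]
  expect_lt(abs(top$theta_mid[2] - theta_grating), 0.5)
  # first orders are symmetric in +/- theta, so they land in one polar bin:
  # their joint power relative to the carrier follows the Bessel expansion
  ratio <- top$power[2] / top$power[1]
  expect_equal(ratio, 2 * besselJ(eps, 1)^2 / besselJ(eps, 0)^2,
               tolerance = 0.01)
})

test_that("binned angular power satisfies Parseval against the spatial sum", {
  ph <- sphere_phantom(2, 0.025, c(128, 128, 48), 0.166)
  f <- propagate(ph)
  sp <- angular_spectrum(f)
  expect_lt(abs(sum(sp$power) - attr(sp, "total_power")), 1e-12)
  expect_lt(abs(attr(sp, "total_power") + attr(sp, "evanescent_power") -
                  attr(sp, "spatial_power")) / attr(sp, "spatial_power"), 1e-6)
})

test_that("energy is conserved through a heterogeneous volume", {
  lv <- generate_packed_nuclei(6, c(96, 96, 64), 0.2, 2, 0.2, seed = 2)
  ri <- smooth_and_embed(assign_inverted(lv), chromatin_params())
  f <- propagate(ri)
  expect_lt(abs(f$power_out / f$power_in - 1), 1e-3)
})

test_that("lateral translation of the volume leaves the spectrum unchanged", {
  ph <- sphere_phantom(2, 0.025, c(64, 64, 32), 0.166)
  sp1 <- angular_spectrum(propagate(ph))
  rolled <- ph
  for (k in seq_len(dim(ph$ri)[3])) rolled$ri[, , k] <- roll_matrix(ph$ri[, , k], c(13, 7))
  sp2 <- angular_spectrum(propagate(rolled))
  expect_lt(max(abs(sp1$power - sp2$power)) / attr(sp1, "total_power"), 1e-6)
})

test_that("large-angle fraction reproduces the solid-angle ratio of an isotropic field", {
  # synthetic hemisphere-isotropic spectrum: per-mode power proportional to
  # its solid angle occupancy; fraction beyond 30 degrees is cos(30 deg)
  set.seed(1)
  theta <- acos(runif(20000))  # isotropic directions over the hemisphere
  fake <- data.frame(theta_lo = 0, theta_hi = 90, theta_mid = 45, power = 1)
  attr(fake, "raw_theta") <- theta * 180 / pi
  attr(fake, "raw_power") <- rep(1, length(theta))
  class(fake) <- c("angular_spectrum", "data.frame")
  expect_equal(large_angle_fraction(fake, 30), cos(30 * pi / 180),
               tolerance = 0.02)
  expect_error(large_angle_fraction(fake, 95), "theta_min")
})

test_that("grid-refinement keeps the single-sphere large-angle fraction stable", {
  # a fixed physical smoothing keeps the index field band-limited so that the
  # large-angle fraction is grid-converged (raw voxel staircases are not)
  frac_at <- function(vox, shape) {
    ph <- sphere_phantom(2, 0.025, shape, vox)
    ph <- smooth_and_embed(ph, chromatin_params(), sigma = 0.166 / vox)
    large_angle_fraction(angular_spectrum(propagate(ph)), 30)
  }
  f_coarse <- frac_at(0.166, c(96, 96, 32))
  f_fine <- frac_at(0.083, c(192, 192, 64))
  expect_lt(abs(f_fine - f_coarse) / f_fine, 0.10)
})

test_that("index-matched chromatin makes both architectures optically identical", {
  lv <- generate_packed_nuclei(4, c(64, 64, 48), 0.25, 2, 0.15, seed = 4)
  pars <- chromatin_params(n1 = 1.36, n2 = 1.36, n0 = 1.33)
  cmp <- compare_models(lv, pars, seed = 8)
  expect_equal(cmp$ratio, 1, tolerance = 1e-9)
  expect_equal(cmp$spectrum_inverted$power, cmp$spectrum_chromocenter$power,
               tolerance = 1e-12)
})

test_that("propagate validates its inputs", {
  vol <- ri_volume(array(1.33, c(16, 16, 4)), 0.166)
  expect_error(propagate(vol, input = matrix(1 + 0i, 8, 8)), "lateral grid")
  bad <- vol; bad$ri[1] <- Inf
  expect_error(propagate(bad), "non-finite")
})
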