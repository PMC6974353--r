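make_stripe_img <- function(contrast, f_um, pix = 1, shape = c(48, 256),
                            mean_i = 100) {
  modul <- sin(2 * pi * f_um * seq_len(shape[2]) * pix)
  matrix(mean_i * (1 + contrast * rep(modul, each = shape[1])), shape[1], shape[2])
}

test_that("stripe contrast is recovered from constructed sinusoids", {
  img <- make_stripe_img(0.40, 0.05)
  sc <- stripe_contrast(img, 0.05, 1, modulation_axis = 2)
  expect_equal(sc$contrast, 0.400, tolerance = 0.01)
  expect_false(sc$low_confidence)
  # a uniform veil of fraction v scales modulation by (1 - v)
  veiled <- 0.5 * img + 0.5 * mean(img)
  sc2 <- stripe_contrast(veiled, 0.05, 1, modulation_axis = 2)
  expect_equal(sc2$contrast, 0.200, tolerance = 0.01)
  expect_error(stripe_contrast(make_stripe_img(0.4, 0.005), 0.005, 1,
                               modulation_axis = 2), "periods")
})

test_that("noise-floor images yield zero contrast with a low-confidence flag", {
  set.seed(42)
  img <- matrix(100 + rnorm(48 * 256, 0, 5), 48, 256)
  sc <- stripe_contrast(img, 0.05, 1, modulation_axis = 2)
  expect_identical(sc$contrast, 0)
  expect_true(sc$low_confidence)
})

test_that("MTF estimation is unbiased on noise-free stripes across contrasts", {
  for (c0 in c(0.02, 0.1, 0.37, 1)) {
    st <- make_stripe_stack(c(0.02, 0.05, 0.1), contrast = c0, veil = 0)
    mc <- mtf_curve(st$sample, st$reference)
    expect_true(all(abs(mc$mtf - 1) < 0.005))
  }
})

test_that("MTF arithmetic follows the contrast-ratio definition with setup normalization", {
  f <- c(0.02, 0.05)
  sample <- stripe_series(lapply(f, function(ff) make_stripe_img(0.4, ff)),
                          f, 1, 2L)
  reference <- stripe_series(lapply(f, function(ff) make_stripe_img(0.8, ff)),
                             f, 1, 2L)
  mc <- mtf_curve(sample, reference)
  expect_equal(mc$mtf, c(0.5, 0.5), tolerance = 1e-3)
  # setup with MTF 0.8 against the same reference
  setup <- stripe_series(lapply(f, function(ff) make_stripe_img(0.64, ff)),
                         f, 1, 2L)
  mc2 <- mtf_curve(sample, reference, setup)
  expect_equal(mc2$mtf, c(0.625, 0.625), tolerance = 1e-3)
  expect_error(mtf_curve(sample, stripe_series(reference$images, f * 2, 1, 2L)),
               "frequency")
})

test_that("imposed exponential MTF profiles are recovered per frequency", {
  f <- seq(0.01, 0.1, by = 0.015)
  st <- make_stripe_stack(f, contrast = 0.5, veil = 0,
                          mtf_profile = function(ff) exp(-ff / 0.05))
  mc <- mtf_curve(st$sample, st$reference)
  expect_true(all(abs(mc$mtf - exp(-f / 0.05)) / exp(-f / 0.05) < 0.03))
})

test_that("Strehl ratio behaves as the frequency-weighted area definition", {
  f <- seq(0, 2.5, by = 0.05)
  m1 <- data.frame(frequency_cpd = f, mtf = exp(-f / 1.3))
  expect_equal(strehl_ratio(m1, m1)$strehl, 1, tolerance = 1e-12)
  m2 <- data.frame(frequency_cpd = f, mtf = 0.5 * exp(-f / 1.3))
  expect_equal(strehl_ratio(m2, m1)$strehl, 0.5, tolerance = 1e-12)
  # band restriction matches a direct trapezoid on the restricted grid
  fb <- f[f <= 2]
  w <- fb * exp(-fb / 1.3)
  direct <- sum(diff(fb) * (w[-1] + w[-length(w)]) / 2)
  sr <- strehl_ratio(m1, band = c(0, 2))
  expect_equal(sr$area, direct, tolerance = 1e-12)
  expect_equal(sr$strehl, direct / 2, tolerance = 1e-12)  # ideal area = 2
  expect_error(strehl_ratio(m1, band = c(0, 5)), "band")
})

test_that("PSF metrics recover a Gaussian spot and are intensity-scale invariant", {
  ps <- make_psf_image(fwhm = 2 * sqrt(2 * log(2)) * 2 * 0.5, veil = 0,
                       pixel_size = 0.5)  # sigma = 2 px
  m <- psf_metrics(ps$image, 0.5)
  expect_equal(m$fwhm / 0.5, 2 * sqrt(2 * log(2)) * 2, tolerance = 0.022)
  m5 <- psf_metrics(ps$image * 5, 0.5)
  expect_equal(m$peak, m5$peak, tolerance = 1e-12)
  expect_equal(m$fwhm, m5$fwhm, tolerance = 1e-12)
  expect_error(psf_metrics(matrix(0, 8, 8), 1), "positive")
})

test_that("a uniform veil halves the normalized PSF peak but not the core width", {
  p0 <- make_psf_image(fwhm = 3, veil = 0, pixel_size = 0.5)
  p5 <- make_psf_image(fwhm = 3, veil = 0.5, pixel_size = 0.5)
  m0 <- psf_metrics(p0$image, 0.5)
  m5 <- psf_metrics(p5$image, 0.5)
  expect_equal(m0$peak / m5$peak, 2, tolerance = 0.05)
  expect_lt(abs(m5$fwhm - m0$fwhm) / m0$fwhm, 0.10)
})

test_that("diffuse transmission is a dark-corrected integral ratio", {
  ref <- matrix(4, 8, 8); smp <- matrix(2, 8, 8)
  expect_identical(diffuse_transmission(smp, ref), 0.5)
  expect_identical(diffuse_transmission(ref, ref), 1)
  # a common dark offset cancels
  expect_equal(diffuse_transmission(smp + 3, ref + 3, 3), 0.5, tolerance = 1e-12)
  expect_error(diffuse_transmission(smp, ref * 0), "positive")
  expect_error(diffuse_transmission(smp, matrix(1, 4, 4)), "shapes")
})

test_that("scattering-to-MTF conversion has the right limits and g-ordering", {
  f <- seq(0, 0.44, by = 0.04)
  m0 <- scattering_to_mtf(0.95, 0.2, 0, 1, 45, f)
  expect_true(all(m0$mtf == 1))
  m1 <- scattering_to_mtf(0.95, 0.2, 0.5, 1, 45, f)
  expect_equal(m1$mtf[1], 1, tolerance = 1e-12)
  expect_true(all(diff(m1$mtf) <= 0))
  # at fixed optical depth, more forward-directed scattering preserves contrast
  for (g_hi in c(0.99, 0.95)) {
    lo <- scattering_to_mtf(g_hi - 0.05, 0.2, 0.5, 1, 45, f)
    hi <- scattering_to_mtf(g_hi, 0.2, 0.5, 1, 45, f)
    expect_true(all(hi$mtf[-1] > lo$mtf[-1]))
  }
})

test_that("outer segments degrade the behavioral-band MTF far less than chromocenter nuclei", {
  f <- seq(0, 0.44, by = 0.02)
  # outer segments: 1.6 x 25 um cylinders (n 1.42) as a volume-equivalent sphere
  v_cyl <- pi * 0.8^2 * 25
  d_eq <- (6 * v_cyl / pi)^(1 / 3)
  os <- mie_efficiencies(sphere_spec(d_eq, 1.42, 1.33))
  mtf_os <- scattering_to_mtf(os$g, os$Qsca, 0.3 / v_cyl, d_eq, 25, f)
  # chromocenter nuclei: 1 um heterochromatin spheres at the nuclear packing
  cc <- mie_efficiencies(sphere_spec(1, 1.382, 1.357))
  mtf_cc <- scattering_to_mtf(cc$g, cc$Qsca, 0.3351 / (pi / 6), 1, 45, f)
  expect_true(all(mtf_os$mtf >= 0.95))
  expect_lt(min(mtf_cc$mtf), min(mtf_os$mtf))
})

test_that("volume-specific scattering normalizes side by forward scatter", {
  rec <- data.frame(fsc_area = c(100, 100, -1), ssc_area = c(200, 50, 10),
                    label = c("a", "b", "b"))
  vs <- volume_specific_scattering(rec)
  expect_identical(vs$n_dropped, 1L)
  expect_equal(vs$events$vss, c(2, 0.5))
  # doubling all forward-scatter areas halves every metric
  rec2 <- rec[1:2, ]; rec2$fsc_area <- rec2$fsc_area * 2
  vs2 <- volume_specific_scattering(rec2)
  expect_equal(vs2$events$vss, vs$events$vss / 2)
})

test_that("AULC obeys the rectangle and log-linearity identities", {
  expect_equal(aulc(c(0.1, 0.5), c(0.1, 0.1)), log10(10) * 0.4,
               tolerance = 1e-12)
  f <- c(0.05, 0.1, 0.2, 0.3)
  thr <- c(0.02, 0.05, 0.2, 0.8)
  base <- aulc(f, thr)
  # scaling every sensitivity by 10 adds the frequency span
  expect_equal(aulc(f, thr / 10), base + (0.3 - 0.05), tolerance = 1e-12)
  expect_error(aulc(0.1, 0.1), "two frequencies")
  expect_error(aulc(c(0.1, 0.2), c(0.5, 1.5)), "thresholds")
})
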