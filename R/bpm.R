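#' Plane-wave or custom-beam scalar propagation through an RI volume
#'
#' Split-step Fourier (beam-propagation) solution of the scalar Helmholtz
#' equation through an inhomogeneous refractive-index volume: each z-slice
#' applies the accumulated phase \eqn{\exp(i k_0 (n - n_0) \Delta z)} followed
#' by homogeneous-medium diffraction with the non-paraxial angular-spectrum
#' propagator \eqn{H(f) = \exp(i 2\pi \Delta z \sqrt{(n_0/\lambda_0)^2 -
#' f^2})}; spatial frequencies beyond the homogeneous-medium cutoff
#' (evanescent components) are truncated.
#'
#' Lateral boundaries are periodic by default, which makes the energy
#' bookkeeping exact (total intensity is conserved through any real-index
#' volume, apart from truncated evanescent power). An absorbing super-Gaussian
#' apron is available via \code{boundary = "absorb"} for beams that approach
#' the lateral edges.
#'
#' @param ri An \code{\link{ri_volume}}; the third array axis is the
#'   propagation axis.
#' @param wavelength Vacuum wavelength in nanometres. Default 500.
#' @param n0 Background refractive index the propagator is referenced to.
#'   Default 1.33.
#' @param input Optional complex matrix of the incident field at the entrance
#'   plane (defaults to a unit-amplitude plane wave).
#' @param boundary \code{"periodic"} (default) or \code{"absorb"}.
#' @param absorb_width Apron width as a fraction of the grid when
#'   \code{boundary = "absorb"}. Default 0.08.
#' @return An object of class \code{"complex_field"}: list with
#'   \code{amplitude} (complex exit-plane matrix), \code{dx} (lateral pitch,
#'   um, length 2), \code{wavelength}, \code{n0}, \code{power_in},
#'   \code{power_out}.
#' @examples
#' ph <- sphere_phantom(2, 0.025, c(64, 64, 32), 0.166)
#' fld <- propagate(ph)
#' fld$power_out / fld$power_in
#' @export
propagate <- function(ri, wavelength = 500, n0 = 1.33, input = NULL,
                      boundary = c("periodic", "absorb"),
                      absorb_width = 0.08) {
  stopifnot(inherits(ri, "ri_volume"))
  boundary <- match.arg(boundary)
  if (any(!is.finite(ri$ri))) stop("RI volume contains non-finite values",
                                   call. = FALSE)
  d <- dim(ri$ri)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  if (any(c(nx, ny) %% 2L != 0L)) {
    warning("lateral grid sizes are odd; FFTs are fastest for highly composite even sizes")
  }
  vx <- ri$voxel_size
  lambda <- wavelength / 1000
  k0 <- 2 * pi / lambda
  fx <- fft_freq(nx, vx[1])
  fy <- fft_freq(ny, vx[2])
  arg <- (n0 / lambda)^2 - outer(fx^2, fy^2, "+")
  prop <- matrix(0 + 0i, nx, ny)
  ok <- arg > 0
  prop[ok] <- exp(2i * pi * vx[3] * sqrt(arg[ok]))
  field <- if (is.null(input)) matrix(1 + 0i, nx, ny) else input
  if (!all(dim(field) == c(nx, ny))) {
    stop("`input` field does not match the lateral grid", call. = FALSE)
  }
  apron <- if (boundary == "absorb") {
    outer(apron_profile(nx, absorb_width), apron_profile(ny, absorb_width))
  } else NULL
  power_in <- sum(Mod(field)^2)
  dz <- vx[3]
  for (z in seq_len(nz)) {
    field <- field * exp(1i * k0 * (ri$ri[, , z] - n0) * dz)
    field <- stats::fft(stats::fft(field) * prop, inverse = TRUE) / (nx * ny)
    if (!is.null(apron)) field <- field * apron
  }
  structure(
    list(amplitude = field, dx = vx[1:2], wavelength = wavelength, n0 = n0,
         power_in = power_in, power_out = sum(Mod(field)^2)),
    class = "complex_field")
}

# Super-Gaussian absorbing edge profile on the unit interval.
apron_profile <- function(n, w) {
  u <- (seq_len(n) - 0.5) / n
  e <- pmin(u, 1 - u)
  a <- rep(1, n)
  sel <- e < w
  a[sel] <- exp(-3 * ((w - e[sel]) / w)^4)
  a
}

#' Gaussian beam amplitude for point-stimulus simulations
#'
#' A unit-power Gaussian amplitude spot (intensity FWHM as given) centred on
#' the grid, used as the \code{input} of \code{\link{propagate}} to image a
#' point stimulus through a tissue volume.
#'
#' @param shape Lateral grid size (length 2) in pixels.
#' @param pixel_size Lateral pitch in um (scalar or length 2).
#' @param fwhm Intensity full width at half maximum of the spot, um.
#' @return Complex matrix with total power (sum of squared moduli) 1.
#' @export
gaussian_beam <- function(shape, pixel_size, fwhm) {
  pixel_size <- rep(pixel_size, length.out = 2)
  sigma_i <- fwhm / (2 * sqrt(2 * log(2)))      # intensity sigma
  sigma_a <- sigma_i * sqrt(2)                  # amplitude sigma
  cx <- (shape[1] + 1) / 2
  cy <- (shape[2] + 1) / 2
  gx <- exp(-((seq_len(shape[1]) - cx) * pixel_size[1])^2 / (2 * sigma_a^2))
  gy <- exp(-((seq_len(shape[2]) - cy) * pixel_size[2])^2 / (2 * sigma_a^2))
  amp <- outer(gx, gy)
  amp <- amp / sqrt(sum(amp^2))
  matrix(complex(real = amp), shape[1], shape[2])
}

#' Image an exit field to the far field (2f imaging)
#'
#' Focuses the exit-plane field with an ideal lens: the focal-plane (far
#' field) intensity is the squared modulus of the field's Fourier transform,
#' centred, with pixels uniform in direction sine. The coherent transmitted
#' beam forms the compact core of this image while scattered light lands at
#' larger angles, so \code{\link{psf_metrics}} applied to it separates the
#' unscattered core from the scattering veil.
#'
#' @param field A \code{\link{propagate}} result.
#' @return List: \code{image} (intensity matrix, summing to the exit power),
#'   \code{pixel_deg} (approximate angular pixel pitch in degrees at the
#'   centre of the field).
#' @export
farfield_psf <- function(field) {
  stopifnot(inherits(field, "complex_field"))
  a <- field$amplitude
  nx <- nrow(a); ny <- ncol(a)
  P <- Mod(stats::fft(a))^2 / (nx * ny)
  P <- P[c((nx %/% 2 + 1):nx, 1:(nx %/% 2)), c((ny %/% 2 + 1):ny, 1:(ny %/% 2))]
  lambda <- field$wavelength / 1000
  pixel_deg <- lambda / field$n0 / (nx * field$dx[1]) * 180 / pi
  list(image = P, pixel_deg = pixel_deg)
}

#' Far-field angular power spectrum of an exit field
#'
#' Decomposes the exit-plane field into plane waves by 2D Fourier transform
#' and maps spatial frequency to propagation angle through
#' \eqn{\sin\theta = \lambda_0 f / n_0}. Power is binned over the polar angle
#' (azimuthally integrated); the binned power sums to the total
#' non-evanescent exit power (Parseval).
#'
#' @param field A \code{\link{propagate}} result (class
#'   \code{"complex_field"}).
#' @param dtheta Polar-angle bin width in degrees. Default 1.
#' @return A \code{data.frame} of class \code{"angular_spectrum"} with
#'   columns \code{theta_lo}, \code{theta_hi}, \code{theta_mid} (degrees) and
#'   \code{power}. Attributes: \code{total_power} (non-evanescent),
#'   \code{evanescent_power}, \code{spatial_power} and the unbinned
#'   per-mode angles/powers (\code{raw_theta}, \code{raw_power}).
#' @export
angular_spectrum <- function(field, dtheta = 1) {
  stopifnot(inherits(field, "complex_field"))
  a <- field$amplitude
  nx <- nrow(a); ny <- ncol(a)
  P <- Mod(stats::fft(a))^2 / (nx * ny)
  lambda <- field$wavelength / 1000
  fx <- fft_freq(nx, field$dx[1])
  fy <- fft_freq(ny, field$dx[2])
  sin_t <- sqrt(outer(fx^2, fy^2, "+")) * lambda / field$n0
  keep <- sin_t <= 1
  theta <- asin(sin_t[keep]) * 180 / pi
  pw <- P[keep]
  edges <- seq(0, 90, by = dtheta)
  nbin <- length(edges) - 1L
  bin <- pmin(findInterval(theta, edges, rightmost.closed = TRUE), nbin)
  sums <- rowsum(pw, bin)
  power <- numeric(nbin)
  power[as.integer(rownames(sums))] <- sums[, 1]
  out <- data.frame(theta_lo = edges[-length(edges)], theta_hi = edges[-1],
                    theta_mid = (edges[-length(edges)] + edges[-1]) / 2,
                    power = power)
  attr(out, "total_power") <- sum(pw)
  attr(out, "evanescent_power") <- sum(P[!keep])
  attr(out, "spatial_power") <- sum(Mod(a)^2)
  attr(out, "raw_theta") <- theta
  attr(out, "raw_power") <- pw
  class(out) <- c("angular_spectrum", "data.frame")
  out
}

#' Fraction of power scattered beyond a polar angle
#'
#' The cumulative large-angle scattering fraction: power propagating at
#' angles greater than \code{theta_min} divided by the total non-evanescent
#' power. Large-angle light is the part that builds up image veil.
#'
#' @param spectrum An \code{\link{angular_spectrum}}.
#' @param theta_min Threshold angle in degrees, in (0, 90). Default 30.
#' @return Scalar fraction in [0, 1].
#' @export
large_angle_fraction <- function(spectrum, theta_min = 30) {
  stopifnot(inherits(spectrum, "angular_spectrum"))
  if (theta_min <= 0 || theta_min >= 90) {
    stop("`theta_min` must lie in (0, 90) degrees", call. = FALSE)
  }
  th <- attr(spectrum, "raw_theta")
  pw <- attr(spectrum, "raw_power")
  sum(pw[th > theta_min]) / sum(pw)
}

#' Paired-architecture scattering comparison on identical geometry
#'
#' The core in-silico experiment: paint both chromatin architectures onto the
#' same labeled nucleus volume (identical geometry, identical dense-phase
#' volume), propagate a plane wave through each, and compare their far-field
#' scattering. Reports per-model angular spectra, large-angle (>
#' \code{theta_min}) fractions, integrated side-scattering cross-sections
#' (side-scattered power referred to unit incident irradiance) and the
#' chromocenter/inverted ratio.
#'
#' @param labels A \code{\link{labeled_volume}}.
#' @param params A \code{\link{chromatin_params}}.
#' @param seed Integer seed for the chromocenter painting.
#' @param wavelength Vacuum wavelength, nm. Default 500.
#' @param n_cc Optional forced chromocenter count (see
#'   \code{\link{assign_chromocenters}}).
#' @param theta_min Large-angle threshold in degrees. Default 30.
#' @param sigma Smoothing width in voxels; defaults to
#'   \code{params$smoothing_sigma}.
#' @return Object of class \code{"onl_comparison"}: list with
#'   \code{spectrum_inverted}, \code{spectrum_chromocenter},
#'   \code{fraction_inverted}, \code{fraction_chromocenter},
#'   \code{side_csca_inverted}, \code{side_csca_chromocenter} (um^2),
#'   \code{ratio} (chromocenter / inverted large-angle fraction),
#'   \code{theta_min}, \code{seed}.
#' @export
compare_models <- function(labels, params = chromatin_params(), seed,
                           wavelength = 500, n_cc = NULL, theta_min = 30,
                           sigma = params$smoothing_sigma) {
  stopifnot(inherits(labels, "labeled_volume"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  ri_inv <- smooth_and_embed(assign_inverted(labels, params), params, sigma)
  ri_cc <- smooth_and_embed(
    assign_chromocenters(labels, params, seed = seed, n_cc = n_cc),
    params, sigma)
  sp_inv <- angular_spectrum(propagate(ri_inv, wavelength, params$n0))
  sp_cc <- angular_spectrum(propagate(ri_cc, wavelength, params$n0))
  f_inv <- large_angle_fraction(sp_inv, theta_min)
  f_cc <- large_angle_fraction(sp_cc, theta_min)
  area <- prod(dim(labels$labels)[1:2] * labels$voxel_size[1:2])
  structure(
    list(spectrum_inverted = sp_inv, spectrum_chromocenter = sp_cc,
         fraction_inverted = f_inv, fraction_chromocenter = f_cc,
         side_csca_inverted = f_inv * area,
         side_csca_chromocenter = f_cc * area,
         ratio = f_cc / f_inv, theta_min = theta_min, seed = seed,
         n_cc = n_cc),
    class = "onl_comparison")
}

#' @export
print.onl_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("paired ONL scattering comparison (theta > %g deg):\n",
           "  inverted architecture:      fraction %.5g (side Csca %.5g um^2)\n",
           "  chromocenter architecture:  fraction %.5g (side Csca %.5g um^2)\n",
           "  chromocenter / inverted ratio: %.4g\n"),
    x$theta_min, x$fraction_inverted, x$side_csca_inverted,
    x$fraction_chromocenter, x$side_csca_chromocenter, x$ratio))
  invisible(x)
}
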