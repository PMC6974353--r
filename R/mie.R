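#' Specify a homogeneous sphere in a surrounding medium
#'
#' Bundles the geometric and optical parameters of a single non-absorbing
#' sphere: its diameter, the refractive indices of particle and medium, and
#' the vacuum wavelength of the illumination. The derived Mie size parameter
#' is \eqn{x = \pi d \, n_{med}/\lambda_0}.
#'
#' Two index conventions are common for chromatin models. Either both indices
#' are absolute (e.g. heterochromatin 1.382 in euchromatin 1.357), or the pair
#' is quoted as "1.04 particles in a 1.02 medium", i.e. a ~2\% relative
#' contrast with the absolute scale left implicit. Only the ratio
#' \code{m_particle/m_medium} enters the Mie coefficients; the absolute medium
#' index enters only through the size parameter. \code{n_medium_abs} therefore
#' lets you scale \eqn{x} with an absolute index (such as the euchromatin
#' value 1.357) while quoting the contrast pair; it defaults to
#' \code{m_medium}.
#'
#' @param diameter Sphere diameter in micrometres. Must be positive.
#' @param m_particle Refractive index of the sphere (real, >= 1).
#' @param m_medium Refractive index of the surrounding medium (real, >= 1).
#' @param wavelength Vacuum wavelength in nanometres. Default 500 nm.
#' @param n_medium_abs Absolute medium index used for the size parameter;
#'   defaults to \code{m_medium}.
#' @return An object of class \code{"sphere_spec"}: a list with the input
#'   fields plus \code{m_rel} (relative index) and \code{x} (size parameter).
#' @examples
#' sp <- sphere_spec(2, m_particle = 1.04, m_medium = 1.02)
#' sp$x
#' @export
sphere_spec <- function(diameter, m_particle, m_medium,
                        wavelength = 500, n_medium_abs = m_medium) {
  if (!is.numeric(diameter) || length(diameter) != 1L || !is.finite(diameter) ||
      diameter <= 0) {
    stop("`diameter` must be a single positive number (micrometres)",
         call. = FALSE)
  }
  if (!is.numeric(wavelength) || length(wavelength) != 1L || wavelength <= 0) {
    stop("`wavelength` must be a single positive number (nanometres)",
         call. = FALSE)
  }
  if (m_particle < 1 || m_medium < 1) {
    stop("refractive indices must be real-valued and >= 1", call. = FALSE)
  }
  lambda_um <- wavelength / 1000
  x <- pi * diameter * n_medium_abs / lambda_um
  structure(
    list(diameter = diameter, m_particle = m_particle, m_medium = m_medium,
         wavelength = wavelength, n_medium_abs = n_medium_abs,
         m_rel = m_particle / m_medium, x = x),
    class = "sphere_spec")
}

#' @export
print.sphere_spec <- function(x, ...) {
  cat(sprintf(
    "sphere: d = %g um, m = %.4f/%.4f (m_rel = %.5f), lambda0 = %g nm, x = %.3f\n",
    x$diameter, x$m_particle, x$m_medium, x$m_rel, x$wavelength, x$x))
  invisible(x)
}

# Mie expansion coefficients a_n, b_n for a real relative index.
# Downward recurrence for the logarithmic derivative D_n(mx) (stable),
# upward recurrence for the Riccati-Bessel functions psi_n(x), chi_n(x),
# truncation at the Wiscombe order n_max = x + 4 x^(1/3) + 2.
mie_coefficients <- function(x, m) {
  if (!is.finite(x) || x <= 0) {
    stop("size parameter must be positive and finite", call. = FALSE)
  }
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  mx <- m * x
  nstart <- max(nmax, ceiling(abs(mx))) + 16L
  # D[n] holds the logarithmic derivative D_n(mx)
  D <- numeric(nmax + 1L)
  Dcur <- 0
  for (n in nstart:1) {
    Dprev <- n / mx - 1 / (Dcur + n / mx)
    if (n <= nmax + 1L) D[n] <- Dcur
    Dcur <- Dprev
  }
  a <- complex(nmax)
  b <- complex(nmax)
  psim1 <- sin(x); psim2 <- cos(x)   # psi_0, psi_-1
  chim1 <- cos(x); chim2 <- -sin(x)  # chi_0, chi_-1
  for (k in seq_len(nmax)) {
    psik <- (2 * k - 1) / x * psim1 - psim2
    chik <- (2 * k - 1) / x * chim1 - chim2
    xik   <- complex(real = psik, imaginary = -chik)
    xikm1 <- complex(real = psim1, imaginary = -chim1)
    fa <- D[k] / m + k / x
    fb <- D[k] * m + k / x
    a[k] <- (fa * psik - psim1) / (fa * xik - xikm1)
    b[k] <- (fb * psik - psim1) / (fb * xik - xikm1)
    if (any(!is.finite(c(Re(a[k]), Im(a[k]), Re(b[k]), Im(b[k]))))) {
      stop(sprintf(
        "Mie series failed to converge (non-finite coefficient at order %d, x = %g)",
        k, x), call. = FALSE)
    }
    psim2 <- psim1; psim1 <- psik
    chim2 <- chim1; chim1 <- chik
  }
  list(a = a, b = b, nmax = nmax)
}

#' Mie scattering efficiencies, anisotropy and hiding power of a sphere
#'
#' Computes the scattering and extinction efficiencies \eqn{Q_{sca}},
#' \eqn{Q_{ext}}, the anisotropy factor \eqn{g = \langle\cos\theta\rangle},
#' the scattering cross-section \eqn{C_{sca} = Q_{sca}\,\pi (d/2)^2} and the
#' angle-weighted hiding power for a single non-absorbing sphere, from the
#' Lorenz--Mie partial-wave series.
#'
#' Hiding power ranks how strongly a particle population degrades transmitted
#' image contrast. Light scattered into near-forward angles stays close to
#' the image-forming beam and is nearly harmless; only the side-scattered
#' part builds up the veil that hides detail. The implemented hiding power
#' therefore weights the scattering efficiency by the non-forward fraction of
#' the phase function, \eqn{H = Q_{sca}(1 - g)} (the reduced scattering
#' efficiency). The raw forward-weighted product \eqn{Q_{sca}\,g} is returned
#' alongside as \code{Qg}.
#'
#' @param sphere A \code{\link{sphere_spec}}.
#' @return An object of class \code{"mie_efficiencies"}: list with
#'   \code{Qsca}, \code{Qext}, \code{g}, \code{Csca} (um^2),
#'   \code{H} (= Qsca*(1-g)), \code{Qg} (= Qsca*g), \code{x}, \code{nmax}.
#'   For a zero-contrast sphere (\code{m_rel == 1}) all scattering vanishes
#'   and \code{g} is \code{NA} (the scattering direction is undefined).
#' @examples
#' mie_efficiencies(sphere_spec(2, 1.04, 1.02, n_medium_abs = 1.357))
#' @export
mie_efficiencies <- function(sphere) {
  stopifnot(inherits(sphere, "sphere_spec"))
  x <- sphere$x
  m <- sphere$m_rel
  if (m == 1) {
    # index-matched sphere: no scattering, direction undefined
    return(structure(
      list(Qsca = 0, Qext = 0, g = NA_real_, Csca = 0, H = 0, Qg = 0,
           x = x, nmax = 0L, sphere = sphere),
      class = "mie_efficiencies"))
  }
  co <- mie_coefficients(x, m)
  a <- co$a; b <- co$b; nmax <- co$nmax
  n <- seq_len(nmax)
  Qsca <- (2 / x^2) * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2))
  Qext <- (2 / x^2) * sum((2 * n + 1) * Re(a + b))
  k <- seq_len(nmax - 1L)
  gsum <- sum(k * (k + 2) / (k + 1) *
                Re(a[k] * Conj(a[k + 1L]) + b[k] * Conj(b[k + 1L]))) +
    sum((2 * n + 1) / (n * (n + 1)) * Re(a * Conj(b)))
  g <- 4 / (x^2 * Qsca) * gsum
  Csca <- Qsca * pi * (sphere$diameter / 2)^2
  structure(
    list(Qsca = Qsca, Qext = Qext, g = g, Csca = Csca,
         H = Qsca * (1 - g), Qg = Qsca * g, x = x, nmax = nmax,
         sphere = sphere),
    class = "mie_efficiencies")
}

#' @export
print.mie_efficiencies <- function(x, ...) {
  cat(sprintf(
    "Mie efficiencies (x = %.3f, %d orders):\n  Qsca = %.6g  Qext = %.6g  g = %.6g\n  Csca = %.6g um^2  hiding power Qsca(1-g) = %.6g  Qsca*g = %.6g\n",
    x$x, x$nmax, x$Qsca, x$Qext, x$g, x$Csca, x$H, x$Qg))
  invisible(x)
}

#' Normalized single-sphere scattering phase function
#'
#' Evaluates the unpolarized angular scattering intensity
#' \eqn{p(\theta) \propto (|S_1|^2 + |S_2|^2)/2} of a sphere from the Mie
#' amplitude functions, normalized so that
#' \eqn{\int_0^\pi p(\theta)\, 2\pi \sin\theta \, d\theta = 1}.
#'
#' @param sphere A \code{\link{sphere_spec}} with non-zero index contrast.
#' @param angles Scattering angles in radians, each in \eqn{[0, \pi]}.
#' @return Numeric vector \code{p(angles)} (per steradian).
#' @examples
#' sp <- sphere_spec(2, 1.04, 1.02)
#' th <- seq(0, pi, length.out = 181)
#' p <- phase_function(sp, th)
#' @export
phase_function <- function(sphere, angles) {
  stopifnot(inherits(sphere, "sphere_spec"))
  if (any(!is.finite(angles)) || any(angles < 0 | angles > pi)) {
    stop("`angles` must lie in [0, pi]", call. = FALSE)
  }
  if (sphere$m_rel == 1) {
    stop("zero-contrast sphere: scattering phase function is undefined",
         call. = FALSE)
  }
  co <- mie_coefficients(sphere$x, sphere$m_rel)
  i_raw <- mie_intensity(co, angles)
  # normalization constant by fine-grid Simpson quadrature of i(theta) sin(theta)
  nq <- 2001L
  thq <- seq(0, pi, length.out = nq)
  iq <- mie_intensity(co, thq) * sin(thq)
  h <- pi / (nq - 1L)
  w <- rep(c(4, 2), length.out = nq - 2L)
  Z <- 2 * pi * h / 3 * (iq[1] + iq[nq] + sum(w * iq[2:(nq - 1L)]))
  i_raw / Z
}

# Unpolarized scattered intensity (|S1|^2+|S2|^2)/2 at the given angles,
# using the pi_n/tau_n angular-function recurrences.
mie_intensity <- function(co, angles) {
  a <- co$a; b <- co$b; nmax <- co$nmax
  mu <- cos(angles)
  S1 <- complex(length(mu)); S2 <- complex(length(mu))
  pim1 <- rep(0, length(mu))  # pi_0
  pik <- rep(1, length(mu))   # pi_1
  for (k in seq_len(nmax)) {
    tauk <- k * mu * pik - (k + 1) * pim1
    f <- (2 * k + 1) / (k * (k + 1))
    S1 <- S1 + f * (a[k] * pik + b[k] * tauk)
    S2 <- S2 + f * (a[k] * tauk + b[k] * pik)
    pinew <- ((2 * k + 1) * mu * pik - (k + 1) * pim1) / k
    pim1 <- pik
    pik <- pinew
  }
  (Mod(S1)^2 + Mod(S2)^2) / 2
}

#' Volume-conserving chromocenter-fusion series
#'
#' Models a nucleus whose heterochromatin is split into \code{N} equal
#' chromocenters at conserved total volume: each of the \code{N} sub-spheres
#' has diameter \eqn{d_N = d_{fused} N^{-1/3}}, so the fully fused state
#' (\code{N = 1}) is a single sphere of diameter \code{d_fused}. Sub-spheres
#' are treated as independent scatterers (intensities add); per-nucleus
#' cross-sections and the volume-specific hiding power
#' \eqn{N H(d_N) \pi (d_N/2)^2 / V_{tot} = \tfrac{3}{2} H(d_N)/d_N}
#' are reported per chromocenter count.
#'
#' @param d_fused Diameter (um) of the fully fused chromocenter. A warning is
#'   issued outside the physiological sweep 0.9--4 um.
#' @param counts Integer vector of chromocenter numbers N (each >= 1).
#' @param m_particle,m_medium,wavelength,n_medium_abs Optics of the
#'   sub-spheres, as in \code{\link{sphere_spec}}. Defaults are the
#'   heterochromatin/euchromatin contrast pair (1.04 in 1.02) at 500 nm with
#'   the absolute euchromatin index 1.357 scaling the size parameter.
#' @param volume_fraction Scatterer volume fraction used when
#'   \code{packing_correction} is \code{TRUE}. Default 0.3351.
#' @param packing_correction Apply the dependent-scattering packing factor
#'   \code{\link{dependent_packing_factor}} to the cross-sections?
#'   Default \code{FALSE} (independent scattering).
#' @return A \code{data.frame} of class \code{"fusion_series"} with one row
#'   per N: \code{d_fused}, \code{N}, \code{d_sub}, \code{Qsca}, \code{g},
#'   \code{H}, \code{Csca_per_nucleus} (um^2), \code{volume_specific_H}
#'   (um^-1).
#' @examples
#' fs <- fusion_series(2, counts = c(1, 2, 4, 8, 12))
#' fs$volume_specific_H  # increases with chromocenter number
#' @export
fusion_series <- function(d_fused, counts = 1:12,
                          m_particle = 1.04, m_medium = 1.02,
                          wavelength = 500, n_medium_abs = 1.357,
                          volume_fraction = 0.3351,
                          packing_correction = FALSE) {
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("`counts` must be integers >= 1", call. = FALSE)
  }
  if (d_fused < 0.9 || d_fused > 4) {
    warning(sprintf(
      "d_fused = %g um is outside the modelled chromocenter range 0.9-4 um",
      d_fused))
  }
  pf <- if (packing_correction) dependent_packing_factor(volume_fraction) else 1
  rows <- lapply(counts, function(N) {
    d_sub <- d_fused * N^(-1 / 3)
    eff <- mie_efficiencies(sphere_spec(
      d_sub, m_particle, m_medium, wavelength, n_medium_abs))
    v_tot <- pi / 6 * d_fused^3
    csca_nuc <- N * eff$Csca * pf
    h_area <- N * eff$H * pi * (d_sub / 2)^2 * pf
    data.frame(d_fused = d_fused, N = N, d_sub = d_sub,
               Qsca = eff$Qsca, g = eff$g, H = eff$H,
               Csca_per_nucleus = csca_nuc,
               volume_specific_H = h_area / v_tot)
  })
  out <- do.call(rbind, rows)
  attr(out, "volume_fraction") <- volume_fraction
  attr(out, "packing_correction") <- packing_correction
  class(out) <- c("fusion_series", "data.frame")
  out
}

#' Dependent-scattering packing correction
#'
#' At the volume fractions of packed nuclei, scatterers are correlated and the
#' independent-scattering cross-section overestimates the true one. This
#' multiplicative correction is the Percus--Yevick hard-sphere
#' structure-factor factor \eqn{(1 - vf)^4 / (1 + 2 vf)^2}: 1 in the dilute
#' limit and monotonically decreasing with packing.
#'
#' @param volume_fraction Scatterer volume fraction, in \eqn{[0, 0.64)}
#'   (the random close-packing bound for spheres).
#' @return Scalar correction factor in (0, 1].
#' @examples
#' dependent_packing_factor(0)       # 1
#' dependent_packing_factor(0.3351)  # < 1
#' @export
dependent_packing_factor <- function(volume_fraction) {
  if (!is.numeric(volume_fraction) || any(!is.finite(volume_fraction)) ||
      any(volume_fraction < 0) || any(volume_fraction >= 0.64)) {
    stop("`volume_fraction` must lie in [0, 0.64)", call. = FALSE)
  }
  (1 - volume_fraction)^4 / (1 + 2 * volume_fraction)^2
}
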