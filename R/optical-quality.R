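#' Stripe-projection image series
#'
#' A stack of 2D intensity images, each carrying a sinusoidal stripe pattern
#' of known spatial frequency, as produced by projecting stripe series
#' through a sample.
#'
#' @param images List of non-negative numeric matrices.
#' @param frequencies Spatial frequency of each image in cycles/um.
#' @param pixel_size Pixel pitch in um.
#' @param modulation_axis Image axis along which the sinusoid runs: 1 (rows)
#'   or 2 (columns). Default 1.
#' @return Object of class \code{"stripe_series"}.
#' @export
stripe_series <- function(images, frequencies, pixel_size,
                          modulation_axis = 1L) {
  if (!is.list(images)) images <- list(images)
  if (length(images) != length(frequencies)) {
    stop("one frequency per image is required", call. = FALSE)
  }
  if (any(vapply(images, function(im) any(im < 0), logical(1)))) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  if (!modulation_axis %in% c(1L, 2L)) {
    stop("`modulation_axis` must be 1 or 2", call. = FALSE)
  }
  structure(list(images = images, frequencies = frequencies,
                 pixel_size = pixel_size,
                 modulation_axis = as.integer(modulation_axis)),
            class = "stripe_series")
}

#' Sinusoidal stripe contrast of a single image
#'
#' Averages the image along the direction orthogonal to the stripe
#' modulation and fits the resulting 1D profile to a sine wave
#' (offset + amplitude + phase, frequency refined within ±5\% of the hint).
#' Contrast is \eqn{(I_{max} - I_{min})/(I_{max} + I_{min})} with
#' \eqn{I_{max/min}} the fitted extremes.
#'
#' If the fitted amplitude is indistinguishable from the noise floor
#' (amplitude below three times its standard error), contrast 0 is returned with
#' \code{low_confidence = TRUE} rather than a spurious estimate.
#'
#' @param image Non-negative numeric matrix.
#' @param frequency Frequency hint in cycles/um.
#' @param pixel_size Pixel pitch in um.
#' @param modulation_axis Axis of the sinusoid (1 or 2). Default 1.
#' @param refine Fractional frequency search half-width. Default 0.05.
#' @return List: \code{I_max}, \code{I_min}, \code{contrast},
#'   \code{frequency} (refined, cycles/um), \code{low_confidence}.
#' @export
stripe_contrast <- function(image, frequency, pixel_size,
                            modulation_axis = 1L, refine = 0.05) {
  if (any(image < 0)) stop("intensities must be non-negative", call. = FALSE)
  prof <- if (modulation_axis == 1L) rowMeans(image) else colMeans(image)
  n <- length(prof)
  f_pix <- frequency * pixel_size  # cycles per pixel
  if (f_pix * n < 2) {
    stop("fewer than 2 stripe periods in the image", call. = FALSE)
  }
  xs <- seq_len(n)
  fit_at <- function(fp) {
    X <- cbind(1, sin(2 * pi * fp * xs), cos(2 * pi * fp * xs))
    stats::lm.fit(X, prof)
  }
  rss <- function(fp) sum(fit_at(fp)$residuals^2)
  opt <- stats::optimize(rss, f_pix * c(1 - refine, 1 + refine))
  fit <- fit_at(opt$minimum)
  cf <- fit$coefficients
  amp <- sqrt(cf[2]^2 + cf[3]^2)
  offset <- cf[1]
  sigma_res <- sqrt(sum(fit$residuals^2) / max(n - 3, 1))
  amp_se <- sigma_res * sqrt(2 / n)
  low_conf <- amp < 3 * amp_se
  if (low_conf) {
    return(list(I_max = offset, I_min = offset, contrast = 0,
                frequency = opt$minimum / pixel_size, low_confidence = TRUE))
  }
  list(I_max = unname(offset + amp), I_min = unname(offset - amp),
       contrast = unname(amp / offset),
       frequency = opt$minimum / pixel_size, low_confidence = FALSE)
}

#' Modulation transfer function from sample and reference stripe series
#'
#' Per spatial frequency, the MTF is the ratio of the stripe contrast in the
#' transmitted (sample) image to the contrast in the projected (reference)
#' image, optionally normalized by the MTF of the optical setup alone
#' measured the same way. Negative fitted ratios are floored at 0 and
#' flagged.
#'
#' @param sample,reference \code{\link{stripe_series}} on matching frequency
#'   grids.
#' @param setup Optional \code{\link{stripe_series}} of the setup-only
#'   measurement used for per-frequency normalization.
#' @param um_per_deg Retinal magnification used to express frequencies in
#'   cycles/degree. Default 31 um/deg.
#' @return A \code{data.frame} of class \code{"mtf_curve"}: columns
#'   \code{frequency} (cycles/um), \code{frequency_cpd} (cycles/deg),
#'   \code{mtf}, \code{contrast_sample}, \code{contrast_reference},
#'   \code{flagged}.
#' @export
mtf_curve <- function(sample, reference, setup = NULL, um_per_deg = 31) {
  stopifnot(inherits(sample, "stripe_series"),
            inherits(reference, "stripe_series"))
  if (length(sample$frequencies) != length(reference$frequencies) ||
      any(abs(sample$frequencies - reference$frequencies) >
            1e-8 * pmax(sample$frequencies, 1e-12))) {
    stop("sample and reference frequency grids do not match", call. = FALSE)
  }
  get_contrasts <- function(ss) {
    vapply(seq_along(ss$images), function(i) {
      stripe_contrast(ss$images[[i]], ss$frequencies[i], ss$pixel_size,
                      ss$modulation_axis)$contrast
    }, numeric(1))
  }
  cs <- get_contrasts(sample)
  cr <- get_contrasts(reference)
  mtf <- cs / cr
  if (!is.null(setup)) {
    stopifnot(inherits(setup, "stripe_series"))
    if (any(abs(setup$frequencies - sample$frequencies) >
              1e-8 * pmax(sample$frequencies, 1e-12))) {
      stop("setup frequency grid does not match", call. = FALSE)
    }
    # setup series is assumed measured against the same projected reference
    mtf_setup <- get_contrasts(setup) / cr
    mtf <- mtf / mtf_setup
  }
  flagged <- mtf < 0
  mtf[flagged] <- 0
  out <- data.frame(frequency = sample$frequencies,
                    frequency_cpd = sample$frequencies * um_per_deg,
                    mtf = mtf, contrast_sample = cs, contrast_reference = cr,
                    flagged = flagged)
  out <- out[order(out$frequency), ]
  rownames(out) <- NULL
  class(out) <- c("mtf_curve", "data.frame")
  out
}

#' Strehl ratio as frequency-weighted area under the MTF
#'
#' For thin, nearly phase-neutral samples the Strehl ratio can be computed in
#' the frequency domain as the area under the frequency-weighted MTF,
#' relative to the same area of a reference system:
#' \deqn{SR = \int_band \xi\, MTF(\xi)\, d\xi \; / \; \int_band \xi\,
#' MTF_{ref}(\xi)\, d\xi} evaluated by trapezoid on the measured grid over a
#' frequency band (behaviorally relevant default 0--2 cycles/deg).
#'
#' @param mtf An \code{\link{mtf_curve}} (or data.frame with
#'   \code{frequency_cpd} and \code{mtf}).
#' @param reference Optional reference curve; if omitted the ideal
#'   \code{MTF = 1} over the band is used.
#' @param band Length-2 frequency interval in cycles/deg. Default
#'   \code{c(0, 2)}.
#' @return Object of class \code{"strehl_result"}: list with \code{strehl},
#'   \code{band}, \code{area}, \code{area_reference}.
#' @export
strehl_ratio <- function(mtf, reference = NULL, band = c(0, 2)) {
  area <- weighted_mtf_area(mtf, band)
  area_ref <- if (is.null(reference)) {
    (band[2]^2 - band[1]^2) / 2  # ideal MTF = 1
  } else {
    weighted_mtf_area(reference, band)
  }
  structure(list(strehl = area / area_ref, band = band, area = area,
                 area_reference = area_ref),
            class = "strehl_result")
}

# Trapezoidal integral of xi * MTF(xi) over `band` (cycles/deg), with linear
# interpolation at the band edges.
weighted_mtf_area <- function(mtf, band) {
  x <- mtf$frequency_cpd
  y <- mtf$mtf
  if (min(x) > band[1] + 1e-9 || max(x) < band[2] - 1e-9) {
    stop("MTF curve does not cover the requested band", call. = FALSE)
  }
  keep <- x >= band[1] & x <= band[2]
  xi <- x[keep]; yi <- y[keep]
  if (!any(abs(xi - band[1]) < 1e-12)) {
    xi <- c(band[1], xi); yi <- c(stats::approx(x, y, band[1])$y, yi)
  }
  if (!any(abs(xi - band[2]) < 1e-12)) {
    xi <- c(xi, band[2]); yi <- c(yi, stats::approx(x, y, band[2])$y)
  }
  w <- xi * yi
  sum(diff(xi) * (w[-1] + w[-length(w)]) / 2)
}

#' @export
print.strehl_result <- function(x, ...) {
  cat(sprintf("Strehl ratio %.4f (frequency-weighted MTF area over %g-%g cycles/deg)\n",
              x$strehl, x$band[1], x$band[2]))
  invisible(x)
}

#' Point-spread-function metrics: normalized peak and FWHM
#'
#' Normalizes a background-subtracted point image by its integral intensity
#' over the field of view, then reports the peak (the fraction of total
#' intensity in the brightest pixel inside the analysis ROI), the intensity
#' centroid, and the full width at half maximum of the radially averaged
#' profile about the centroid (linear interpolation at half peak). The
#' normalization makes the peak a veil-sensitive quantity -- diffusely
#' redistributed light lowers it -- while the FWHM tracks the width of the
#' unscattered core only.
#'
#' @param image Numeric matrix (background already subtracted).
#' @param pixel_size Pixel pitch in um.
#' @param roi Optional ROI side length in um, centred on the intensity
#'   centroid (e.g. 40); \code{NULL} uses the full field.
#' @return Object of class \code{"psf_metrics"}: \code{peak} (fraction of
#'   field-of-view intensity), \code{fwhm} (um), \code{centroid} (um),
#'   \code{profile} (radially averaged, data.frame r/intensity).
#' @export
psf_metrics <- function(image, pixel_size, roi = NULL) {
  tot <- sum(image)
  if (!is.finite(tot) || tot <= 0) {
    stop("image integral must be positive", call. = FALSE)
  }
  img <- image / tot
  nx <- nrow(img); ny <- ncol(img)
  xs <- seq_len(nx); ys <- seq_len(ny)
  wx <- rowSums(img); wy <- colSums(img)
  cx <- sum(xs * wx) / sum(wx)
  cy <- sum(ys * wy) / sum(wy)
  if (!is.null(roi)) {
    half <- roi / 2 / pixel_size
    ix <- xs[abs(xs - cx) <= half]
    iy <- ys[abs(ys - cy) <= half]
    sub <- img[ix, iy]
    rx <- ix; ry <- iy
  } else {
    sub <- img
    rx <- xs; ry <- ys
  }
  peak <- max(sub)
  # radial profile about the centroid, half-pixel bins
  r <- sqrt(outer((rx - cx)^2, (ry - cy)^2, "+"))
  bw <- 0.5
  bin <- floor(as.vector(r) / bw)
  prof <- tapply(as.vector(sub), bin, mean)
  rmid <- tapply(as.vector(r), bin, mean)  # mean radius per annulus, not bin centre
  ord <- order(rmid)
  rmid <- as.numeric(rmid[ord]); prof <- as.numeric(prof[ord])
  half_max <- peak / 2
  below <- which(prof < half_max)
  if (length(below) == 0) {
    fwhm <- NA_real_
  } else {
    i2 <- below[1]
    if (i2 == 1L) {
      fwhm <- 2 * rmid[1] * pixel_size
    } else {
      i1 <- i2 - 1L
      r_half <- rmid[i1] + (prof[i1] - half_max) /
        (prof[i1] - prof[i2]) * (rmid[i2] - rmid[i1])
      fwhm <- 2 * r_half * pixel_size
    }
  }
  structure(
    list(peak = peak, fwhm = fwhm,
         centroid = c(cx, cy) * pixel_size,
         profile = data.frame(r = rmid * pixel_size, intensity = prof)),
    class = "psf_metrics")
}

#' @export
print.psf_metrics <- function(x, ...) {
  cat(sprintf("PSF: normalized peak %.4g, FWHM %.3f um, centroid (%.2f, %.2f) um\n",
              x$peak, x$fwhm, x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Diffuse (total) transmission from integrated intensities
#'
#' Fractional transmission of a sample: dark-frame-corrected integrated
#' intensity of the image with the sample in place over the same without the
#' sample.
#'
#' @param sample_img,reference_img Numeric matrices of matching shape.
#' @param dark_img Dark frame (matrix or scalar). Default 0.
#' @return Scalar transmission.
#' @export
diffuse_transmission <- function(sample_img, reference_img, dark_img = 0) {
  if (!all(dim(sample_img) == dim(reference_img))) {
    stop("sample and reference images must have matching shapes", call. = FALSE)
  }
  denom <- sum(reference_img - dark_img)
  if (denom <= 0) stop("reference integral must be positive", call. = FALSE)
  sum(sample_img - dark_img) / denom
}

#' Convert sphere scattering descriptors into a layer MTF
#'
#' Small-angle scattering transfer model for a slab of thickness
#' \code{thickness} containing \code{number_density} spheres: the transmitted
#' contrast at spatial frequency \eqn{\xi} is carried by the unscattered
#' (ballistic) fraction \eqn{e^{-\tau}}, with optical depth
#' \eqn{\tau = \rho\, C_{sca}\, L}, plus the forward-scattered component,
#' whose contrast rolls off as a Gaussian blur of spatial scale
#' \eqn{\sigma_b = \theta_g L / 2} set by the characteristic scattering angle
#' \eqn{\theta_g = \arccos g}:
#' \deqn{MTF(\xi) = e^{-\tau} + (1 - e^{-\tau})\,
#'   e^{-2 \pi^2 \sigma_b^2 \xi^2}.}
#' The form guarantees \eqn{MTF(0) = 1}, is non-increasing in \eqn{\xi}, and
#' at fixed \eqn{\tau} is higher at every frequency for more
#' forward-directed (larger \eqn{g}) scatterers. It is a deliberately simple
#' closed form meant for ranking scattering contributions, not for absolute
#' prediction.
#'
#' @param g Anisotropy factor of the scatterers.
#' @param Qsca Scattering efficiency.
#' @param number_density Scatterers per um^3.
#' @param diameter Scatterer diameter, um.
#' @param thickness Layer thickness, um.
#' @param frequencies Spatial frequencies in cycles/deg.
#' @param um_per_deg Retinal magnification, um/deg. Default 31.
#' @return An \code{\link{mtf_curve}}-style data.frame.
#' @export
scattering_to_mtf <- function(g, Qsca, number_density, diameter, thickness,
                              frequencies, um_per_deg = 31) {
  csca <- Qsca * pi * (diameter / 2)^2
  tau <- number_density * csca * thickness
  if (tau < 0) stop("optical depth must be >= 0", call. = FALSE)
  theta_g <- acos(pmin(pmax(g, -1), 1))
  sigma_b <- theta_g * thickness / 2
  xi_um <- frequencies / um_per_deg
  mtf <- exp(-tau) + (1 - exp(-tau)) * exp(-2 * pi^2 * sigma_b^2 * xi_um^2)
  out <- data.frame(frequency = xi_um, frequency_cpd = frequencies,
                    mtf = mtf, contrast_sample = NA_real_,
                    contrast_reference = NA_real_, flagged = FALSE)
  attr(out, "tau") <- tau
  class(out) <- c("mtf_curve", "data.frame")
  out
}

#' Volume-specific scattering from flow-cytometry events
#'
#' Normalizes each event's side-scattering area by its forward-scattering
#' area (forward scattering taken as the size/volume proxy), yielding a
#' per-event scattering strength per unit material, and summarizes
#' populations by median and interquartile range. Events with non-positive
#' forward scatter are dropped and counted.
#'
#' @param records data.frame with columns \code{fsc_area}, \code{ssc_area}
#'   and optionally \code{label} (population id).
#' @return List: \code{events} (input rows kept, with \code{vss} column),
#'   \code{populations} (per-label median, IQR, n), \code{n_dropped}.
#' @export
volume_specific_scattering <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("fsc_area", "ssc_area") %in% names(records)))
  if (is.null(records$label)) records$label <- "all"
  bad <- !(records$fsc_area > 0)
  kept <- records[!bad, , drop = FALSE]
  kept$vss <- kept$ssc_area / kept$fsc_area
  pops <- do.call(rbind, lapply(split(kept, kept$label), function(d) {
    data.frame(label = d$label[1], n = nrow(d),
               median_vss = stats::median(d$vss),
               iqr_vss = stats::IQR(d$vss))
  }))
  rownames(pops) <- NULL
  list(events = kept, populations = pops, n_dropped = sum(bad))
}

#' Area under the log contrast-sensitivity curve (AULC)
#'
#' Summarizes a behavioral contrast-sensitivity curve as the trapezoidal
#' area of \eqn{\log_{10}} sensitivity (sensitivity = 1/threshold contrast,
#' floored at 1) against spatial frequency over the measured range.
#'
#' @param frequencies Spatial frequencies (cycles/deg), at least 2,
#'   increasing.
#' @param threshold_contrast Threshold contrast per frequency, in (0, 1].
#' @return Scalar AULC (log10-units x cycles/deg).
#' @export
aulc <- function(frequencies, threshold_contrast) {
  if (length(frequencies) < 2) {
    stop("at least two frequencies are required", call. = FALSE)
  }
  if (length(threshold_contrast) != length(frequencies)) {
    stop("one threshold per frequency is required", call. = FALSE)
  }
  if (any(threshold_contrast <= 0 | threshold_contrast > 1)) {
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  }
  ord <- order(frequencies)
  x <- frequencies[ord]
  s <- pmax(1 / threshold_contrast[ord], 1)
  y <- log10(s)
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}
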