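# Apply a noise model to an intensity image under the current RNG stream.
apply_noise <- function(img, noise = c("none", "gaussian", "poisson"),
                        noise_param = 1) {
  noise <- match.arg(noise)
  switch(noise,
         none = img,
         gaussian = img + matrix(stats::rnorm(length(img), 0, noise_param),
                                 nrow(img)),
         poisson = {
           # shot-like noise: counts at `noise_param` photons per intensity unit
           counts <- stats::rpois(length(img), as.vector(img) * noise_param)
           matrix(counts / noise_param, nrow(img))
         })
}

#' Generate a sample/reference stripe-stack pair with known ground truth
#'
#' Emulates a stripe micro-projection measurement: the reference stack holds
#' clean sinusoids of the requested contrast; the sample stack is the
#' reference attenuated by a scattering veil -- a fraction \code{veil} of the
#' light redistributed uniformly, \code{(1 - v) I + v mean(I)} -- optionally
#' multiplied by a frequency-dependent transfer profile, plus shot-like or
#' Gaussian noise. With no profile the ground-truth MTF of the pair is
#' exactly \code{1 - veil} at every frequency.
#'
#' @param frequencies Stripe frequencies, cycles/um.
#' @param contrast Modulation contrast of the projected stripes, in (0, 1].
#'   Default 0.37.
#' @param veil Veil fraction v in [0, 1). Default 0.
#' @param shape Image size in pixels (length 2). Default \code{c(96, 256)}.
#' @param pixel_size Pixel pitch, um. Default 1.
#' @param mean_intensity Mean image intensity (arbitrary units). Default 100.
#' @param noise \code{"none"}, \code{"gaussian"} or \code{"poisson"}.
#' @param noise_param Gaussian SD, or photons per intensity unit for Poisson.
#' @param mtf_profile Optional function of frequency (cycles/um) returning a
#'   per-frequency modulation factor applied to the sample on top of the
#'   veil.
#' @param seed Integer seed (required when noise is stochastic).
#' @return List: \code{sample}, \code{reference} (both
#'   \code{\link{stripe_series}}), \code{truth} (contrast, veil, expected
#'   MTF per frequency, seed).
#' @export
make_stripe_stack <- function(frequencies, contrast = 0.37, veil = 0,
                              shape = c(96L, 256L), pixel_size = 1,
                              mean_intensity = 100,
                              noise = c("none", "gaussian", "poisson"),
                              noise_param = 1, mtf_profile = NULL,
                              seed = 1) {
  noise <- match.arg(noise)
  if (contrast <= 0 || contrast > 1) stop("`contrast` must be in (0, 1]",
                                          call. = FALSE)
  if (veil < 0 || veil >= 1) stop("`veil` must be in [0, 1)", call. = FALSE)
  xs <- seq_len(shape[2]) * pixel_size
  prof_fun <- if (is.null(mtf_profile)) function(f) 1 else mtf_profile
  with_seed(seed, {
    ref <- list(); smp <- list()
    for (i in seq_along(frequencies)) {
      modul <- sin(2 * pi * frequencies[i] * xs)
      base <- mean_intensity * (1 + contrast * modul)
      ref_img <- matrix(rep(base, each = shape[1]), shape[1], shape[2])
      m_i <- (1 - veil) * prof_fun(frequencies[i])
      smp_img <- mean_intensity * (1 + contrast * m_i *
                                     rep(modul, each = shape[1]))
      dim(smp_img) <- shape
      ref[[i]] <- ref_img
      smp[[i]] <- apply_noise(smp_img, noise, noise_param)
    }
    truth_mtf <- (1 - veil) * vapply(frequencies, prof_fun, numeric(1))
    list(sample = stripe_series(smp, frequencies, pixel_size, 2L),
         reference = stripe_series(ref, frequencies, pixel_size, 2L),
         truth = list(contrast = contrast, veil = veil,
                      mtf = truth_mtf, frequencies = frequencies,
                      noise = noise, seed = seed))
  })
}

#' Generate a point-image with a Gaussian core and a uniform veil
#'
#' Emulates a point-stimulus projection: a Gaussian core of the requested
#' FWHM carrying a fraction \code{1 - veil} of the total energy, plus a
#' uniform veil carrying the rest. Total image energy is independent of the
#' veil fraction by construction, mirroring scattering that redistributes
#' but does not absorb light.
#'
#' @param fwhm Core FWHM in um.
#' @param veil Veil energy fraction in [0, 1). Default 0.
#' @param pixel_size Pixel pitch, um. Default 0.5.
#' @param shape Image size in pixels. Default \code{c(160, 160)}.
#' @param total_energy Total image energy. Default 1.
#' @param noise,noise_param As in \code{\link{make_stripe_stack}}.
#' @param seed Integer seed.
#' @return List: \code{image} (matrix), \code{truth} (fwhm, veil,
#'   core_energy, total_energy, seed).
#' @export
make_psf_image <- function(fwhm, veil = 0, pixel_size = 0.5,
                           shape = c(161L, 161L), total_energy = 1,
                           noise = c("none", "gaussian", "poisson"),
                           noise_param = 1, seed = 1) {
  noise <- match.arg(noise)
  if (veil < 0 || veil >= 1) stop("`veil` must be in [0, 1)", call. = FALSE)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / pixel_size  # pixels
  cx <- (shape[1] + 1) / 2; cy <- (shape[2] + 1) / 2
  gx <- exp(-(seq_len(shape[1]) - cx)^2 / (2 * sigma^2))
  gy <- exp(-(seq_len(shape[2]) - cy)^2 / (2 * sigma^2))
  core <- outer(gx, gy)
  core <- core / sum(core) * (1 - veil) * total_energy
  img <- core + veil * total_energy / prod(shape)
  img <- with_seed(seed, apply_noise(img, noise, noise_param))
  list(image = img,
       truth = list(fwhm = fwhm, veil = veil,
                    core_energy = (1 - veil) * total_energy,
                    total_energy = total_energy, pixel_size = pixel_size,
                    seed = seed))
}

#' Generate a synthetic flow-cytometry event table
#'
#' Draws forward- and side-scattering areas for one or more populations from
#' log-normal distributions with the requested medians (log-normal medians
#' are exactly the location parameters, so population ratios of medians are
#' controlled exactly).
#'
#' @param populations data.frame with columns \code{n}, \code{fsc_median},
#'   \code{ssc_median}, \code{spread} (log-scale SD; 0 gives identical
#'   events) and optionally \code{label}.
#' @param seed Integer seed.
#' @return data.frame with columns \code{fsc_area}, \code{ssc_area},
#'   \code{label}.
#' @export
make_facs_table <- function(populations, seed = 1) {
  stopifnot(is.data.frame(populations),
            all(c("n", "fsc_median", "ssc_median", "spread") %in%
                  names(populations)))
  if (is.null(populations$label)) {
    populations$label <- paste0("pop", seq_len(nrow(populations)))
  }
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(populations)), function(i) {
      p <- populations[i, ]
      data.frame(
        fsc_area = p$fsc_median * exp(stats::rnorm(p$n, 0, p$spread)),
        ssc_area = p$ssc_median * exp(stats::rnorm(p$n, 0, p$spread)),
        label = p$label)
    }))
  })
}

#' Simulate optomotor staircase trials from a known threshold curve
#'
#' Emulates descending-contrast optomotor testing: per spatial frequency,
#' display contrast steps down in 5\% steps to 10\% and 2\% steps below, and
#' each presentation yields a yes/no tracking response -- yes with
#' probability \code{1 - lapse_rate} when the contrast is at or above the
#' true threshold, and \code{lapse_rate} otherwise.
#'
#' @param threshold_curve data.frame with columns \code{frequency}
#'   (cycles/deg) and \code{threshold_contrast} in (0, 1].
#' @param lapse_rate Probability of an erroneous response. Default 0.
#' @param n_trials Presentations per contrast step. Default 5.
#' @param seed Integer seed.
#' @return data.frame of trials: \code{frequency}, \code{contrast},
#'   \code{response} (0/1); attribute \code{truth} holds the input curve.
#' @export
make_cs_trials <- function(threshold_curve, lapse_rate = 0, n_trials = 5,
                           seed = 1) {
  stopifnot(is.data.frame(threshold_curve),
            all(c("frequency", "threshold_contrast") %in%
                  names(threshold_curve)))
  steps <- round(c(seq(1, 0.10, by = -0.05), seq(0.08, 0.02, by = -0.02)), 2)
  out <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(threshold_curve)), function(i) {
      thr <- threshold_curve$threshold_contrast[i]
      do.call(rbind, lapply(steps, function(ct) {
        p_yes <- if (ct >= thr) 1 - lapse_rate else lapse_rate
        data.frame(frequency = threshold_curve$frequency[i],
                   contrast = ct,
                   response = stats::rbinom(n_trials, 1, p_yes))
      }))
    }))
  })
  attr(out, "truth") <- threshold_curve
  out
}

#' Estimate threshold contrasts from staircase trial tables
#'
#' Per frequency, the estimated threshold is the lowest tested contrast at
#' which the majority response is "yes" and every higher contrast also has a
#' majority "yes" (the sustained-tracking criterion of descending
#' staircases). Frequencies with no sustained positive response get
#' \code{NA}.
#'
#' @param trials Trial table as produced by \code{\link{make_cs_trials}}.
#' @return data.frame: \code{frequency}, \code{threshold_contrast}.
#' @export
estimate_thresholds <- function(trials) {
  stopifnot(all(c("frequency", "contrast", "response") %in% names(trials)))
  res <- lapply(split(trials, trials$frequency), function(d) {
    agg <- stats::aggregate(response ~ contrast, d, mean)
    agg <- agg[order(-agg$contrast), ]
    pos <- agg$response > 0.5
    run <- cumprod(pos) > 0  # TRUE while every higher contrast was positive
    thr <- if (any(run)) min(agg$contrast[run]) else NA_real_
    data.frame(frequency = d$frequency[1], threshold_contrast = thr)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$frequency), , drop = FALSE]
}
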