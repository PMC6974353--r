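#' @useDynLib onloptics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All stochastic operations in the package draw from
# one such explicitly-seeded stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv), add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

#' Labeled 3D nucleus volume
#'
#' A 3D integer grid in which 0 is background and each positive integer k
#' marks the voxels of nucleus k, together with the voxel pitch.
#'
#' @param labels 3D integer array (0 = background).
#' @param voxel_size Voxel pitch in micrometres: a scalar (isotropic) or a
#'   length-3 vector (x, y, z).
#' @param meta Optional list of generator metadata.
#' @return Object of class \code{"labeled_volume"}.
#' @export
labeled_volume <- function(labels, voxel_size, meta = list()) {
  if (length(dim(labels)) != 3L) stop("`labels` must be a 3D array", call. = FALSE)
  if (any(labels < 0) || any(labels != round(labels))) {
    stop("`labels` must contain non-negative integers", call. = FALSE)
  }
  voxel_size <- expand_voxel(voxel_size)
  structure(list(labels = labels, voxel_size = voxel_size, meta = meta),
            class = "labeled_volume")
}

expand_voxel <- function(voxel_size) {
  if (!is.numeric(voxel_size) || !length(voxel_size) %in% c(1L, 3L) ||
      any(voxel_size <= 0)) {
    stop("`voxel_size` must be one or three positive numbers (um)", call. = FALSE)
  }
  if (length(voxel_size) == 1L) rep(voxel_size, 3L) else voxel_size
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("labeled volume: %d x %d x %d voxels at (%g, %g, %g) um, %d nuclei\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

#' Chromatin refractive-index parameters
#'
#' Holds the two-phase chromatin optics: euchromatin index \code{n1},
#' heterochromatin index \code{n2}, surround (interphotoreceptor matrix)
#' index \code{n0}, the admissible range of chromocenter counts for the
#' multi-chromocenter architecture, and the Gaussian smoothing width applied
#' to painted volumes.
#'
#' @param n1 Euchromatin refractive index. Default 1.357.
#' @param n2 Heterochromatin refractive index. Default 1.382.
#' @param n0 Surround refractive index. Default 1.33.
#' @param n_cc_range Integer interval (length 2) of chromocenter counts drawn
#'   per nucleus. Default \code{c(8, 12)}.
#' @param smoothing_sigma Gaussian smoothing width in voxels. Default 2.
#' @return Object of class \code{"chromatin_params"}.
#' @export
chromatin_params <- function(n1 = 1.357, n2 = 1.382, n0 = 1.33,
                             n_cc_range = c(8L, 12L), smoothing_sigma = 2) {
  if (!(n2 >= n1 && n1 >= n0)) {
    stop("require n2 >= n1 >= n0", call. = FALSE)
  }
  if (length(n_cc_range) != 2L || any(n_cc_range < 1) || any(n_cc_range > 64) ||
      n_cc_range[1] > n_cc_range[2]) {
    stop("`n_cc_range` must be an increasing integer interval within [1, 64]",
         call. = FALSE)
  }
  if (smoothing_sigma < 0) stop("`smoothing_sigma` must be >= 0", call. = FALSE)
  structure(list(n1 = n1, n2 = n2, n0 = n0,
                 n_cc_range = as.integer(round(n_cc_range)),
                 smoothing_sigma = smoothing_sigma),
            class = "chromatin_params")
}

#' Refractive-index volume
#'
#' @param ri 3D numeric array of refractive indices.
#' @param voxel_size Voxel pitch in micrometres (scalar or length 3).
#' @param model Provenance string, e.g. \code{"inverted"},
#'   \code{"chromocenter"}, \code{"phantom"}.
#' @param seed Seed used to build the volume, if any.
#' @param meta Optional list (per-nucleus statistics etc.).
#' @return Object of class \code{"ri_volume"}.
#' @export
ri_volume <- function(ri, voxel_size, model = "custom", seed = NULL,
                      meta = list()) {
  if (length(dim(ri)) != 3L) stop("`ri` must be a 3D array", call. = FALSE)
  if (any(!is.finite(ri))) stop("`ri` contains non-finite values", call. = FALSE)
  structure(list(ri = ri, voxel_size = expand_voxel(voxel_size), model = model,
                 seed = seed, meta = meta),
            class = "ri_volume")
}

#' @export
print.ri_volume <- function(x, ...) {
  d <- dim(x$ri)
  cat(sprintf(
    "refractive-index volume (%s): %d x %d x %d voxels at (%g, %g, %g) um, n in [%.4f, %.4f]\n",
    x$model, d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
    x$voxel_size[3], min(x$ri), max(x$ri)))
  invisible(x)
}

# 3D Euclidean distance transform (physical units) from TRUE voxels to the
# nearest FALSE voxel, via the compiled Felzenszwalb-Huttenlocher transform.
edt3d <- function(mask, spacing = c(1, 1, 1)) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  out <- .edt3d_cpp(as.logical(mask), as.integer(d), as.numeric(spacing))
  dim(out) <- d
  out
}

#' Generate a packed-nuclei labeled volume
#'
#' Random sequential addition of non-overlapping, axis-aligned ellipsoidal
#' nuclei with mildly eccentric axes (a synthetic stand-in for a segmented
#' photoreceptor-nuclei volume). Placement, radii and eccentricities are
#' drawn from one explicitly seeded stream, so identical arguments give
#' voxel-identical volumes.
#'
#' @param n_nuclei Number of nuclei requested.
#' @param domain_shape Grid size in voxels, length 3. Default
#'   \code{c(256, 256, 128)}.
#' @param voxel_size Voxel pitch in micrometres (scalar or length 3).
#'   Default 0.166.
#' @param radius_mean,radius_sd Mean and SD (um) of the nucleus equivalent
#'   radius. Defaults 2.8 and 0.3 um (rod-nucleus scale).
#' @param axis_ratio_range Range of per-axis eccentricity factors applied to
#'   the drawn radius. Default \code{c(0.8, 1.2)}.
#' @param max_volume_fraction Reject the request up front if the expected
#'   packing exceeds this fraction. Default 0.55.
#' @param max_attempts Placement attempts per nucleus before giving up.
#' @param seed Integer seed (required; determinism contract).
#' @return A \code{\link{labeled_volume}}; \code{meta} reports the achieved
#'   count, per-nucleus centres/semi-axes and the achieved volume fraction.
#' @examples
#' lv <- generate_packed_nuclei(4, c(64, 64, 48), 0.33, seed = 1)
#' @export
generate_packed_nuclei <- function(n_nuclei,
                                   domain_shape = c(256L, 256L, 128L),
                                   voxel_size = 0.166,
                                   radius_mean = 2.8, radius_sd = 0.3,
                                   axis_ratio_range = c(0.8, 1.2),
                                   max_volume_fraction = 0.55,
                                   max_attempts = 500L,
                                   seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  voxel_size <- expand_voxel(voxel_size)
  domain_shape <- as.integer(domain_shape)
  vol_domain <- prod(domain_shape) * prod(voxel_size)
  vf_req <- n_nuclei * 4 / 3 * pi * radius_mean^3 / vol_domain
  if (vf_req > max_volume_fraction) {
    stop(sprintf(
      "requested packing fraction %.3f exceeds max_volume_fraction %.3f",
      vf_req, max_volume_fraction), call. = FALSE)
  }
  labels <- array(0L, domain_shape)
  meta <- list(centers = matrix(NA_real_, n_nuclei, 3L),
               semi_axes = matrix(NA_real_, n_nuclei, 3L))
  achieved <- 0L
  with_seed(seed, {
    for (k in seq_len(n_nuclei)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        r <- max(stats::rnorm(1, radius_mean, radius_sd), 2 * max(voxel_size))
        ax <- r * stats::runif(3, axis_ratio_range[1], axis_ratio_range[2])
        ax_vox <- ax / voxel_size
        lo <- ax_vox + 1
        hi <- domain_shape - ax_vox
        if (any(hi <= lo)) next  # nucleus does not fit the domain
        ctr <- stats::runif(3, lo, hi)
        bb_lo <- pmax(1L, floor(ctr - ax_vox))
        bb_hi <- pmin(domain_shape, ceiling(ctr + ax_vox))
        ix <- bb_lo[1]:bb_hi[1]; iy <- bb_lo[2]:bb_hi[2]; iz <- bb_lo[3]:bb_hi[3]
        ex <- ((ix - ctr[1]) / ax_vox[1])^2
        ey <- ((iy - ctr[2]) / ax_vox[2])^2
        ez <- ((iz - ctr[3]) / ax_vox[3])^2
        inside <- outer(outer(ex, ey, "+"), ez, "+") <= 1
        sub <- labels[ix, iy, iz]
        if (any(sub[inside] != 0L)) next
        sub[inside] <- k
        labels[ix, iy, iz] <- sub
        meta$centers[k, ] <- ctr
        meta$semi_axes[k, ] <- ax
        achieved <- k
        placed <- TRUE
        break
      }
      if (!placed) {
        stop(sprintf(
          "packing failure: placed %d of %d nuclei within %d attempts each",
          achieved, n_nuclei, max_attempts), call. = FALSE)
      }
    }
  })
  meta$achieved <- achieved
  meta$volume_fraction <- sum(labels > 0L) / prod(domain_shape)
  meta$seed <- seed
  labeled_volume(labels, voxel_size, meta)
}

#' Single-sphere refractive-index phantom
#'
#' A centred homogeneous sphere of index \code{n0 + delta_n} in a uniform
#' background \code{n0}; the standard fixture for validating the beam
#' propagator against single-sphere Mie theory.
#'
#' @param diameter Sphere diameter in um.
#' @param delta_n Index contrast of the sphere over the background.
#' @param shape Grid size in voxels (length 3).
#' @param voxel_size Voxel pitch (um), scalar or length 3.
#' @param n0 Background refractive index. Default 1.33.
#' @return An \code{\link{ri_volume}} with \code{model = "phantom"}.
#' @export
sphere_phantom <- function(diameter, delta_n, shape = c(256L, 256L, 64L),
                           voxel_size = 0.083, n0 = 1.33) {
  voxel_size <- expand_voxel(voxel_size)
  shape <- as.integer(shape)
  ctr <- (shape + 1) / 2
  rx <- (seq_len(shape[1]) - ctr[1]) * voxel_size[1]
  ry <- (seq_len(shape[2]) - ctr[2]) * voxel_size[2]
  rz <- (seq_len(shape[3]) - ctr[3]) * voxel_size[3]
  r2 <- outer(outer(rx^2, ry^2, "+"), rz^2, "+")
  ri <- array(n0, shape)
  ri[r2 <= (diameter / 2)^2] <- n0 + delta_n
  ri_volume(ri, voxel_size, model = "phantom")
}

# Iterate over nuclei: returns list per label with voxel linear indices and
# bounding-box info, computed in a single pass over the volume.
nucleus_index <- function(labels) {
  idx <- which(labels > 0L)
  lab <- labels[idx]
  split(idx, lab)
}

# For one nucleus: linear indices -> padded bounding-box crop returning the
# logical mask, the offset, and functions mapping sub-indices back.
crop_mask <- function(labels, idx) {
  d <- dim(labels)
  ai <- arrayInd(idx, d)
  lo <- pmax(apply(ai, 2, min) - 1L, 1L)
  hi <- pmin(apply(ai, 2, max) + 1L, d)
  sub_dim <- hi - lo + 1L
  mask <- array(FALSE, sub_dim)
  sub_ai <- sweep(ai, 2, lo - 1L)
  sub_lin <- sub_ai[, 1] + (sub_ai[, 2] - 1L) * sub_dim[1] +
    (sub_ai[, 3] - 1L) * sub_dim[1] * sub_dim[2]
  mask[sub_lin] <- TRUE
  list(mask = mask, lo = lo, dim = sub_dim, sub_lin = sub_lin, ai = ai)
}

#' Paint the inverted (rod-like) chromatin architecture
#'
#' Splits every nucleus into a core and a shell of equal volume by
#' morphological depth (Euclidean distance to the nucleus border) and assigns
#' the dense heterochromatin index \code{n2} to the core and the euchromatin
#' index \code{n1} to the shell -- the single-central-chromocenter geometry of
#' inverted rod nuclei. Background voxels get the surround index \code{n0}.
#'
#' Voxels are ranked by distance to the border (deepest first); ties are
#' broken by distance to the nucleus centroid so the core stays concentric.
#' The core is exactly \code{round(V/2)} voxels, so both phases occupy half
#' the nucleus volume to within one voxel. Nuclei smaller than 16 voxels
#' cannot be split meaningfully and are assigned the uniform mean index with
#' a warning.
#'
#' @param labels A \code{\link{labeled_volume}}.
#' @param params A \code{\link{chromatin_params}}.
#' @return An \code{\link{ri_volume}} (\code{model = "inverted"}, unsmoothed;
#'   apply \code{\link{smooth_and_embed}} for the simulation-ready field).
#'   \code{meta$nuclei} tabulates per-nucleus voxel and core counts.
#' @export
assign_inverted <- function(labels, params = chromatin_params()) {
  stopifnot(inherits(labels, "labeled_volume"),
            inherits(params, "chromatin_params"))
  ri <- array(params$n0, dim(labels$labels))
  nuc <- nucleus_index(labels$labels)
  stats_rows <- list()
  for (nm in names(nuc)) {
    idx <- nuc[[nm]]
    V <- length(idx)
    if (V < 16L) {
      warning(sprintf("nucleus %s has only %d voxels; assigned uniform mean index",
                      nm, V))
      ri[idx] <- (params$n1 + params$n2) / 2
      stats_rows[[nm]] <- data.frame(label = as.integer(nm), voxels = V,
                                     core_voxels = NA_integer_)
      next
    }
    cm <- crop_mask(labels$labels, idx)
    depth <- edt3d(cm$mask, labels$voxel_size)[cm$sub_lin]
    ctr <- colMeans(cm$ai)
    dc <- sqrt(colSums((t(cm$ai) - ctr)^2 * labels$voxel_size^2))
    ncore <- round(V / 2)
    ord <- order(-depth, dc)
    ri[idx] <- params$n1
    ri[idx[ord[seq_len(ncore)]]] <- params$n2
    stats_rows[[nm]] <- data.frame(label = as.integer(nm), voxels = V,
                                   core_voxels = ncore)
  }
  ri_volume(ri, labels$voxel_size, model = "inverted",
            meta = list(nuclei = do.call(rbind, stats_rows), params = params))
}

#' Paint the multi-chromocenter (conventional) chromatin architecture
#'
#' Emulates a conventional nucleus with several peripheral heterochromatin
#' bodies: per nucleus, a chromocenter count is drawn from
#' \code{params$n_cc_range}, that many seed points are picked uniformly
#' inside the mask, and voxels close to either the nucleus border (a
#' one-voxel shell) or one of the seeds are assigned the dense index
#' \code{n2}, growing outward from the seeds by Euclidean distance until the
#' dense phase occupies exactly half the nucleus volume. Remaining voxels get
#' \code{n1}; background gets \code{n0}.
#'
#' Because the dense-phase budget is the same \code{round(V/2)} as in
#' \code{\link{assign_inverted}}, the two architectures on the same labels
#' have identical per-nucleus mean refractive index and differ only in the
#' spatial arrangement of the phases.
#'
#' @param labels A \code{\link{labeled_volume}}.
#' @param params A \code{\link{chromatin_params}}.
#' @param seed Integer seed for chromocenter counts and positions (required).
#' @param n_cc Optional fixed chromocenter count overriding
#'   \code{params$n_cc_range} (used to sweep architectures between fully
#'   fused, 1, and conventional, 8--12).
#' @return An \code{\link{ri_volume}} (\code{model = "chromocenter"},
#'   unsmoothed). \code{meta$nuclei} tabulates per-nucleus voxel counts and
#'   the drawn chromocenter numbers.
#' @export
assign_chromocenters <- function(labels, params = chromatin_params(), seed,
                                 n_cc = NULL) {
  stopifnot(inherits(labels, "labeled_volume"),
            inherits(params, "chromatin_params"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  ri <- array(params$n0, dim(labels$labels))
  nuc <- nucleus_index(labels$labels)
  stats_rows <- list()
  shell_d <- 1.5 * min(labels$voxel_size)  # one-voxel border layer
  with_seed(seed, {
    for (nm in names(nuc)) {
      idx <- nuc[[nm]]
      V <- length(idx)
      if (V < 16L) {
        warning(sprintf("nucleus %s has only %d voxels; assigned uniform mean index",
                        nm, V))
        ri[idx] <- (params$n1 + params$n2) / 2
        stats_rows[[nm]] <- data.frame(label = as.integer(nm), voxels = V,
                                       n_cc = NA_integer_)
        next
      }
      ncc <- if (is.null(n_cc)) {
        sample(params$n_cc_range[1]:params$n_cc_range[2], 1L)
      } else as.integer(n_cc)
      seeds <- sample.int(V, min(ncc, V))
      cm <- crop_mask(labels$labels, idx)
      depth <- edt3d(cm$mask, labels$voxel_size)[cm$sub_lin]
      xyz <- sweep(cm$ai, 2, labels$voxel_size, "*")
      d_seed <- rep(Inf, V)
      for (s in seeds) {
        ds <- sqrt(colSums((t(xyz) - xyz[s, ])^2))
        d_seed <- pmin(d_seed, ds)
      }
      budget <- round(V / 2)
      priority <- ifelse(depth <= shell_d, 0, d_seed)
      ord <- order(priority, d_seed, seq_len(V))
      ri[idx] <- params$n1
      ri[idx[ord[seq_len(budget)]]] <- params$n2
      stats_rows[[nm]] <- data.frame(label = as.integer(nm), voxels = V,
                                     n_cc = ncc)
    }
  })
  ri_volume(ri, labels$voxel_size, model = "chromocenter", seed = seed,
            meta = list(nuclei = do.call(rbind, stats_rows), params = params,
                        n_cc_forced = n_cc))
}

#' Gaussian-smooth a refractive-index volume
#'
#' Applies an isotropic Gaussian blur of width \code{sigma} voxels to the
#' index perturbation \code{ri - n0} (periodic boundaries, implemented in the
#' Fourier domain), leaving the background level untouched. Smoothing
#' redistributes optical path but conserves it: the volume sum of
#' \code{ri - n0} is unchanged to machine precision.
#'
#' @param ri An \code{\link{ri_volume}}.
#' @param params A \code{\link{chromatin_params}} supplying \code{n0} and the
#'   default \code{sigma}.
#' @param sigma Gaussian width in voxels; overrides
#'   \code{params$smoothing_sigma}. \code{sigma = 0} returns the input
#'   unchanged.
#' @return The smoothed \code{\link{ri_volume}}.
#' @export
smooth_and_embed <- function(ri, params = chromatin_params(),
                             sigma = params$smoothing_sigma) {
  stopifnot(inherits(ri, "ri_volume"))
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (sigma == 0) return(ri)
  d <- dim(ri$ri)
  f <- ri$ri - params$n0
  FT <- stats::fft(f)
  gx <- exp(-2 * pi^2 * sigma^2 * fft_freq(d[1])^2)
  gy <- exp(-2 * pi^2 * sigma^2 * fft_freq(d[2])^2)
  gz <- exp(-2 * pi^2 * sigma^2 * fft_freq(d[3])^2)
  gxy <- outer(gx, gy)
  for (k in seq_len(d[3])) FT[, , k] <- FT[, , k] * (gxy * gz[k])
  sm <- Re(stats::fft(FT, inverse = TRUE)) / prod(d)
  out <- ri
  out$ri <- sm + params$n0
  out$meta$smoothing_sigma <- sigma
  out
}

# DFT sample frequencies in cycles per sample, matching stats::fft ordering.
fft_freq <- function(n, d = 1) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / (n * d)
}
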