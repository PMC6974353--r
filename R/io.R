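#' Write a labeled or refractive-index volume as multi-page TIFF
#'
#' Volumes are stored as one 32-bit float TIFF page per z-slice. Because the
#' TIFF writer stores values on a [0, 1] scale, data are mapped through an
#' affine offset/scale recorded -- together with the voxel size, volume kind
#' and provenance -- in a JSON sidecar next to the image
#' (\code{<path>.json}). \code{\link{read_volume}} reverses the mapping;
#' label volumes are rounded back to exact integers.
#'
#' @param x A \code{\link{labeled_volume}} or \code{\link{ri_volume}}.
#' @param path Output TIFF path (the sidecar gets \code{.json} appended).
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "labeled_volume")) {
    arr <- x$labels
    kind <- "labels"
    extra <- list()
  } else if (inherits(x, "ri_volume")) {
    arr <- x$ri
    kind <- "ri"
    extra <- list(model = x$model, seed = x$seed)
  } else {
    stop("`x` must be a labeled_volume or ri_volume", call. = FALSE)
  }
  lo <- min(arr); hi <- max(arr)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(arr)[3]),
                  function(k) (arr[, , k] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- c(list(kind = kind, dim = dim(arr), voxel_size = x$voxel_size,
                 offset = lo, scale = scale), extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a volume written by \code{\link{write_volume}}
#'
#' @param path TIFF path with its \code{<path>.json} sidecar present.
#' @return A \code{\link{labeled_volume}} or \code{\link{ri_volume}},
#'   according to the sidecar's \code{kind}.
#' @export
read_volume <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (!file.exists(sidecar)) {
    stop("missing metadata sidecar: ", sidecar, call. = FALSE)
  }
  meta <- tryCatch(jsonlite::read_json(sidecar, simplifyVector = TRUE),
                   error = function(e) stop("corrupt metadata sidecar: ",
                                            conditionMessage(e), call. = FALSE))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("not a readable TIFF: ",
                                             conditionMessage(e), call. = FALSE))
  arr <- array(0, meta$dim)
  if (length(pages) != meta$dim[3]) {
    stop("TIFF page count does not match recorded volume depth", call. = FALSE)
  }
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * meta$scale + meta$offset
  if (identical(meta$kind, "labels")) {
    labeled_volume(array(as.integer(round(arr)), meta$dim), meta$voxel_size)
  } else {
    ri_volume(arr, meta$voxel_size,
              model = if (is.null(meta$model)) "custom" else meta$model,
              seed = meta$seed)
  }
}

#' Write a curve or table to CSV at full double precision
#'
#' Numeric columns are serialized with 17 significant digits so that reading
#' the file back reproduces the doubles exactly.
#'
#' @param x data.frame (e.g. an \code{\link{mtf_curve}} or
#'   \code{\link{angular_spectrum}}).
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_curve <- function(x, path) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(v) format(v, digits = 17, trim = TRUE,
                                              scientific = TRUE))
  utils::write.csv(y, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a curve written by \code{\link{write_curve}}
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.csv(path)
}
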