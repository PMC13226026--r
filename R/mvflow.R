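#' Simulate a microvascular flow-signal map
#'
#' A binary vessel field with occupancy `density_true` (the number of vessel
#' pixels is the rounded expected count, so the noiseless above-threshold
#' fraction equals the truth up to pixel quantization); vessel pixels carry
#' the flow `contrast` and every pixel carries additive Gaussian background
#' noise. With `contrast` well above the noise floor and the threshold
#' between the two, the expected above-threshold fraction equals
#' `density_true`.
#'
#' @param density_true true microvascular density fraction in \[0, 1\].
#' @param dim grid dimensions (pixels), default 256 x 256.
#' @param contrast flow-signal magnitude on vessel pixels (a.u.).
#' @param noise_sd background noise SD (a.u.).
#' @param threshold constant color threshold used for quantification (a.u.);
#'   kept fixed across subjects and sessions.
#' @param roi optional logical matrix congruent with the grid; defaults to
#'   the full grid.
#' @return an object of class `vascular_map`: `magnitude` matrix, `roi`
#'   mask, `threshold`.
#' @examples
#' compute_vi(simulate_vascular_map(0.4, dim = c(64, 64), noise_sd = 0))
#' @export
simulate_vascular_map <- function(density_true, dim = c(256, 256),
                                  contrast = 10, noise_sd = 1, threshold = 5,
                                  roi = NULL) {
  assert_number(density_true, "density_true", 0, 1)
  assert_number(contrast, "contrast", lo = 0)
  assert_number(noise_sd, "noise_sd", lo = 0)
  stopifnot(length(dim) == 2L, all(dim >= 1))
  npix <- prod(dim)
  n_vessel <- round(density_true * npix)
  field <- numeric(npix)
  if (n_vessel > 0) field[sample.int(npix, n_vessel)] <- contrast
  if (noise_sd > 0) field <- field + rnorm(npix, sd = noise_sd)
  mag <- matrix(field, nrow = dim[1], ncol = dim[2])
  if (is.null(roi)) roi <- matrix(TRUE, dim[1], dim[2])
  stopifnot(is.logical(roi), all(base::dim(roi) == dim))
  structure(list(magnitude = mag, roi = roi, threshold = threshold),
            class = "vascular_map")
}

#' Vascular index of a flow-signal map
#'
#' Percentage of ROI pixels whose flow-signal magnitude exceeds the constant
#' color threshold; a surrogate of microvascular density. Invariant to any
#' strictly monotone transform of the magnitudes that maps the threshold
#' accordingly.
#'
#' @param map a `vascular_map`, or a list with `magnitude`, `roi`,
#'   `threshold`.
#' @return vascular index in percent, in \[0, 100\].
#' @export
compute_vi <- function(map) {
  mag <- map$magnitude
  roi <- map$roi %||% (is.finite(mag) | TRUE)
  thr <- map$threshold
  stopifnot(is.numeric(mag), is.logical(roi), all(dim(mag) == dim(roi)))
  assert_number(thr, "threshold")
  n_roi <- sum(roi)
  if (n_roi == 0L) {
    stop("invalid measurement: empty ROI", call. = FALSE)
  }
  100 * sum(mag[roi] > thr) / n_roi
}
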