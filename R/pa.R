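#' Molar extinction coefficients of hemoglobin at the two laser wavelengths
#'
#' Standard compiled adult-hemoglobin spectra at the dual-wavelength
#' excitation pair 750/850 nm, in 1/(cm M). 750 nm is deoxy-dominant and
#' 850 nm oxy-dominant, which is what makes the pair suitable for two-point
#' spectral unmixing. Rows are chromophores (HbO2, Hb), columns wavelengths.
#'
#' @param wavelengths wavelengths in nm (labels only; coefficients are for
#'   the default pair).
#' @return a 2x2 matrix with dimnames `chromophore` x `wavelength`.
#' @examples
#' hb_extinction()
#' @export
hb_extinction <- function(wavelengths = c(750, 850)) {
  m <- matrix(c(518.0, 1058.0,      # HbO2 at 750, 850
                1405.24, 691.32),   # Hb   at 750, 850
              nrow = 2, byrow = TRUE,
              dimnames = list(chromophore = c("HbO2", "Hb"),
                              wavelength = as.character(wavelengths)))
  validate_extinction(m)
  m
}

#' @noRd
validate_extinction <- function(eps) {
  if (!is.matrix(eps) || any(dim(eps) != 2L)) {
    stop("configuration error: extinction matrix must be 2x2 (chromophore x wavelength)",
         call. = FALSE)
  }
  if (any(!is.finite(eps)) || any(eps <= 0)) {
    stop("configuration error: extinction coefficients must be positive and finite",
         call. = FALSE)
  }
  if (abs(det(eps)) < 1e-10 * prod(colSums(abs(eps)))) {
    stop("configuration error: extinction matrix is singular; wavelengths carry no spectral contrast",
         call. = FALSE)
  }
  invisible(eps)
}

#' Forward-simulate a dual-wavelength photoacoustic signal pair
#'
#' The ROI-mean photoacoustic amplitude at wavelength `lambda` follows the
#' linear absorption model
#' `p_lambda = Phi_lambda * (eps_HbO2,lambda * C_HbO2 + eps_Hb,lambda * C_Hb) + noise`
#' with `C_HbO2 = sO2 * C_total` and `C_Hb = (1 - sO2) * C_total`. Negative
#' amplitudes after noise are clipped to zero with a warning.
#'
#' @param so2_true true oxygen saturation fraction in \[0, 1\].
#' @param total_hb total hemoglobin concentration (a.u., > 0).
#' @param eps 2x2 extinction matrix from [hb_extinction()].
#' @param fluence per-wavelength optical fluence factors (a.u.).
#' @param noise_sd additive Gaussian noise SD (a.u.).
#' @return an object of class `pa_signal_pair`: wavelength-named amplitudes
#'   plus the simulation settings.
#' @examples
#' p <- simulate_pa_signals(0.5, total_hb = 2)
#' p$amplitude # c(`750` = 1923.24, `850` = 1749.32)
#' @export
simulate_pa_signals <- function(so2_true, total_hb = 1, eps = hb_extinction(),
                                fluence = c(1, 1), noise_sd = 0) {
  assert_number(so2_true, "so2_true", 0, 1)
  assert_number(total_hb, "total_hb", lo = .Machine$double.xmin)
  assert_number(noise_sd, "noise_sd", lo = 0)
  validate_extinction(eps)
  stopifnot(length(fluence) == 2L, all(fluence > 0))
  conc <- c(HbO2 = so2_true, Hb = 1 - so2_true) * total_hb
  p <- as.vector(fluence * crossprod(eps, conc))
  if (noise_sd > 0) p <- p + rnorm(2L, sd = noise_sd)
  p <- clamp(p, lo = 0, what = "PA amplitude")
  structure(list(wavelengths = as.numeric(colnames(eps)),
                 amplitude = setNames(p, colnames(eps)),
                 fluence = fluence, noise_sd = noise_sd),
            class = "pa_signal_pair")
}

#' Estimate oxygen saturation by linear spectral unmixing
#'
#' Solves the 2x2 linear system `p = t(eps) %*% c(C_HbO2, C_Hb)` (equal
#' fluence at both wavelengths assumed, so any common fluence magnitude
#' cancels) and returns `C_HbO2 / (C_HbO2 + C_Hb)`, clipped to \[0, 1\] with
#' a warning when noise pushes a concentration negative. Exact inverse of
#' [simulate_pa_signals()] in the noiseless equal-fluence case.
#'
#' @param pair a `pa_signal_pair`, or a numeric length-2 amplitude vector in
#'   wavelength order.
#' @param eps 2x2 extinction matrix; must match the one used forward.
#' @return estimated sO2 fraction in \[0, 1\].
#' @examples
#' unmix_so2(c(1923.24, 1749.32)) # 0.5
#' @export
unmix_so2 <- function(pair, eps = hb_extinction()) {
  validate_extinction(eps)
  p <- if (inherits(pair, "pa_signal_pair")) pair$amplitude else pair
  stopifnot(is.numeric(p), length(p) == 2L)
  conc <- solve(t(eps), as.numeric(p)) # (C_HbO2, C_Hb)
  if (any(conc < -1e-10 * sum(abs(conc)))) {
    warning("negative unmixed concentration; estimate clipped", call. = FALSE)
  }
  conc <- pmax(conc, 0)
  tot <- sum(conc)
  if (tot <= 0) {
    warning("zero total unmixed hemoglobin; returning NA", call. = FALSE)
    return(NA_real_)
  }
  unname(clamp(conc[1] / tot, 0, 1, what = "sO2", warn = FALSE))
}
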