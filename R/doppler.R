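#' Simulate consecutive cardiac-cycle velocity readings
#'
#' Per-cycle peak-systolic and end-diastolic velocities are the true values
#' plus independent Gaussian reading noise; the waveform order constraint
#' `0 <= EDV <= PSV` is enforced per cycle by clipping with a warning.
#'
#' @param psv_true,edv_true true velocities (mm/s), `0 <= edv_true <= psv_true`.
#' @param n_cycles number of consecutive cycles averaged (3 to 5).
#' @param noise_sd per-reading Gaussian noise SD (mm/s).
#' @return an object of class `doppler_cycles` with per-cycle `psv`, `edv`.
#' @examples
#' compute_ri(simulate_doppler_cycles(60, 21, noise_sd = 0))
#' @export
simulate_doppler_cycles <- function(psv_true, edv_true, n_cycles = 5,
                                    noise_sd = 0) {
  assert_number(psv_true, "psv_true", lo = 0)
  assert_number(edv_true, "edv_true", lo = 0, hi = psv_true)
  assert_number(n_cycles, "n_cycles", lo = 3, hi = 5)
  assert_number(noise_sd, "noise_sd", lo = 0)
  n_cycles <- as.integer(n_cycles)
  psv <- psv_true + rnorm(n_cycles, sd = noise_sd)
  edv <- edv_true + rnorm(n_cycles, sd = noise_sd)
  bad <- edv > psv | edv < 0 | psv < 0
  if (any(bad)) {
    warning(sprintf("%d cycle(s) violated 0 <= EDV <= PSV; clipped", sum(bad)),
            call. = FALSE)
    psv <- pmax(psv, 0)
    edv <- pmin(pmax(edv, 0), psv)
  }
  structure(list(psv = psv, edv = edv, n_cycles = n_cycles),
            class = "doppler_cycles")
}

#' Resistance index from averaged cardiac cycles
#'
#' `RI = (PSV - EDV) / PSV` per cycle, averaged over the recorded cycles.
#' The index is scale-free: rescaling all velocities by a common factor
#' leaves it unchanged. Absent diastolic flow gives 1, a resistance-free
#' waveform gives 0.
#'
#' @param cycles a `doppler_cycles`, or a list with numeric `psv` and `edv`.
#' @return mean resistance index, in \[0, 1\].
#' @examples
#' compute_ri(list(psv = 60, edv = 21)) # 0.65
#' @export
compute_ri <- function(cycles) {
  psv <- cycles$psv
  edv <- cycles$edv
  stopifnot(is.numeric(psv), is.numeric(edv), length(psv) == length(edv))
  if (any(psv <= 0)) {
    stop("invalid measurement: peak systolic velocity must be positive in every cycle",
         call. = FALSE)
  }
  mean((psv - edv) / psv)
}
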