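#' Instrument settings for the measurement stage
#'
#' Collects the per-modality acquisition settings used by
#' [measure_cohort()]: photoacoustic signal model, bolus kinetics, Doppler
#' cycle averaging and flow-map quantification. `noiseless = TRUE` zeroes
#' every instrument noise SD (the session-level biological fluctuation is
#' part of the calibration and is zeroed by [calibration_zero_noise()]).
#'
#' @param noiseless zero all instrument noise?
#' @param pa list: `total_hb`, `fluence`, `noise_sd`.
#' @param tic list: `t0`, `mu`, `sigma`, `baseline`, `duration`, `dt`,
#'   `noise_sd`.
#' @param doppler list: `n_cycles`, `noise_sd`.
#' @param mvflow list: `dim`, `contrast`, `noise_sd`, `threshold`.
#' @return an object of class `pd_protocol`.
#' @export
measurement_protocol <- function(noiseless = FALSE,
                                 pa = list(total_hb = 1, fluence = c(1, 1),
                                           noise_sd = 5),
                                 tic = list(t0 = 5, mu = 3.38, sigma = 0.4,
                                            baseline = 10, duration = 60,
                                            dt = 0.5, noise_sd = 30),
                                 doppler = list(n_cycles = 5, noise_sd = 2),
                                 mvflow = list(dim = c(256, 256), contrast = 10,
                                               noise_sd = 1, threshold = 5)) {
  p <- list(pa = pa, tic = tic, doppler = doppler, mvflow = mvflow,
            noiseless = isTRUE(noiseless))
  if (p$noiseless) {
    p$pa$noise_sd <- 0
    p$tic$noise_sd <- 0
    p$doppler$noise_sd <- 0
    p$mvflow$noise_sd <- 0
  }
  structure(p, class = "pd_protocol")
}

#' Simulate the full measurement of a cohort
#'
#' Runs every dam's every session through the forward models and
#' quantification operators:
#' \itemize{
#'   \item systemic markers: measured value = truth + session residual noise;
#'   \item `so2`: session truth -> dual-wavelength PA pair
#'     ([simulate_pa_signals()]) -> spectral unmixing ([unmix_so2()]),
#'     reported in percent;
#'   \item `wiauc`: session truth -> bolus TIC ([simulate_tic()]) -> kinetic
#'     fit ([fit_tic()]) -> wash-in AUC;
#'   \item `uta_ri`: session truth -> velocity pair -> 3-5 cardiac cycles
#'     ([simulate_doppler_cycles()]) -> averaged RI ([compute_ri()]);
#'   \item `vi`: session truth -> flow map ([simulate_vascular_map()]) ->
#'     fixed-threshold index ([compute_vi()]).
#' }
#' Each imaging session first receives a session-level truth fluctuation
#' with the marker's calibrated `residual_sd` (biology varies between
#' sessions), then the instrument chain adds its own noise and
#' transformation.
#'
#' @param cohort a `pd_cohort`.
#' @param protocol a [measurement_protocol()].
#' @param seed optional integer seed for the measurement noise stream.
#' @return tidy long tibble: `dam_id`, `group`, `gd`, `marker`, `value`,
#'   `quality` (`"ok"` unless a fit was flagged).
#' @export
measure_cohort <- function(cohort, protocol = measurement_protocol(),
                           seed = NULL) {
  stopifnot(inherits(cohort, "pd_cohort"), inherits(protocol, "pd_protocol"))
  set_seed_if(seed)
  cal_set <- cohort$calibration$markers
  truth <- cohort$truth

  out <- vector("list", length(cal_set))
  names(out) <- names(cal_set)
  for (m in names(cal_set)) {
    cal <- cal_set[[m]]
    tr <- truth[truth$marker == m, ]
    nr <- nrow(tr)
    sess <- tr$truth_value
    if (cal$residual_sd > 0) sess <- sess + rnorm(nr, sd = cal$residual_sd)
    sess <- clamp(sess, cal$range[1], cal$range[2], what = m, warn = FALSE)
    quality <- rep("ok", nr)

    value <- switch(
      m,
      so2 = vapply(sess, function(v) {
        pair <- simulate_pa_signals(v / 100, total_hb = protocol$pa$total_hb,
                                    fluence = protocol$pa$fluence,
                                    noise_sd = protocol$pa$noise_sd)
        100 * unmix_so2(pair)
      }, numeric(1)),
      wiauc = {
        v <- numeric(nr)
        for (i in seq_len(nr)) {
          tic <- simulate_tic(sess[i], t0 = protocol$tic$t0, mu = protocol$tic$mu,
                              sigma = protocol$tic$sigma,
                              baseline = protocol$tic$baseline,
                              duration = protocol$tic$duration,
                              dt = protocol$tic$dt,
                              noise_sd = protocol$tic$noise_sd)
          fit <- fit_tic(tic)
          v[i] <- fit$wiauc
          quality[i] <- fit$quality
        }
        v
      },
      uta_ri = {
        psv <- cohort$calibration$doppler$psv %||% 60
        vapply(sess, function(ri) {
          cyc <- simulate_doppler_cycles(psv, psv * (1 - ri),
                                         n_cycles = protocol$doppler$n_cycles,
                                         noise_sd = protocol$doppler$noise_sd)
          compute_ri(cyc)
        }, numeric(1))
      },
      vi = vapply(sess, function(d) {
        map <- simulate_vascular_map(d / 100, dim = protocol$mvflow$dim,
                                     contrast = protocol$mvflow$contrast,
                                     noise_sd = protocol$mvflow$noise_sd,
                                     threshold = protocol$mvflow$threshold)
        compute_vi(map)
      }, numeric(1)),
      # systemic markers: direct reading, residual noise already applied
      sess
    )
    out[[m]] <- tibble::tibble(dam_id = tr$dam_id, group = tr$group,
                               gd = tr$gd, marker = m, value = value,
                               quality = quality)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  tibble::as_tibble(res)
}
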