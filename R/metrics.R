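#' Per-subject longitudinal recovery slope with directional adjustment
#'
#' Ordinary least-squares slope of the marker value on gestational day for a
#' single subject, kept as a deliberately simple linear trend given the
#' small number of sessions. The raw slope is sign-flipped for markers where
#' a decrease indicates improvement, so a positive adjusted slope always
#' means movement toward the healthy phenotype.
#'
#' @param gd gestational days (>= 2 distinct values).
#' @param value marker values, same length; `NA` pairs are dropped.
#' @param orientation `"increase"` (raw slope kept) or `"decrease"`
#'   (slope inverted).
#' @return a list of class `subject_slope`: `beta_raw`, `beta_adj`,
#'   `n_points`, `rss`.
#' @examples
#' subject_slope(c(14, 16, 18), c(0.70, 0.72, 0.74), "decrease")$beta_adj # -0.01
#' @export
subject_slope <- function(gd, value, orientation = c("increase", "decrease")) {
  orientation <- match.arg(orientation)
  keep <- is.finite(gd) & is.finite(value)
  gd <- gd[keep]
  value <- value[keep]
  if (length(unique(gd)) < 2L) {
    stop("undefined slope: need >= 2 distinct gestational days", call. = FALSE)
  }
  gc_ <- gd - mean(gd)
  beta <- sum(gc_ * (value - mean(value))) / sum(gc_^2)
  fitted <- mean(value) + beta * gc_
  structure(
    list(beta_raw = beta,
         beta_adj = if (orientation == "decrease") -beta else beta,
         n_points = length(gd),
         rss = sum((value - fitted)^2)),
    class = "subject_slope"
  )
}

#' Functional Recovery Index
#'
#' `FRI = 100 * (x_i - mean_disease) / (mean_control - mean_disease)`:
#' the extent to which a treated subject's endpoint value was restored from
#' the untreated disease level toward the healthy control level. 100 means
#' complete normalization, 0 no improvement, negative values further
#' deterioration; values are reported unbounded in both directions, never
#' clipped. The index is invariant under affine rescaling of the marker and
#' does not depend on the marker's recovery orientation. A degenerate
#' reference (control and disease means closer than the guard) is an error
#' so that the marker can be excluded explicitly.
#'
#' @param x_i individual value(s) of treated subjects at the endpoint.
#' @param mean_control,mean_disease reference group means at the endpoint.
#' @param guard relative guard threshold on the reference separation.
#' @return FRI in percent, same length as `x_i`.
#' @examples
#' fri(80, 80, 50)    # 100
#' fri(50, 80, 50)    # 0
#' fri(77.81, 80, 50) # 92.7
#' @export
fri <- function(x_i, mean_control, mean_disease, guard = 1e-9) {
  assert_number(mean_control, "mean_control")
  assert_number(mean_disease, "mean_disease")
  if (abs(mean_control - mean_disease) <= guard * abs(mean_control)) {
    stop("degenerate reference: control and disease means are indistinguishable",
         call. = FALSE)
  }
  100 * (x_i - mean_disease) / (mean_control - mean_disease)
}

#' Endpoint recovery-index summary for the treated arm
#'
#' Computes the reference means from the measured control- and disease-arm
#' values at the study endpoint, the per-treated-subject [fri()], and the
#' summary mean with its standard error (SD / sqrt(n)).
#'
#' @param value endpoint measured values for all dams.
#' @param group arm labels, same length; must contain `"control"`,
#'   `"disease"` and `"treated"` entries (or the labels given in `arms`).
#' @param arms length-3 character: control, disease and treated labels.
#' @param guard forwarded to [fri()].
#' @return a list of class `fri_summary`: `fri` (per-treated-subject
#'   tibble), `mean`, `sem`, `mean_control`, `mean_disease`, `n`.
#' @export
group_fri_summary <- function(value, group,
                              arms = c("control", "disease", "treated"),
                              guard = 1e-9) {
  stopifnot(length(value) == length(group), length(arms) == 3L)
  keep <- is.finite(value)
  value <- value[keep]
  group <- group[keep]
  counts <- table(factor(group, levels = arms))
  if (any(counts == 0L)) {
    stop(sprintf("empty arm(s): %s",
                 paste(names(counts)[counts == 0L], collapse = ", ")),
         call. = FALSE)
  }
  m_c <- mean(value[group == arms[1]])
  m_pe <- mean(value[group == arms[2]])
  x_t <- value[group == arms[3]]
  f <- fri(x_t, m_c, m_pe, guard = guard)
  structure(
    list(fri = tibble::tibble(value = x_t, fri = f),
         mean = mean(f),
         sem = if (length(f) > 1L) sd(f) / sqrt(length(f)) else 0,
         mean_control = m_c, mean_disease = m_pe, n = length(f)),
    class = "fri_summary"
  )
}

#' Per-subject pharmacodynamic metrics for a measured cohort
#'
#' For every dam and analyzed marker, the per-subject OLS slope over the
#' marker's observation grid (directionally adjusted per the marker's
#' calibrated orientation) and, for treated dams, the endpoint recovery
#' index computed against the measured control/disease group means at the
#' final imaging day.
#'
#' @param measured long tibble from [measure_cohort()].
#' @param calibration the `pd_calibration` used to generate the cohort
#'   (provides orientations and the marker list).
#' @return tibble: `dam_id`, `group`, `marker`, `n_points`, `beta_raw`,
#'   `beta_adj`, `fri` (NA outside the treated arm).
#' @export
compute_pd_metrics <- function(measured, calibration) {
  stopifnot(inherits(calibration, "pd_calibration"))
  check_schema(measured, c("dam_id", "group", "gd", "marker", "value"),
               "measured long table")
  markers <- names(calibration$markers)
  rows <- list()
  for (m in markers) {
    cal <- calibration$markers[[m]]
    sub <- measured[measured$marker == m, ]
    gd_fin <- max(sub$gd)
    fin <- sub[sub$gd == gd_fin, ]
    fsum <- group_fri_summary(fin$value, fin$group)
    fri_by_dam <- setNames(fri(fin$value, fsum$mean_control, fsum$mean_disease),
                           fin$dam_id)

    dams <- unique(sub$dam_id)
    sl <- lapply(dams, function(d) {
      dd <- sub[sub$dam_id == d, ]
      s <- subject_slope(dd$gd, dd$value, cal$orientation)
      tibble::tibble(dam_id = d, group = dd$group[1], marker = m,
                     n_points = s$n_points, beta_raw = s$beta_raw,
                     beta_adj = s$beta_adj,
                     fri = if (dd$group[1] == "treated")
                       unname(fri_by_dam[d]) else NA_real_)
    })
    rows[[m]] <- do.call(rbind, sl)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  tibble::as_tibble(out)
}
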