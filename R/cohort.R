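#' Generate a seeded three-arm cohort of dams with longitudinal ground truth
#'
#' Each dam's true trajectory for a marker is the deterministic group line
#' ([group_trajectory()]) plus a subject-specific random intercept whose SD
#' comes from the marker calibration. A latent per-dam "functional rescue"
#' factor (standard normal) is shared, with marker-specific loadings, by the
#' subject intercepts of the functional markers and by fetal weight, so that
#' functional recovery and fetal outcome are coupled while resistance recovery
#' is not. Doppler velocity truths are derived from the resistance-index
#' truth as `EDV = PSV * (1 - RI)` with the calibrated PSV. Endpoints
#' (weights, histology percentages) are drawn by [sample_endpoints()].
#' Structural invariants (fractions, ranges, EDV <= PSV) are enforced by
#' clipping with a warning.
#'
#' @param design a [study_design()].
#' @param calibration a [default_calibration()]-shaped `pd_calibration`.
#' @param seed integer seed; identical `(design, calibration, seed)` give a
#'   bit-identical cohort.
#' @return an object of class `pd_cohort` with components `design`,
#'   `calibration`, `truth` (tidy long tibble: `dam_id`, `group`, `gd`,
#'   `marker`, `truth_value`), `endpoints` (one row per dam) and `provenance`.
#' @examples
#' coh <- generate_cohort(study_design(), default_calibration(), seed = 1)
#' nrow(coh$endpoints) # 24 dams
#' @export
generate_cohort <- function(design = study_design(),
                            calibration = default_calibration(),
                            seed = NULL) {
  stopifnot(inherits(design, "pd_design"), inherits(calibration, "pd_calibration"))
  set_seed_if(seed)

  n <- design$n_per_group
  groups <- rep(design$groups, each = n)
  n_dam <- length(groups)
  dam_id <- sprintf("dam%02d", seq_len(n_dam))

  z <- rnorm(n_dam) # latent functional-rescue factor (z-score)

  truth <- list()
  for (m in names(calibration$markers)) {
    cal <- calibration$markers[[m]]
    gd <- if (cal$grid == "systemic") design$systemic_gd else design$imaging_gd
    rc <- unname(calibration$coupling$rescue_cor[m])
    if (is.na(rc) || is.null(rc)) rc <- 0
    eps <- rnorm(n_dam)
    b_i <- cal$intercept_sd * (rc * z + sqrt(1 - rc^2) * eps)
    mu <- vapply(groups, function(g) cal$anchor[[g]], numeric(1)) -
      vapply(groups, function(g) cal$slope[[g]], numeric(1)) %o% (cal$anchor_gd - gd)
    vals <- mu + b_i # recycles b_i down columns (dams x gds)
    vals <- clamp(vals, cal$range[1], cal$range[2], what = m)
    truth[[m]] <- tibble::tibble(
      dam_id = rep(dam_id, times = length(gd)),
      group = rep(groups, times = length(gd)),
      gd = rep(gd, each = n_dam),
      marker = m,
      truth_value = as.vector(vals))
  }
  truth <- do.call(rbind, truth)

  # Doppler velocity truths derived from the resistance-index truth
  if ("uta_ri" %in% names(calibration$markers)) {
    ri <- truth[truth$marker == "uta_ri", ]
    psv <- calibration$doppler$psv %||% 60
    edv <- clamp(psv * (1 - ri$truth_value), 0, psv, what = "edv")
    truth <- rbind(truth,
                   transform(ri, marker = "psv", truth_value = psv),
                   transform(ri, marker = "edv", truth_value = edv))
  }
  truth <- truth[order(truth$marker, truth$gd, truth$dam_id), ]
  rownames(truth) <- NULL

  final_truth <- final_gd_truth(truth, design, calibration)
  final_truth$z <- z[match(final_truth$dam_id, dam_id)]
  endpoints <- sample_endpoints(final_truth, calibration)

  structure(
    list(design = design, calibration = calibration,
         truth = tibble::as_tibble(truth), endpoints = endpoints,
         provenance = list(seed = seed,
                           calibration_hash = rlang::hash(calibration))),
    class = "pd_cohort"
  )
}

#' @noRd
final_gd_truth <- function(truth, design, calibration) {
  gd_fin <- max(design$imaging_gd)
  fin <- truth[truth$gd == gd_fin & truth$marker %in% names(calibration$markers), ]
  wide <- tibble::as_tibble(
    stats::reshape(as.data.frame(fin[, c("dam_id", "group", "marker", "truth_value")]),
                   idvar = c("dam_id", "group"), timevar = "marker",
                   direction = "wide"))
  names(wide) <- sub("^truth_value\\.", "", names(wide))
  wide
}

#' Draw endpoint outcomes for each dam from the final-session truths
#'
#' Fetal weight is the arm's base value plus a loading on the latent rescue
#' factor plus Gaussian noise; the histology percentages are linear in the
#' final-session imaging truths plus noise (hypoxia marker decreasing in
#' oxygen saturation, endothelial marker increasing in microvascular
#' density). All outcomes are clipped to their declared ranges with a
#' warning. The draw uses the current RNG stream.
#'
#' @param final_truth tibble with one row per dam: `dam_id`, `group`, the
#'   final-session truth columns named by marker, and the latent factor `z`.
#' @param calibration a `pd_calibration` providing `$endpoints`.
#' @return tibble with one row per dam: weights, ratio and histology columns.
#' @export
sample_endpoints <- function(final_truth, calibration) {
  ep <- calibration$endpoints
  n <- nrow(final_truth)
  out <- tibble::tibble(dam_id = final_truth$dam_id, group = final_truth$group,
                        rescue_z = final_truth$z %||% rep(NA_real_, n))

  draw_weight <- function(spec) {
    base <- unname(spec$anchor[final_truth$group])
    sdv <- unname(spec$sd[final_truth$group])
    rc <- spec$rescue_cor %||% 0
    z <- if (rc != 0) final_truth$z else 0
    w <- base + sdv * (rc * z + sqrt(1 - rc^2) * rnorm(n))
    clamp(w, spec$range[1], spec$range[2], what = "endpoint weight")
  }
  if (!is.null(ep$fetal_weight)) out$fetal_weight <- draw_weight(ep$fetal_weight)
  if (!is.null(ep$placental_weight)) {
    out$placental_weight <- draw_weight(ep$placental_weight)
    if (!is.null(out$fetal_weight)) {
      out$fp_ratio <- out$fetal_weight / out$placental_weight
    }
  }
  draw_hist <- function(spec) {
    src <- final_truth[[spec$source]]
    if (is.null(src)) {
      stop(sprintf("configuration error: endpoint source marker '%s' absent",
                   spec$source), call. = FALSE)
    }
    v <- spec$intercept + spec$coef * src + spec$sd * rnorm(n)
    clamp(v, spec$range[1], spec$range[2], what = "histology percentage")
  }
  if (!is.null(ep$hif1a)) out$hif1a_pct <- draw_hist(ep$hif1a)
  if (!is.null(ep$cd31)) out$cd31_pct <- draw_hist(ep$cd31)
  out
}

#' @export
print.pd_cohort <- function(x, ...) {
  cat("<pd_cohort> ", nrow(x$endpoints), " dams, ",
      length(unique(x$truth$marker)), " truth markers, seed ",
      x$provenance$seed %||% NA, "\n", sep = "")
  invisible(x)
}

#' Write / read the tidy cohort tables as CSV
#'
#' The long truth table (`dam_id`, `group`, `gd`, `marker`, `truth_value`)
#' and the endpoints table round-trip exactly; headers are validated on read
#' so a malformed file fails with a schema error.
#'
#' @param cohort a `pd_cohort` (or any tibble with the long-table schema for
#'   `write_cohort_csv`).
#' @param path file path.
#' @return `read_cohort_csv()` returns a tibble; writers return `path`
#'   invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  tab <- if (inherits(cohort, "pd_cohort")) cohort$truth else cohort
  check_schema(tab, c("dam_id", "group", "gd", "marker"), "cohort long table")
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, colClasses = NA)
  check_schema(tab, c("dam_id", "group", "gd", "marker"), "cohort long table")
  value_col <- intersect(c("truth_value", "value"), names(tab))
  for (cc in c("gd", value_col)) {
    if (!is.numeric(tab[[cc]])) {
      stop(sprintf("schema error: column '%s' is not numeric", cc), call. = FALSE)
    }
  }
  tibble::as_tibble(tab)
}

#' @noRd
check_schema <- function(tab, required, what) {
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop(sprintf("schema error: %s is missing column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(tab)
}
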