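#' Define the three-arm longitudinal study design
#'
#' A design holds the arm labels, the number of dams per arm, and the two
#' observation grids: systemic markers (blood pressure, proteinuria) are
#' sampled on `systemic_gd` and the imaging session markers on `imaging_gd`.
#' One representative placenta is monitored per dam, so the dam is the
#' experimental unit throughout.
#'
#' @param n_per_group number of dams per arm (>= 2; default 8).
#' @param groups arm labels; the first is the healthy reference arm, the
#'   second the untreated disease arm, the third the treated arm.
#' @param systemic_gd strictly increasing gestational days for systemic
#'   markers (default GD 7, 10, 13, 18).
#' @param imaging_gd strictly increasing gestational days for imaging
#'   sessions (default GD 14, 16, 18); must lie within the systemic span.
#' @return an object of class `pd_design`.
#' @examples
#' study_design()
#' @export
study_design <- function(n_per_group = 8,
                         groups = c("control", "disease", "treated"),
                         systemic_gd = c(7, 10, 13, 18),
                         imaging_gd = c(14, 16, 18)) {
  assert_number(n_per_group, "n_per_group", lo = 2)
  if (length(groups) != 3L || anyDuplicated(groups) > 0L) {
    stop("configuration error: `groups` must be three distinct arm labels", call. = FALSE)
  }
  for (g in list(systemic_gd = systemic_gd, imaging_gd = imaging_gd)) {
    if (length(g) < 2L || any(diff(g) <= 0)) {
      stop("configuration error: gestational-day grids must be strictly increasing with >= 2 points",
           call. = FALSE)
    }
  }
  if (min(imaging_gd) < min(systemic_gd) || max(imaging_gd) > max(systemic_gd)) {
    stop("configuration error: imaging grid must lie within the systemic gestational span",
         call. = FALSE)
  }
  structure(
    list(n_per_group = as.integer(n_per_group),
         groups = as.character(groups),
         systemic_gd = as.numeric(systemic_gd),
         imaging_gd = as.numeric(imaging_gd)),
    class = "pd_design"
  )
}

#' @export
print.pd_design <- function(x, ...) {
  cat("<pd_design> ", 3L * x$n_per_group, " dams (", x$n_per_group, "/arm: ",
      paste(x$groups, collapse = ", "), ")\n", sep = "")
  cat("  systemic GDs: ", paste(x$systemic_gd, collapse = ", "), "\n", sep = "")
  cat("  imaging GDs:  ", paste(x$imaging_gd, collapse = ", "), "\n", sep = "")
  invisible(x)
}
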