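#' Classify a marker's therapeutic response pattern
#'
#' Rule set applied to the directionally-adjusted disease and treated arm
#' slopes and the slope-comparison p-value (labels drawn from a fixed
#' vocabulary):
#' \itemize{
#'   \item `p >= alpha` -> `"no slope alteration"`;
#'   \item adjusted slopes of opposite sign (disease deteriorating, treated
#'     improving) -> `"trajectory inversion"`;
#'   \item both improving, treated faster -> `"enhanced increase"`;
#'   \item both deteriorating, treated more slowly -> for markers that rise
#'     with disease (`orientation = "decrease"`) `"attenuated progression"`,
#'     for falling markers `"partial mitigation"`;
#'   \item remaining significant configurations -> `"partial mitigation"`.
#' }
#'
#' @param slope_disease_adj,slope_treated_adj directionally-adjusted arm
#'   slopes (positive = moving toward the healthy phenotype).
#' @param p_slope slope-comparison p-value.
#' @param orientation the marker's recovery orientation.
#' @param alpha significance threshold (default 0.05).
#' @return one of `"no slope alteration"`, `"trajectory inversion"`,
#'   `"enhanced increase"`, `"attenuated progression"`,
#'   `"partial mitigation"`.
#' @examples
#' classify_response(-0.70, 1.95, 1e-4, "increase") # trajectory inversion
#' @export
classify_response <- function(slope_disease_adj, slope_treated_adj, p_slope,
                              orientation = c("increase", "decrease"),
                              alpha = 0.05) {
  orientation <- match.arg(orientation)
  if (!is.finite(p_slope) || p_slope >= alpha) return("no slope alteration")
  d <- slope_disease_adj
  t <- slope_treated_adj
  if (d < 0 && t > 0) return("trajectory inversion")
  if (d > 0 && t < 0) return("trajectory inversion")
  if (d >= 0 && t >= 0) {
    return(if (t > d) "enhanced increase" else "partial mitigation")
  }
  # both still deteriorating
  if (abs(t) < abs(d)) {
    return(if (orientation == "decrease") "attenuated progression"
           else "partial mitigation")
  }
  "partial mitigation"
}

#' @noRd
response_pattern_vocabulary <- function() {
  c("no slope alteration", "trajectory inversion", "enhanced increase",
    "attenuated progression", "partial mitigation")
}

#' Run the full simulate-measure-metrics-inference study
#'
#' Executes all stages in order for one or more replicate cohorts:
#' [generate_cohort()] -> [measure_cohort()] -> [compute_pd_metrics()] ->
#' inference ([ancova_slopes()] per marker, [rm_anova()] Bonferroni
#' contrasts per session, [oneway_anova_tukey()] across imaging-marker
#' recovery indices, endpoint correlations) -> a per-marker study summary
#' with response-pattern labels. Replicate `i` uses seed `seed + i - 1` for
#' the cohort and `seed + i - 1 + 5e5` for the measurement noise stream, so
#' the whole run is deterministic given `(calibration, design, protocol,
#' seed)`.
#'
#' @param calibration a `pd_calibration`.
#' @param design a `pd_design`.
#' @param protocol a `pd_protocol`.
#' @param seed base integer seed.
#' @param replicates number of replicate cohorts (>= 1).
#' @param alpha significance threshold for contrasts and labels.
#' @return an object of class `pd_study`:
#'   \describe{
#'     \item{summary}{per-marker tibble averaged over replicates (slopes
#'       with their within-cohort SEMs, slope-comparison p, recovery index
#'       with SEM, modal response label; Monte-Carlo SEs when
#'       `replicates > 1`).}
#'     \item{replicate_summaries}{stacked per-replicate summaries.}
#'     \item{contrast_freq}{frequency of Bonferroni-significant pairwise
#'       contrasts per marker, session day and group pair.}
#'     \item{fri_anova, correlations}{inference on the first replicate's
#'       recovery indices and endpoint associations.}
#'   }
#' @export
run_study <- function(calibration = default_calibration(),
                      design = study_design(),
                      protocol = measurement_protocol(),
                      seed = 1, replicates = 1, alpha = 0.05) {
  stopifnot(replicates >= 1)
  reps <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    s <- as.integer(seed + i - 1L)
    cohort <- generate_cohort(design, calibration, seed = s)
    measured <- measure_cohort(cohort, protocol, seed = s + 500000L)
    metrics <- compute_pd_metrics(measured, calibration)
    reps[[i]] <- replicate_analysis(cohort, measured, metrics, calibration,
                                    alpha, replicate = i)
  }

  rep_sum <- do.call(rbind, lapply(reps, `[[`, "summary"))
  rep_con <- do.call(rbind, lapply(reps, `[[`, "contrasts"))

  summary <- aggregate_summaries(rep_sum, replicates)
  contrast_freq <- aggregate_contrasts(rep_con, alpha)

  structure(
    list(summary = summary,
         replicate_summaries = rep_sum,
         contrast_freq = contrast_freq,
         fri_anova = reps[[1]]$fri_anova,
         correlations = reps[[1]]$correlations,
         settings = list(seed = seed, replicates = replicates, alpha = alpha,
                         design = design,
                         calibration_hash = rlang::hash(calibration))),
    class = "pd_study"
  )
}

#' @noRd
replicate_analysis <- function(cohort, measured, metrics, calibration, alpha,
                               replicate) {
  markers <- names(calibration$markers)
  rows <- list()
  cons <- list()
  for (m in markers) {
    cal <- calibration$markers[[m]]
    mm <- metrics[metrics$marker == m, ]
    dis <- mm[mm$group == "disease", ]
    tre <- mm[mm$group == "treated", ]
    sem <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else 0

    long <- measured[measured$marker == m & is.finite(measured$value), ]
    anc <- ancova_slopes(long, groups = c("disease", "treated"),
                         subject = "dam_id", group = "group",
                         gd = "gd", value = "value")
    fsum <- {
      gd_fin <- max(long$gd)
      fin <- long[long$gd == gd_fin, ]
      group_fri_summary(fin$value, fin$group)
    }
    rma <- tryCatch(
      rm_anova(as.data.frame(long), subject = "dam_id", group = "group",
               time = "gd", value = "value"),
      error = function(e) NULL) # e.g. a flagged fit left a session missing
    if (!is.null(rma)) {
      con <- rma$contrasts
      con$marker <- m
      con$replicate <- replicate
      cons[[m]] <- con
    }

    adj_sign <- if (cal$orientation == "decrease") -1 else 1
    rows[[m]] <- tibble::tibble(
      replicate = replicate, marker = m, unit = cal$unit,
      slope_disease = mean(dis$beta_raw), slope_disease_sem = sem(dis$beta_raw),
      slope_treated = mean(tre$beta_raw), slope_treated_sem = sem(tre$beta_raw),
      slope_treated_adj = mean(tre$beta_adj),
      slope_disease_adj = mean(dis$beta_adj),
      p_slope = anc$p, p_slope_subject_t = anc$slope_t$p,
      fri_mean = fsum$mean, fri_sem = fsum$sem,
      pattern = classify_response(adj_sign * mean(dis$beta_raw),
                                  adj_sign * mean(tre$beta_raw),
                                  anc$p, cal$orientation, alpha))
  }
  summary <- do.call(rbind, rows)

  imaging <- markers[vapply(calibration$markers, function(c.) c.$grid, "") == "imaging"]
  fri_lists <- lapply(imaging, function(m) {
    v <- metrics$fri[metrics$marker == m & metrics$group == "treated"]
    v[is.finite(v)]
  })
  names(fri_lists) <- imaging
  fri_anova <- tryCatch(oneway_anova_tukey(fri_lists), error = function(e) NULL)

  correlations <- endpoint_correlations(cohort, measured, metrics)

  list(summary = summary, contrasts = do.call(rbind, cons),
       fri_anova = fri_anova, correlations = correlations)
}

#' @noRd
endpoint_correlations <- function(cohort, measured, metrics) {
  ep <- cohort$endpoints
  out <- list()
  # fetal-outcome association: treated-arm FRIs vs fetal weight
  tre <- ep[ep$group == "treated", ]
  for (m in intersect(c("so2", "wiauc", "vi", "uta_ri"),
                      unique(metrics$marker))) {
    f <- metrics[metrics$marker == m & metrics$group == "treated", ]
    v <- f$fri[match(tre$dam_id, f$dam_id)]
    res <- tryCatch(lin_regress(v, tre$fetal_weight), error = function(e) NULL)
    if (!is.null(res)) {
      out[[paste0("fri_", m, "_vs_fetal_weight")]] <-
        tibble::tibble(association = paste0("FRI ", m, " vs fetal weight"),
                       r = res$r, slope = res$slope, n = res$df + 2, p = res$p)
    }
  }
  # in vivo vs ex vivo, pooled across all arms at the endpoint
  fin_gd <- max(measured$gd[measured$marker == "so2"])
  pool_cor <- function(marker, col, label) {
    mv <- measured[measured$marker == marker & measured$gd == fin_gd, ]
    v <- mv$value[match(ep$dam_id, mv$dam_id)]
    res <- tryCatch(pearson_cor(v, ep[[col]]), error = function(e) NULL)
    if (is.null(res)) return(NULL)
    tibble::tibble(association = label, r = res$r, slope = NA_real_,
                   n = res$n, p = res$p)
  }
  if ("hif1a_pct" %in% names(ep)) {
    out$so2_vs_hif <- pool_cor("so2", "hif1a_pct", "sO2 vs HIF-1a % area")
  }
  if ("cd31_pct" %in% names(ep)) {
    out$vi_vs_cd31 <- pool_cor("vi", "cd31_pct", "VI vs CD31 % area")
  }
  do.call(rbind, out)
}

#' @noRd
aggregate_summaries <- function(rep_sum, replicates) {
  markers <- unique(rep_sum$marker)
  num_cols <- c("slope_disease", "slope_disease_sem", "slope_treated",
                "slope_treated_sem", "slope_treated_adj", "slope_disease_adj",
                "p_slope", "p_slope_subject_t", "fri_mean", "fri_sem")
  rows <- lapply(markers, function(m) {
    sub <- rep_sum[rep_sum$marker == m, ]
    agg <- lapply(num_cols, function(cc) mean(sub[[cc]], na.rm = TRUE))
    names(agg) <- num_cols
    mcse <- if (replicates > 1L)
      sd(sub$fri_mean, na.rm = TRUE) / sqrt(replicates) else NA_real_
    pat <- names(sort(table(sub$pattern), decreasing = TRUE))[1]
    tibble::tibble(marker = m, unit = sub$unit[1], !!!agg,
                   fri_mc_se = mcse, pattern = pat,
                   pattern_freq = mean(sub$pattern == pat))
  })
  do.call(rbind, rows)
}

#' @noRd
aggregate_contrasts <- function(rep_con, alpha) {
  key <- interaction(rep_con$marker, rep_con$time, rep_con$pair, drop = TRUE)
  rows <- lapply(split(rep_con, key), function(sub) {
    tibble::tibble(marker = sub$marker[1], gd = as.numeric(as.character(sub$time[1])),
                   pair = sub$pair[1],
                   freq_significant = mean(sub$p_bonf < alpha),
                   mean_estimate = mean(sub$estimate))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$marker, out$gd, out$pair), ]
  rownames(out) <- NULL
  out
}

#' @export
print.pd_study <- function(x, digits = 3, ...) {
  cat("<pd_study> ", x$settings$replicates, " replicate(s), seed ",
      x$settings$seed, "\n\n", sep = "")
  s <- x$summary
  cat(sprintf("%-8s %22s %22s %10s %16s  %s\n", "marker", "slope disease",
              "slope treated", "p(slope)", "FRI@endpoint", "pattern"))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("%-8s %12.4g ± %-7.3g %12.4g ± %-7.3g %10.3g %9.4g ± %-5.3g  %s\n",
                s$marker[i], s$slope_disease[i], s$slope_disease_sem[i],
                s$slope_treated[i], s$slope_treated_sem[i], s$p_slope[i],
                s$fri_mean[i], s$fri_sem[i], s$pattern[i]))
  }
  invisible(x)
}

#' Write / read the per-marker study summary as CSV
#'
#' @param study a `pd_study` (or its `summary` tibble).
#' @param path file path.
#' @return `read_summary_csv()` returns a tibble; the writer returns `path`
#'   invisibly.
#' @export
write_summary_csv <- function(study, path) {
  tab <- if (inherits(study, "pd_study")) study$summary else study
  check_schema(tab, c("marker", "slope_disease", "slope_treated",
                      "p_slope", "fri_mean", "pattern"), "study summary")
  write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_summary_csv
#' @export
read_summary_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  check_schema(tab, c("marker", "slope_disease", "slope_treated",
                      "p_slope", "fri_mean", "pattern"), "study summary")
  tibble::as_tibble(tab)
}
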