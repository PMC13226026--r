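#' Mixed (split-plot) repeated-measures ANOVA with Bonferroni contrasts
#'
#' Classical sums-of-squares decomposition for a balanced mixed design with
#' one between-subject factor (treatment group) and one within-subject
#' factor (session time), subjects nested in groups:
#' between-subject stratum `group` tested against `subject-within-group`,
#' within-subject strata `time` and `group:time` tested against the
#' within-subject residual. The Greenhouse-Geisser epsilon (Box's formula on
#' the pooled within-group covariance of the repeated measures) corrects the
#' within-subject degrees of freedom for sphericity violations and is
#' applied by default. Post hoc pairwise group contrasts are pooled-variance
#' two-sample t-tests at each time with the p-value multiplied by the number
#' of pairwise comparisons at that time (capped at 1).
#'
#' Missing cells are a hard error (no imputation): the classical
#' decomposition requires every subject at every time.
#'
#' @param data data frame with columns `subject`, `group`, `time`, `value`
#'   (names configurable).
#' @param subject,group,time,value column names.
#' @param gg apply the Greenhouse-Geisser correction to within-subject
#'   p-values?
#' @return a list of class `rm_anova`: `effects` (tibble: effect, ss, df,
#'   ms, f, p, and GG-corrected `p_gg` for within effects), `gg_epsilon`,
#'   `contrasts` (tibble: time, pair, estimate, t, df, p, p_bonf).
#' @export
rm_anova <- function(data, subject = "subject", group = "group",
                     time = "time", value = "value", gg = TRUE) {
  check_schema(data, c(subject, group, time, value), "repeated-measures table")
  s <- factor(data[[subject]])
  g <- factor(data[[group]])
  tt <- factor(data[[time]])
  y <- data[[value]]
  if (any(!is.finite(y))) stop("unbalanced design: missing values present", call. = FALSE)

  tab <- table(s, tt)
  if (any(tab != 1L)) {
    stop("unbalanced design: every subject must be observed exactly once at every time",
         call. = FALSE)
  }
  gmap <- tapply(as.character(g), s, function(x) unique(x))
  if (any(lengths(gmap) != 1L)) {
    stop("unbalanced design: each subject must belong to exactly one group", call. = FALSE)
  }
  n_per <- table(factor(unlist(gmap), levels = levels(g)))
  if (length(unique(n_per)) != 1L) {
    stop("unbalanced design: groups must have equal subject counts", call. = FALSE)
  }

  a <- nlevels(g)
  b <- nlevels(tt)
  n <- unique(as.integer(n_per))
  N <- a * b * n
  grand <- mean(y)

  m_s <- tapply(y, s, mean)
  m_g <- tapply(y, g, mean)
  m_t <- tapply(y, tt, mean)
  m_gt <- tapply(y, list(g, tt), mean)

  ss_total <- sum((y - grand)^2)
  ss_group <- n * b * sum((m_g - grand)^2)
  ss_subj <- b * sum((m_s - grand)^2) - ss_group
  ss_time <- n * a * sum((m_t - grand)^2)
  ss_gt <- n * sum((m_gt - outer(m_g, m_t, `+`) + grand)^2)
  ss_err <- ss_total - ss_group - ss_subj - ss_time - ss_gt

  df <- c(group = a - 1, subject = a * (n - 1), time = b - 1,
          `group:time` = (a - 1) * (b - 1), residual = a * (n - 1) * (b - 1))
  ss <- c(ss_group, ss_subj, ss_time, ss_gt, ss_err)
  ms <- ss / df

  f_of <- function(ss_eff, ms_eff, ms_err) {
    if (ss_eff <= 1e-12 * max(ss_total, 1)) return(c(0, 1))
    if (ms_err <= 1e-300) return(c(Inf, 0))
    c(ms_eff / ms_err, NA)
  }
  p_from_f <- function(fv, df1, df2) {
    if (is.infinite(fv)) 0 else pf(fv, df1, df2, lower.tail = FALSE)
  }
  fg <- f_of(ss_group, ms[1], ms[2])
  ft <- f_of(ss_time, ms[3], ms[5])
  fi <- f_of(ss_gt, ms[4], ms[5])
  fstat <- c(fg[1], NA, ft[1], fi[1], NA)
  p <- c(if (is.na(fg[2])) p_from_f(fg[1], df[1], df[2]) else fg[2], NA,
         if (is.na(ft[2])) p_from_f(ft[1], df[3], df[5]) else ft[2],
         if (is.na(fi[2])) p_from_f(fi[1], df[4], df[5]) else fi[2], NA)

  eps <- gg_epsilon(y, s, g, tt)
  p_gg <- rep(NA_real_, 5)
  if (gg) {
    p_gg[3] <- if (!is.na(p[3]) && p[3] %in% c(0, 1) && fstat[3] %in% c(0, Inf)) p[3] else
      p_from_f(fstat[3], eps * df[3], eps * df[5])
    p_gg[4] <- if (!is.na(p[4]) && p[4] %in% c(0, 1) && fstat[4] %in% c(0, Inf)) p[4] else
      p_from_f(fstat[4], eps * df[4], eps * df[5])
  }

  effects <- tibble::tibble(
    effect = c(group, paste0(subject, "(", group, ")"), time,
               paste0(group, ":", time), "residual"),
    ss = unname(ss), df = unname(df), ms = unname(ms), f = unname(fstat),
    p = unname(p), p_gg = p_gg)

  contrasts <- bonferroni_contrasts(y, g, tt)
  structure(list(effects = effects, gg_epsilon = eps, contrasts = contrasts,
                 design = c(groups = a, times = b, n_per_group = n)),
            class = "rm_anova")
}

#' Greenhouse-Geisser sphericity epsilon (Box's formula)
#' @noRd
gg_epsilon <- function(y, s, g, tt) {
  b <- nlevels(tt)
  if (b <= 2L) return(1)
  # pooled within-group covariance of the subjects x times matrix
  wide <- tapply(y, list(s, tt), mean)
  grp <- tapply(as.character(g), s, unique)[rownames(wide)]
  centered <- wide
  for (gl in unique(grp)) {
    idx <- grp == gl
    centered[idx, ] <- sweep(wide[idx, , drop = FALSE], 2,
                             colMeans(wide[idx, , drop = FALSE]))
  }
  S <- crossprod(centered) / (nrow(wide) - length(unique(grp)))
  sbar <- mean(S)
  sdiag <- mean(diag(S))
  row_m <- rowMeans(S)
  num <- (b * (sdiag - sbar))^2
  den <- (b - 1) * (sum(S^2) - 2 * b * sum(row_m^2) + b^2 * sbar^2)
  if (den <= 0) return(1)
  min(max(num / den, 1 / (b - 1)), 1)
}

#' @noRd
bonferroni_contrasts <- function(y, g, tt) {
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  m <- length(pairs)
  rows <- list()
  for (tl in levels(tt)) {
    for (pr in pairs) {
      y1 <- y[g == pr[1] & tt == tl]
      y2 <- y[g == pr[2] & tt == tl]
      n1 <- length(y1)
      n2 <- length(y2)
      sp2 <- ((n1 - 1) * var(y1) + (n2 - 1) * var(y2)) / (n1 + n2 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      est <- mean(y2) - mean(y1)
      tv <- if (se > 0) est / se else if (abs(est) < 1e-12) 0 else Inf * sign(est)
      dfree <- n1 + n2 - 2
      pv <- if (is.infinite(tv)) 0 else 2 * pt(-abs(tv), dfree)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        time = tl, pair = paste(pr, collapse = " vs "), estimate = est,
        t = tv, df = dfree, p = pv, p_bonf = min(1, pv * m))
    }
  }
  do.call(rbind, rows)
}

#' Homogeneity-of-slopes ANCOVA on longitudinal trajectories
#'
#' Compares group regression coefficients by fitting the pooled linear model
#' `value ~ gd + group + gd:group` and F-testing the interaction (the
#' standard operationalization of "differences in regression coefficients").
#' A two-sample pooled t-test on the per-subject OLS slopes is reported as a
#' sensitivity analysis; on random-intercept longitudinal data the pooled
#' ANCOVA is conservative (the residual absorbs between-subject intercept
#' variance) while the subject-slope test is not.
#'
#' @param data long data frame with subject, group, gd and value columns.
#' @param groups length-2 character: the two arms to compare.
#' @param subject,group,gd,value column names.
#' @return a list of class `slope_comparison`: `slopes` (tibble: group,
#'   slope, se from the pooled fit), `f`, `df`, `p` for the interaction, and
#'   `slope_t` (list: estimate, t, df, p) for the subject-slope test.
#' @export
ancova_slopes <- function(data, groups, subject = "subject", group = "group",
                          gd = "gd", value = "value") {
  check_schema(data, c(subject, group, gd, value), "longitudinal table")
  data <- data[data[[group]] %in% groups, ]
  d <- data.frame(subject = factor(data[[subject]]),
                  group = factor(data[[group]], levels = groups),
                  gd = as.numeric(data[[gd]]),
                  value = as.numeric(data[[value]]))
  for (gl in groups) {
    if (length(unique(d$gd[d$group == gl])) < 2L) {
      stop("invalid design: each group needs >= 2 distinct gestational days",
           call. = FALSE)
    }
  }
  fit <- lm(value ~ gd * group, data = d)
  an <- anova(fit)
  irow <- match("gd:group", rownames(an))
  fv <- an$`F value`[irow]
  pv <- an$`Pr(>F)`[irow]

  slopes <- do.call(rbind, lapply(groups, function(gl) {
    fg <- lm(value ~ gd, data = d[d$group == gl, ])
    sm <- summary(fg)$coefficients
    tibble::tibble(group = gl, slope = sm["gd", "Estimate"],
                   se = sm["gd", "Std. Error"])
  }))

  subj_slopes <- lapply(split(d, d$subject, drop = TRUE), function(dd) {
    c(slope = subject_slope(dd$gd, dd$value)$beta_raw,
      grp = as.character(dd$group[1]))
  })
  sl <- data.frame(slope = as.numeric(vapply(subj_slopes, `[[`, "", "slope")),
                   grp = vapply(subj_slopes, `[[`, "", "grp"))
  st <- tryCatch({
    tt <- t.test(slope ~ factor(grp, levels = groups), data = sl,
                 var.equal = TRUE)
    list(estimate = unname(diff(tt$estimate)), t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value)
  }, error = function(e) list(estimate = NA_real_, t = NA_real_,
                              df = NA_real_, p = NA_real_))

  structure(list(slopes = tibble::as_tibble(slopes),
                 f = fv, df = c(an$Df[irow], an$Df[nrow(an)]), p = pv,
                 slope_t = st),
            class = "slope_comparison")
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Classical one-way decomposition plus all-pairs honestly-significant-
#' difference tests using the studentized-range distribution
#' (Tukey-Kramer standard errors for unequal group sizes).
#'
#' @param values named list of numeric vectors (one per group), or a numeric
#'   vector with `groups`.
#' @param groups optional group labels when `values` is a vector.
#' @return a list of class `oneway_tukey`: `anova` (tibble: effect, ss, df,
#'   ms, f, p) and `tukey` (tibble: pair, diff, se, q, p).
#' @export
oneway_anova_tukey <- function(values, groups = NULL) {
  if (!is.list(values)) {
    stopifnot(!is.null(groups), length(groups) == length(values))
    values <- split(as.numeric(values), groups)
  }
  values <- lapply(values, function(v) v[is.finite(v)])
  k <- length(values)
  ni <- lengths(values)
  if (k < 2L || any(ni < 2L)) {
    stop("degenerate groups: need >= 2 groups with >= 2 values each", call. = FALSE)
  }
  y <- unlist(values, use.names = FALSE)
  N <- length(y)
  grand <- mean(y)
  mi <- vapply(values, mean, numeric(1))
  ssb <- sum(ni * (mi - grand)^2)
  ssw <- sum(vapply(seq_len(k), function(i) sum((values[[i]] - mi[i])^2),
                    numeric(1)))
  dfb <- k - 1
  dfw <- N - k
  msw <- ssw / dfw
  fv <- if (ssb <= 1e-12 * max(ssb + ssw, 1)) 0 else if (msw <= 1e-300) Inf else
    (ssb / dfb) / msw
  pv <- if (fv == 0) 1 else if (is.infinite(fv)) 0 else
    pf(fv, dfb, dfw, lower.tail = FALSE)

  pairs <- utils::combn(names(values), 2, simplify = FALSE)
  tuk <- do.call(rbind, lapply(pairs, function(pr) {
    d <- mi[[pr[2]]] - mi[[pr[1]]]
    se <- sqrt(msw / 2 * (1 / ni[[pr[1]]] + 1 / ni[[pr[2]]]))
    qv <- if (se > 0) abs(d) / se else if (abs(d) < 1e-12) 0 else Inf
    pq <- if (qv == 0) 1 else if (is.infinite(qv)) 0 else
      ptukey(qv, nmeans = k, df = dfw, lower.tail = FALSE)
    tibble::tibble(pair = paste(pr, collapse = " vs "), diff = d, se = se,
                   q = qv, p = pq)
  }))
  structure(
    list(anova = tibble::tibble(effect = c("group", "residual"),
                                ss = c(ssb, ssw), df = c(dfb, dfw),
                                ms = c(ssb / dfb, msw),
                                f = c(fv, NA), p = c(pv, NA)),
         tukey = tuk),
    class = "oneway_tukey"
  )
}

#' Pearson product-moment correlation with t-based test
#'
#' `r` from the product-moment formula; two-tailed p from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors, `n >= 3`, non-degenerate variance.
#' @return a list of class `correlation_result`: `r`, `n`, `t`, `df`, `p`.
#' @examples
#' pearson_cor(1:5, c(2, 1, 3, 4, 5))$r # 0.9
#' @export
pearson_cor <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("undefined correlation: need n >= 3", call. = FALSE)
  sx <- x - mean(x)
  sy <- y - mean(y)
  vx <- sum(sx^2)
  vy <- sum(sy^2)
  if (vx <= 0 || vy <= 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  r <- sum(sx * sy) / sqrt(vx * vy)
  r <- min(max(r, -1), 1)
  if (abs(r) == 1) {
    tv <- Inf * sign(r)
    p <- 0
  } else {
    tv <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tv), n - 2)
  }
  structure(list(r = r, n = n, t = tv, df = n - 2, p = p),
            class = "correlation_result")
}

#' Simple linear regression by the normal equations
#'
#' Closed-form OLS slope and intercept with the t-based two-tailed slope
#' test; `r` is the Pearson correlation of `x` and `y`.
#'
#' @param x,y numeric vectors, `n >= 3`; `x` must vary.
#' @return a list of class `linregress_result`: `slope`, `intercept`, `se`,
#'   `r`, `t`, `df`, `p`.
#' @export
lin_regress <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("undefined regression: need n >= 3", call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) stop("undefined regression: x has zero variance", call. = FALSE)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  rss <- sum(res^2)
  df <- n - 2
  se <- sqrt(rss / df / sxx)
  if (se == 0) {
    tv <- if (slope == 0) 0 else Inf * sign(slope)
    p <- if (slope == 0) 1 else 0
  } else {
    tv <- slope / se
    p <- 2 * pt(-abs(tv), df)
  }
  syy <- sum((y - mean(y))^2)
  r <- if (syy > 0) slope * sqrt(sxx / syy) else 0
  structure(list(slope = slope, intercept = intercept, se = se, r = r,
                 t = tv, df = df, p = p),
            class = "linregress_result")
}
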