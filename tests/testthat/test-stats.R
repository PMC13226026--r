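# --- mixed repeated-measures ANOVA ------------------------------------------

test_that("mixed ANOVA strata agree with the base aov() oracle", {
  d <- make_rm_data(a = 3, n = 4, b = 3, seed = 11)
  res <- rm_anova(d)

  d$time_f <- factor(d$time)
  oracle <- summary(aov(value ~ group * time_f + Error(subject), data = d))
  bo <- oracle[["Error: subject"]][[1]]
  wo <- oracle[["Error: Within"]][[1]]
  eff <- res$effects
  expect_equal(eff$ss[eff$effect == "group"], bo["group", "Sum Sq"],
               tolerance = 1e-8)
  expect_equal(eff$ss[eff$effect == "subject(group)"], bo["Residuals", "Sum Sq"],
               tolerance = 1e-8)
  expect_equal(eff$ss[eff$effect == "time"], wo["time_f", "Sum Sq"],
               tolerance = 1e-8)
  expect_equal(eff$ss[eff$effect == "group:time"], wo["group:time_f", "Sum Sq"],
               tolerance = 1e-8)
  expect_equal(eff$ss[eff$effect == "residual"], wo["Residuals", "Sum Sq"],
               tolerance = 1e-8)
  expect_equal(eff$p[eff$effect == "group"], bo["group", "Pr(>F)"],
               tolerance = 1e-8)
  expect_equal(eff$p[eff$effect == "time"], wo["time_f", "Pr(>F)"],
               tolerance = 1e-8)

  # sums of squares are additive in the balanced design
  expect_equal(sum(eff$ss), sum((d$value - mean(d$value))^2), tolerance = 1e-8)
})

test_that("degenerate repeated-measures inputs behave as defined", {
  d <- make_rm_data(a = 2, n = 3, b = 3, seed = 1)
  d$value <- 5
  res <- rm_anova(d)
  expect_true(all(res$effects$f[c(1, 3, 4)] == 0))
  expect_true(all(res$effects$p[c(1, 3, 4)] == 1))
  expect_true(all(res$contrasts$p_bonf == 1))

  # pure group shift: time and interaction vanish, group matches the
  # one-way ANOVA on subject means
  d2 <- make_rm_data(a = 3, n = 4, b = 3, seed = 7,
                     effects = list(group_shift = c(0, 2, 5)))
  res2 <- rm_anova(d2)
  sm <- tapply(d2$value, d2$subject, mean)
  sg <- tapply(as.character(d2$group), d2$subject, unique)
  ow <- oneway_anova_tukey(split(as.numeric(sm), sg[names(sm)]))
  expect_equal(res2$effects$f[res2$effects$effect == "group"],
               ow$anova$f[1], tolerance = 1e-8)

  # missing cell -> explicit unbalanced-design error
  d3 <- make_rm_data()[-1, ]
  expect_error(rm_anova(d3), "unbalanced design")
})

test_that("sphericity epsilon is bounded and exact for two time points", {
  d <- make_rm_data(a = 2, n = 5, b = 2, seed = 3)
  expect_equal(rm_anova(d)$gg_epsilon, 1)
  d4 <- make_rm_data(a = 3, n = 6, b = 4, seed = 5)
  eps <- rm_anova(d4)$gg_epsilon
  expect_gte(eps, 1 / 3)
  expect_lte(eps, 1)
})

test_that("Bonferroni contrasts never decrease a p-value and cap at 1", {
  d <- make_rm_data(a = 3, n = 4, b = 3, seed = 23)
  con <- rm_anova(d)$contrasts
  expect_true(all(con$p_bonf >= con$p - 1e-15))
  expect_true(all(con$p_bonf <= 1))
  expect_equal(nrow(con), 3 * 3) # three pairs at each of three times
})

# --- homogeneity-of-slopes ANCOVA -------------------------------------------

test_that("ANCOVA interaction matches the pooled lm and the slope difference", {
  set.seed(3)
  mk <- function(lbl, beta, n = 6, sd = 1) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(subject = paste0(lbl, i), group = lbl, gd = c(14, 16, 18),
                 value = i + beta * c(14, 16, 18) + rnorm(3, sd = sd))
    }))
  }
  d <- rbind(mk("a", 0.5), mk("b", 0.9))
  res <- ancova_slopes(d, groups = c("a", "b"))

  fit <- lm(value ~ gd * group, data = d)
  expect_equal(res$f, anova(fit)["gd:group", "F value"], tolerance = 1e-10)
  expect_equal(res$p, anova(fit)["gd:group", "Pr(>F)"], tolerance = 1e-10)
  # the interaction coefficient is exactly the group slope difference
  expect_equal(unname(coef(fit)["gd:groupb"]),
               diff(res$slopes$slope), tolerance = 1e-10)
  # sensitivity test agrees on the estimate (not, in general, on the p-value)
  expect_equal(res$slope_t$estimate, diff(res$slopes$slope), tolerance = 1e-10)

  expect_error(ancova_slopes(d[d$gd == 14, ], groups = c("a", "b")),
               ">= 2 distinct")
})

test_that("ANCOVA interaction p-values are uniform under the iid null", {
  set.seed(101)
  B <- 400
  p <- numeric(B)
  gds <- c(14, 16, 18)
  for (i in seq_len(B)) {
    d <- data.frame(
      subject = rep(sprintf("s%02d", 1:16), each = 3),
      group = rep(c("x", "y"), each = 24),
      gd = rep(gds, 16),
      value = 2 + 0.5 * rep(gds, 16) + rnorm(48))
    p[i] <- ancova_slopes(d, groups = c("x", "y"))$p
  }
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(p < 0.05) - 0.05), 2.5 * sqrt(0.05 * 0.95 / B))
})

test_that("a study-scale slope difference is detected by the subject-slope test", {
  # 1.76 mmHg/day difference at session-noise scale, n = 8/group
  set.seed(55)
  gds <- c(7, 10, 13, 18)
  hits <- 0
  for (i in 1:50) {
    mk <- function(lbl, beta, inter_sd = 25) {
      do.call(rbind, lapply(1:8, function(j) {
        data.frame(subject = paste0(lbl, j), group = lbl, gd = gds,
                   value = 120 + rnorm(1, sd = inter_sd) + beta * (gds - 7) +
                     rnorm(4, sd = 3))
      }))
    }
    d <- rbind(mk("pe", 3.91), mk("tr", 2.15))
    res <- ancova_slopes(d, groups = c("pe", "tr"))
    if (res$slope_t$p < 0.001) hits <- hits + 1
  }
  expect_gt(hits / 50, 0.5)
})

# --- one-way ANOVA with Tukey HSD -------------------------------------------

test_that("one-way ANOVA and Tukey agree with base R oracles", {
  set.seed(9)
  vals <- list(a = rnorm(6, 0), b = rnorm(6, 1), c = rnorm(6, 0.5))
  res <- oneway_anova_tukey(vals)

  d <- data.frame(y = unlist(vals), g = rep(names(vals), each = 6))
  fit <- aov(y ~ g, data = d)
  expect_equal(res$anova$f[1], summary(fit)[[1]]["g", "F value"],
               tolerance = 1e-10)
  thsd <- TukeyHSD(fit)$g
  for (i in seq_len(nrow(res$tukey))) {
    pr <- strsplit(res$tukey$pair[i], " vs ")[[1]]
    key <- paste(pr[2], pr[1], sep = "-")
    expect_equal(res$tukey$p[i], unname(thsd[key, "p adj"]), tolerance = 1e-8)
  }

  # identical groups: F = 0, all p = 1
  same <- oneway_anova_tukey(list(a = rep(2, 4), b = rep(2, 4)))
  expect_equal(same$anova$f[1], 0)
  expect_equal(same$anova$p[1], 1)
  expect_true(all(same$tukey$p == 1))

  expect_error(oneway_anova_tukey(list(a = 1, b = c(1, 2))), "degenerate")
})

test_that("two-group Tukey reduces to the pooled t-test (q = t sqrt(2))", {
  set.seed(12)
  a <- rnorm(7, 0)
  b <- rnorm(7, 1.2)
  res <- oneway_anova_tukey(list(a = a, b = b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$tukey$q, abs(tt$statistic) * sqrt(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  # ptukey is itself a numerical CDF: agreement to its quadrature accuracy
  expect_equal(res$tukey$p, tt$p.value, tolerance = 1e-6)
})

test_that("Tukey p matches a Monte-Carlo studentized-range estimate", {
  vals <- list(a = c(1.0, 2.1, 2.9, 4.2, 5.1),
               b = c(2.0, 3.2, 4.1, 5.0, 6.2),
               c = c(1.4, 2.6, 3.5, 4.6, 5.3))
  res <- oneway_anova_tukey(vals)
  k <- 3
  n <- 5
  dfw <- k * (n - 1)
  set.seed(99)
  B <- 1e5
  means <- matrix(rnorm(B * k, sd = 1 / sqrt(n)), B, k)
  s <- sqrt(stats::rchisq(B, dfw) / dfw)
  q_null <- (apply(means, 1, max) - apply(means, 1, min)) / (s / sqrt(n))
  for (i in seq_len(nrow(res$tukey))) {
    p_mc <- mean(q_null > res$tukey$q[i])
    expect_lt(abs(res$tukey$p[i] - p_mc), 0.005)
  }
  # multiplicity-protected p is never below the unadjusted pairwise p
  for (i in seq_len(nrow(res$tukey))) {
    pr <- strsplit(res$tukey$pair[i], " vs ")[[1]]
    tt <- t.test(vals[[pr[1]]], vals[[pr[2]]], var.equal = TRUE)
    expect_gte(res$tukey$p[i], tt$p.value - 1e-12)
  }
})

# --- correlation and regression ---------------------------------------------

test_that("product-moment correlation matches hand arithmetic and cor.test", {
  # x = 1..5, y = (2,1,3,4,5): sum of cross-deviations 9, each SS 10 -> r = 0.9
  res <- pearson_cor(1:5, c(2, 1, 3, 4, 5))
  expect_equal(res$r, 0.9, tolerance = 1e-12)
  ct <- stats::cor.test(1:5, c(2, 1, 3, 4, 5))
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  expect_equal(res$t, unname(ct$statistic), tolerance = 1e-12)

  expect_equal(pearson_cor(1:8, 2 * (1:8) + 1)$r, 1)
  expect_equal(pearson_cor(1:8, -(1:8))$r, -1)
  expect_equal(pearson_cor(1:8, -(1:8))$p, 0)
  expect_error(pearson_cor(1:5, rep(3, 5)), "zero variance")
  expect_error(pearson_cor(1:2, 2:3), "n >= 3")
})

test_that("closed-form regression matches the lm oracle on random fixtures", {
  set.seed(4)
  for (i in 1:5) {
    x <- rnorm(10)
    y <- 1.5 - 2 * x + rnorm(10, sd = 0.7)
    res <- lin_regress(x, y)
    fit <- summary(lm(y ~ x))
    expect_equal(res$slope, fit$coefficients["x", "Estimate"], tolerance = 1e-10)
    expect_equal(res$intercept, fit$coefficients["(Intercept)", "Estimate"],
                 tolerance = 1e-10)
    expect_equal(res$p, fit$coefficients["x", "Pr(>|t|)"], tolerance = 1e-10)
  }
  col <- lin_regress(1:6, 3 + 2 * (1:6))
  expect_equal(col$slope, 2)
  expect_equal(col$p, 0)
  expect_error(lin_regress(rep(1, 5), 1:5), "zero variance")
})
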