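# --- photoacoustic forward model and spectral unmixing ---------------------

test_that("pure chromophores produce signals proportional to their extinction column", {
  eps <- hb_extinction()
  oxy <- simulate_pa_signals(1, total_hb = 2)$amplitude
  deoxy <- simulate_pa_signals(0, total_hb = 2)$amplitude
  expect_equal(unname(oxy), unname(2 * eps["HbO2", ]))
  expect_equal(unname(deoxy), unname(2 * eps["Hb", ]))
  # 50% saturation with equal fluence: ratio of summed extinction columns
  half <- simulate_pa_signals(0.5)$amplitude
  expect_equal(unname(half[1] / half[2]),
               sum(eps[, "750"]) / sum(eps[, "850"]))
})

test_that("unmixing inverts the forward model exactly on a saturation grid", {
  for (s in seq(0, 1, by = 0.05)) {
    pair <- simulate_pa_signals(s, total_hb = 0.7)
    expect_equal(unmix_so2(pair), s, tolerance = 1e-12)
  }
  # worked 2x2 solve: amplitudes are the column sums of the extinction table,
  # i.e. unit concentrations of both chromophores
  expect_equal(unmix_so2(c(1405.24 + 518.0, 691.32 + 1058.0)), 0.5,
               tolerance = 1e-12)
})

test_that("estimated saturation is fluence-magnitude invariant and ratio-monotone", {
  pair <- simulate_pa_signals(0.37)
  expect_equal(unmix_so2(7.3 * pair$amplitude), unmix_so2(pair), tolerance = 1e-12)
  # 850 nm is the oxy-dominant wavelength: increasing p850/p750 raises sO2
  p750 <- 1000
  ests <- vapply(seq(0.5, 2, length.out = 12),
                 function(r) unmix_so2(c(p750, p750 * r)), numeric(1))
  expect_true(all(diff(ests) >= 0))
})

test_that("degenerate extinction matrices are rejected", {
  bad <- matrix(c(1, 2, 2, 4), 2, 2)
  expect_error(unmix_so2(c(1, 2), eps = bad), "singular")
  expect_error(simulate_pa_signals(0.5, eps = matrix(c(-1, 2, 3, 4), 2, 2)),
               "positive")
  expect_warning(unmix_so2(c(5000, 100)), "clipped") # out-of-gamut pair
})

# --- contrast bolus curves and kinetic fitting ------------------------------

test_that("bolus curve obeys its generating kinetics", {
  tic <- simulate_tic(20000, t0 = 5, mu = 3.38, sigma = 0.4, dt = 0.05)
  # noiseless maximum at t0 + exp(mu - sigma^2), checked by grid search
  t_peak <- tic$time[which.max(tic$intensity)]
  expect_equal(t_peak, 5 + exp(3.38 - 0.4^2), tolerance = 0.05 / 2 + 1e-9)
  # zero blood volume -> flat baseline
  flat <- simulate_tic(0, baseline = 7)
  expect_equal(flat$intensity, rep(7, length(flat$time)))
  # linearity: doubling the blood volume doubles every enhancement sample
  a <- simulate_tic(9000)
  b <- simulate_tic(18000)
  expect_equal(b$intensity - b$baseline, 2 * (a$intensity - a$baseline),
               tolerance = 1e-12)
})

test_that("kinetic fit recovers noiseless parameters and the quadrature wash-in area", {
  # Latin-hypercube over the kinetic parameter space
  set.seed(31)
  u <- lhs::randomLHS(8, 4)
  t0s <- 2 + 8 * u[, 1]
  mus <- 2.8 + 0.8 * u[, 2]
  sigmas <- 0.25 + 0.35 * u[, 3]
  rbvs <- 5000 + 25000 * u[, 4]
  for (i in seq_len(8)) {
    tic <- simulate_tic(rbvs[i], t0 = t0s[i], mu = mus[i], sigma = sigmas[i])
    fit <- fit_tic(tic)
    expect_identical(fit$quality, "ok")
    A_true <- unname(tic$params["A"])
    expect_equal(unname(fit$params["t0"]), t0s[i], tolerance = 1e-3)
    expect_equal(unname(fit$params["mu"]), mus[i], tolerance = 1e-3)
    expect_equal(unname(fit$params["sigma"]), sigmas[i], tolerance = 1e-3)
    expect_equal(unname(fit$params["A"]), A_true, tolerance = 1e-3)
    # independent quadrature oracle on the true curve, arrival to peak
    peak <- t0s[i] + exp(mus[i] - sigmas[i]^2)
    oracle <- stats::integrate(function(u.) A_true * dlnorm(u. - t0s[i], mus[i], sigmas[i]),
                               t0s[i], peak, rel.tol = 1e-10)$value
    expect_equal(fit$wiauc, oracle, tolerance = 0.01)
  }
})

test_that("wash-in area is linear in amplitude and flat curves are flagged", {
  f1 <- fit_tic(simulate_tic(8000))
  f2 <- fit_tic(simulate_tic(24000))
  expect_equal(f2$wiauc / f1$wiauc, 3, tolerance = 1e-4)

  flat <- fit_tic(simulate_tic(0, noise_sd = 0))
  expect_identical(flat$quality, "flat")
  expect_true(is.na(flat$wiauc))
  set.seed(2)
  noisy_flat <- fit_tic(simulate_tic(0, noise_sd = 30))
  expect_identical(noisy_flat$quality, "flat")

  expect_error(fit_tic(list(time = 1:5, intensity = rnorm(5))), ">= 20 samples")
})

test_that("raw-curve wash-in integration is available and close to the model integral", {
  tic <- simulate_tic(15000, dt = 0.1)
  m <- fit_tic(tic, wiauc_method = "model")
  r <- fit_tic(tic, wiauc_method = "raw")
  expect_equal(r$wiauc, m$wiauc, tolerance = 0.02)
})

# --- Doppler cycles and resistance index ------------------------------------

test_that("resistance index follows its defining ratio", {
  expect_equal(compute_ri(list(psv = 60, edv = 21)), 0.65)
  expect_equal(compute_ri(list(psv = 50, edv = 0)), 1)
  expect_equal(compute_ri(list(psv = 50, edv = 50)), 0)
  # invariant to common velocity rescaling
  cyc <- simulate_doppler_cycles(60, 20, noise_sd = 0)
  expect_equal(compute_ri(list(psv = 3.7 * cyc$psv, edv = 3.7 * cyc$edv)),
               compute_ri(cyc))
  expect_error(compute_ri(list(psv = c(60, 0), edv = c(10, 0))), "positive")
})

test_that("cycle simulation is unbiased, seeded, and order-constrained", {
  expect_equal(compute_ri(simulate_doppler_cycles(60, 21, noise_sd = 0)), 0.65)
  set.seed(8)
  a <- simulate_doppler_cycles(60, 20, noise_sd = 2)
  set.seed(8)
  b <- simulate_doppler_cycles(60, 20, noise_sd = 2)
  expect_identical(a, b)
  # CLT check: mean of many cycles returns the truth within 3 SE
  set.seed(21)
  n <- 1e5
  psv <- 60 + rnorm(n, sd = 2)
  edv <- 20 + rnorm(n, sd = 2)
  expect_lt(abs(mean(psv) - 60), 3 * 2 / sqrt(n))
  # order violations are clipped with a warning
  expect_warning(simulate_doppler_cycles(10, 9.9, noise_sd = 5), "clipped")
  expect_error(simulate_doppler_cycles(10, 11), "configuration error")
  expect_error(simulate_doppler_cycles(10, 5, n_cycles = 7), "configuration error")
})

# --- vascular maps and the vascular index -----------------------------------

test_that("vascular index counts above-threshold ROI pixels", {
  z <- matrix(0, 8, 8)
  expect_equal(compute_vi(list(magnitude = z, roi = z == 0, threshold = 1)), 0)
  expect_equal(compute_vi(list(magnitude = z + 9, roi = z == 0, threshold = 1)), 100)
  half <- matrix(c(rep(0, 32), rep(9, 32)), 8, 8)
  expect_equal(compute_vi(list(magnitude = half, roi = half >= 0, threshold = 1)), 50)
  expect_error(compute_vi(list(magnitude = z, roi = z > 1, threshold = 1)),
               "empty ROI")
})

test_that("expected vascular index equals the true density at high contrast", {
  expect_equal(compute_vi(simulate_vascular_map(0, noise_sd = 0)), 0)
  expect_equal(compute_vi(simulate_vascular_map(1, noise_sd = 0)), 100)
  set.seed(14)
  vi <- compute_vi(simulate_vascular_map(0.4, dim = c(256, 256)))
  expect_lt(abs(vi / 100 - 0.4), 0.01) # binomial SE bound at 256^2 pixels
})

test_that("vascular index is invariant under threshold-preserving monotone transforms", {
  set.seed(15)
  map <- simulate_vascular_map(0.3, dim = c(64, 64))
  vi0 <- compute_vi(map)
  trans <- map
  trans$magnitude <- exp(map$magnitude)
  trans$threshold <- exp(map$threshold)
  expect_equal(compute_vi(trans), vi0)
})
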