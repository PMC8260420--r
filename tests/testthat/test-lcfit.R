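test_that("noiseless fits recover amplitudes to numerical precision", {
  spec <- mrs_spectrum(PARAMS$grid, 3.0 * BASIS$spectra[, "Eth"], PARAMS)
  fit <- lcfit(spec, BASIS, noise_sd = 0)
  expect_equal(unname(fit$amplitudes["Eth"]), 3.0, tolerance = 1e-8)
  expect_equal(unname(fit$amplitudes[c("NAA", "Cr", "Cho")]), rep(0, 3),
               tolerance = 1e-8)

  truth <- c(Eth = 2, NAA = 15, Cr = 10, Cho = 8)
  mix <- mrs_spectrum(PARAMS$grid,
                      as.numeric(BASIS$spectra %*% truth[BASIS$names]),
                      PARAMS)
  fit2 <- lcfit(mix, BASIS, noise_sd = 0)
  expect_equal(fit2$amplitudes[BASIS$names], truth[BASIS$names],
               tolerance = 1e-6)
  expect_lt(fit2$residual_rms, 1e-8)
})

test_that("a spectrum matching the negative of a basis column is fitted at the zero boundary (KKT)", {
  spec <- mrs_spectrum(PARAMS$grid, -2 * BASIS$spectra[, "NAA"], PARAMS)
  fit <- lcfit(spec, BASIS, noise_sd = 0)
  # unconstrained oracle goes negative; the constrained fit must not
  ols <- qr.coef(qr(BASIS$spectra), spec$intensity)
  expect_lt(ols["NAA"], 0)
  expect_identical(unname(fit$amplitudes["NAA"]), 0)
  expect_true(all(fit$amplitudes >= 0))
  # KKT: the gradient at inactive coordinates must not favour entering
  grad <- crossprod(BASIS$spectra, fit$residuals)
  expect_true(all(grad[!fit$active] <= 1e-6))
})

test_that("when the unconstrained solution is nonnegative the fit equals the normal-equations oracle", {
  for (seed in 1:8) {
    tr <- ground_truth(c(Eth = 10, NAA = 14, Cr = 9, Cho = 4),
                       noise_sd = 20, seed = seed)
    spec <- simulate_spectrum(tr, BASIS)
    ols <- qr.coef(qr(BASIS$spectra), spec$intensity)
    if (any(ols < 0)) next
    fit <- lcfit(spec, BASIS)
    expect_equal(fit$amplitudes, ols[BASIS$names], tolerance = 1e-8)
  }
})

test_that("the active-set solver agrees with brute-force enumeration on small designs", {
  sb <- small_basis()
  set.seed(402)
  for (rep in 1:12) {
    y <- as.numeric(sb$spectra %*% runif(3, -2, 4)) +
      rnorm(length(sb$params$grid), 0, 2)
    fit <- lcfit(mrs_spectrum(sb$params$grid, y, sb$params), sb,
                 noise_sd = 1)
    oracle <- nnls_bruteforce(sb$spectra, y)
    expect_equal(unname(fit$amplitudes), oracle$x, tolerance = 1e-6)
  }
})

test_that("CRLBs scale linearly in noise and inversely in amplitude", {
  spec <- mrs_spectrum(PARAMS$grid,
                       as.numeric(BASIS$spectra %*% c(8, 12, 9, 3)), PARAMS)
  fit <- lcfit(spec, BASIS, noise_sd = 10)
  expect_equal(crlb(fit, noise_sd = 20), 2 * crlb(fit, noise_sd = 10),
               tolerance = 1e-12)

  spec2 <- mrs_spectrum(PARAMS$grid,
                        as.numeric(BASIS$spectra %*% c(16, 12, 9, 3)), PARAMS)
  fit2 <- lcfit(spec2, BASIS, noise_sd = 10)
  expect_equal(unname(crlb(fit2, 10)["Eth"]),
               unname(crlb(fit, 10)["Eth"]) / 2, tolerance = 1e-9)
})

test_that("metabolites fitted at zero get a flagged (NA) CRLB", {
  spec <- mrs_spectrum(PARAMS$grid, 5 * BASIS$spectra[, "Cr"], PARAMS)
  fit <- lcfit(spec, BASIS, noise_sd = 1)
  expect_true(is.na(fit$crlb_percent["Eth"]))
  expect_gt(fit$crlb_percent["Cr"], 0)
})

test_that("scaling the spectrum scales amplitudes and leaves relative CRLBs unchanged", {
  tr <- ground_truth(noise_sd = 40, seed = 5)
  spec <- simulate_spectrum(tr, BASIS)
  fit1 <- lcfit(spec, BASIS)
  spec_c <- mrs_spectrum(spec$grid, 3 * spec$intensity, PARAMS)
  fit3 <- lcfit(spec_c, BASIS)
  expect_equal(fit3$amplitudes, 3 * fit1$amplitudes, tolerance = 1e-8)
  expect_equal(fit3$crlb_percent, fit1$crlb_percent, tolerance = 1e-8)
  expect_equal(fit3$noise_sd_est, 3 * fit1$noise_sd_est, tolerance = 1e-8)
})

test_that("noise estimation is accurate, detrended and exact in the noiseless limit", {
  flat <- with(list(), {
    set.seed(31)
    mrs_spectrum(PARAMS$grid, rnorm(length(PARAMS$grid), 0, 0.5), PARAMS)
  })
  expect_lt(abs(estimate_noise(flat) - 0.5) / 0.5, 0.10)
  # adding an offset and a linear trend leaves the estimate unchanged
  trended <- mrs_spectrum(PARAMS$grid,
                          flat$intensity + 7 + 2 * PARAMS$grid, PARAMS)
  expect_equal(estimate_noise(trended), estimate_noise(flat),
               tolerance = 1e-9)
  silent <- mrs_spectrum(PARAMS$grid, rep(0, length(PARAMS$grid)), PARAMS)
  expect_lt(estimate_noise(silent), 1e-12)
  # metabolite tails reaching into the window stay negligible vs the signal
  clean <- mrs_spectrum(PARAMS$grid,
                        as.numeric(BASIS$spectra %*% c(8, 12, 9, 3)), PARAMS)
  expect_lt(estimate_noise(clean) / max(clean$intensity), 1e-4)
  expect_error(estimate_noise(flat, window = c(7, 8)), "window")
})

test_that("rank-deficient bases are refused with the collinear columns named", {
  dup <- basis_set(c("Eth", "EthCopy"),
                   cbind(BASIS$spectra[, "Eth"], BASIS$spectra[, "Eth"]),
                   PARAMS)
  spec <- mrs_spectrum(PARAMS$grid, BASIS$spectra[, "Eth"], PARAMS)
  expect_error(lcfit(spec, dup, noise_sd = 0), "EthCopy")
})

test_that("grid mismatches are resampled when possible and refused when extrapolating", {
  fine <- acq_params(grid = seq(-0.5, 5.5, length.out = 4096))
  tr <- ground_truth(c(Eth = 6, NAA = 10, Cr = 7, Cho = 2), noise_sd = 0)
  fine_basis <- default_basis(fine)
  spec_fine <- simulate_spectrum(tr, fine_basis)
  fit <- lcfit(spec_fine, BASIS, noise_sd = 0)
  expect_equal(fit$amplitudes[names(tr$concentrations)],
               tr$concentrations, tolerance = 5e-3)

  narrow <- mrs_spectrum(seq(1, 4, length.out = 1024),
                         rep(0, 1024), acq_params(grid = seq(1, 4,
                                                             length.out = 1024)))
  expect_error(lcfit(narrow, BASIS, noise_sd = 0), "extrapolate")
})

test_that("an optional polynomial baseline is removed without biasing the amplitudes", {
  truth <- c(Eth = 8, NAA = 12, Cr = 9, Cho = 3)
  base <- 40 + 15 * PARAMS$grid - 2 * PARAMS$grid^2
  y <- as.numeric(BASIS$spectra %*% truth[BASIS$names]) + base
  fit <- lcfit(mrs_spectrum(PARAMS$grid, y, PARAMS), BASIS, noise_sd = 0,
               baseline_degree = 2)
  expect_equal(fit$amplitudes[BASIS$names], truth[BASIS$names],
               tolerance = 1e-4)
})

test_that("model methods are consistent: fitted + residuals reconstruct the data, simulate is seeded", {
  tr <- ground_truth(noise_sd = 40, seed = 8)
  spec <- simulate_spectrum(tr, BASIS)
  fit <- lcfit(spec, BASIS)
  expect_equal(fitted(fit) + residuals(fit), spec$intensity,
               tolerance = 1e-12)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, newdata = data.frame(ppm = c(2.01, 3.03))),
               approx(fit$grid, fitted(fit), xout = c(2.01, 3.03))$y)
  reps1 <- simulate(fit, nsim = 3, seed = 21)
  reps2 <- simulate(fit, nsim = 3, seed = 21)
  expect_identical(reps1, reps2)
  expect_equal(dim(reps1), c(length(PARAMS$grid), 3L))
  s <- summary(fit)
  expect_s3_class(s, "summary.lcfit")
  expect_named(s$table, c("metabolite", "amplitude", "crlb_percent",
                          "active"))
})
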