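test_that("spatial binning sums the square window with border truncation", {
  instr <- flim_instrument(n_channels = 8)
  cube <- simulate_flim_cube(flim_scene(10, 10, background_photons = 0),
                             instr, seed = 1)
  cube$counts[] <- 1  # constant 1 count/channel/pixel
  out <- spatial_bin(cube, 3)
  expect_equal(out$counts[1, 5, 5], 49)  # interior: full 7x7 window
  expect_equal(out$counts[1, 1, 1], 16)  # corner: 4x4 in-bounds window
  expect_equal(out$counts[1, 1, 5], 28)  # edge: 4x7
  # binning = 0 is the identity
  expect_identical(spatial_bin(cube, 0)$counts, cube$counts)
  # window sums conserve the uniform field exactly
  expect_equal(sum(out$counts[1, , ]),
               sum(sapply(1:10, function(y) sapply(1:10, function(x)
                 (min(y + 3, 10) - max(y - 3, 1) + 1) *
                   (min(x + 3, 10) - max(x - 3, 1) + 1)))))
})

test_that("intensity threshold mask separates a two-level image exactly", {
  instr <- flim_instrument(n_channels = 8)
  cube <- simulate_flim_cube(flim_scene(6, 6, background_photons = 0),
                             instr, seed = 1)
  cube$counts[] <- 1
  bright <- matrix(FALSE, 6, 6); bright[2:4, 3:5] <- TRUE
  for (i in which(bright)) cube$counts[, i %% 6 + 1, (i - 1) %/% 6 + 1] <- 0
  cube$counts[, 2:4, 3:5] <- 10
  expect_equal(intensity_threshold_mask(cube, 40), cube_intensity(cube) >= 40)
  expect_true(all(intensity_threshold_mask(cube, 0)))
  expect_false(any(intensity_threshold_mask(cube, 1e6)))
})

test_that("fit recovers parameters of simulated M1-like decays", {
  instr <- flim_instrument()
  truth <- m1_cell()
  res <- t(sapply(1:25, function(i) {
    h <- simulate_decay(truth, instr, total_photons = 1e5, seed = 100 + i)
    f <- fit_biexponential(h)
    c(f$tau1, f$tau2, f$a1 / f$a2, f$chi2_reduced)
  }))
  expect_lt(median(abs(res[, 1] - truth$tau1) / truth$tau1), 0.10)
  expect_lt(median(abs(res[, 2] - truth$tau2) / truth$tau2), 0.10)
  expect_lt(median(abs(res[, 3] - 5) / 5), 0.15)
  # correctly specified model: reduced Pearson chi2 near 1
  expect_gte(mean(res[, 4] >= 0.8 & res[, 4] <= 1.2), 0.9)
})

test_that("fit handles degenerate and invalid inputs", {
  instr <- test_instrument()
  # noiseless mono-exponential: effective lifetime recovered, flag set
  h <- expected_decay(list(tau1 = 1000, tau2 = 1000, a1 = 0.5), instr, 1e6)
  f <- fit_biexponential(h)
  eff <- compute_tau_m(f$a1, f$a2, f$tau1, f$tau2)
  dominant <- if (f$a1 > f$a2) f$tau1 else f$tau2
  expect_equal(dominant, 1000, tolerance = 0.01)
  expect_true(f$degenerate)
  expect_lt(f$chi2_reduced, 0.05)  # noiseless

  zero <- decay_histogram(rep(0, instr$n_channels), instr)
  expect_error(fit_biexponential(zero), "all-zero")
  few <- decay_histogram(rep(1, instr$n_channels), instr)
  expect_error(fit_biexponential(few), "1000 photons")

  low <- simulate_decay(m1_cell(), instr, 3000, seed = 1)
  expect_true(fit_biexponential(low)$warn_low_photons)
})

test_that("fit is invariant to swapping the initializer components", {
  h <- simulate_decay(m1_cell(), flim_instrument(), 5e4, seed = 9)
  f1 <- fit_biexponential(h, init = list(tau1 = 300, tau2 = 2000, a1 = 0.7))
  f2 <- fit_biexponential(h, init = list(tau1 = 2000, tau2 = 300, a1 = 0.3))
  expect_identical(f1[c("tau1", "tau2", "a1", "shift", "offset")],
                   f2[c("tau1", "tau2", "a1", "shift", "offset")])
})

test_that("estimator bias shrinks with the photon budget", {
  instr <- flim_instrument()
  err <- sapply(c(1e4, 1e6), function(np) {
    res <- sapply(1:8, function(i) {
      f <- fit_biexponential(simulate_decay(m1_cell(), instr, np,
                                            seed = 200 + i))
      abs(f$tau2 - 1698) / 1698
    })
    median(res)
  })
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.01)
})

test_that("fit on binned uniform data equals fit on the summed histogram", {
  instr <- flim_instrument()
  sc <- flim_scene(7, 7, background = m1_cell(), background_photons = 2000)
  cube <- simulate_flim_cube(sc, instr, seed = 3)
  binned <- spatial_bin(cube, 3)
  centre <- binned$counts[, 4, 4]
  expect_equal(centre, rowSums(matrix(cube$counts, instr$n_channels)))
  f1 <- fit_biexponential(decay_histogram(centre, instr))
  f2 <- fit_biexponential(decay_histogram(
    rowSums(matrix(cube$counts, instr$n_channels)), instr))
  expect_identical(f1$tau1, f2$tau1)
})

test_that("diagnostic correlations behave under null and perfect dependence", {
  set.seed(1)
  fits <- lapply(1:200, function(i) {
    structure(list(tau1 = rnorm(1, 200, 20), tau2 = rnorm(1, 1700, 100),
                   a1 = 0.8, a2 = 0.2, chi2_reduced = rnorm(1, 1, 0.05)),
              class = "biexp_fit")
  })
  intens <- rnorm(200, 1000, 100)  # independent of everything
  rep <- check_diagnostic_correlations(fits, intens)
  ok <- rep$predictor == "intensity" & !rep$undefined
  expect_true(all(abs(rep$pearson_r[ok]) < 0.2))
  # constant a1 makes the amp-ratio correlation undefined, not zero
  expect_true(rep$undefined[rep$predictor == "intensity" &
                              rep$parameter == "amp_ratio"])

  # intensity defined as a copy of tau1: perfect correlation
  tau1s <- vapply(fits, `[[`, numeric(1), "tau1")
  rep2 <- check_diagnostic_correlations(fits, tau1s)
  expect_equal(rep2$pearson_r[rep2$predictor == "intensity" &
                                rep2$parameter == "tau1"], 1)

  expect_error(check_diagnostic_correlations(fits[1:2], intens[1:2]),
               "at least 3")
  # constant column reported as undefined
  cfits <- lapply(fits, function(f) { f$tau1 <- 200; f })
  rep3 <- check_diagnostic_correlations(cfits, intens)
  expect_true(any(rep3$undefined))
})
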