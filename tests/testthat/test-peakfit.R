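test_that("the eight default windows carry the documented bounds", {
  w <- default_windows()
  expect_equal(nrow(w), 8)
  expect_setequal(w$name, c("Cr2", "Ins2", "Ins1", "Cho", "Cr1",
                            "Glx3", "Glx4", "NAA"))
  expect_equal(w[w$name == "Glx3", c("lo_ppm", "hi_ppm")],
               data.frame(lo_ppm = 2.25, hi_ppm = 2.35),
               ignore_attr = TRUE)
  expect_equal(w[w$name == "NAA", c("lo_ppm", "hi_ppm")],
               data.frame(lo_ppm = 1.82, hi_ppm = 2.22),
               ignore_attr = TRUE)
  expect_true(all(w$lo_ppm < w$hi_ppm))
  # Glx3 and Glx4 overlap; no other pair does
  expect_lt(w$hi_ppm[w$name == "Glx3"] - w$lo_ppm[w$name == "Glx4"], 0.05)
  expect_gt(w$hi_ppm[w$name == "Glx3"], w$lo_ppm[w$name == "Glx4"])
})

test_that("a noiseless Gaussian is recovered with its analytic area", {
  truth <- list(A = 120, c = 3.22, s = 0.025)
  spec <- spectrum_from_fn(function(ppm) {
    truth$A * exp(-(ppm - truth$c)^2 / (2 * truth$s^2))
  })
  fit <- fit_window(spec, list(name = "Cho", lo_ppm = 3.14, hi_ppm = 3.34))
  expect_true(fit$converged)
  expect_false(fit$at_bound)
  analytic <- truth$A * truth$s * sqrt(2 * pi)
  expect_equal(fit$area, analytic, tolerance = 0.005)
  expect_equal(fit$center_ppm, truth$c, tolerance = 1e-4)

  # area formula agrees with numeric integration of the fitted curve
  grid <- seq(fit$center_ppm - 10 * fit$sigma_ppm,
              fit$center_ppm + 10 * fit$sigma_ppm, length.out = 20001)
  numeric_area <- sum(fit$amplitude *
                        exp(-(grid - fit$center_ppm)^2 /
                              (2 * fit$sigma_ppm^2))) * diff(grid[1:2])
  expect_equal(fit$area, numeric_area, tolerance = 1e-3)
})

test_that("degenerate windows behave per contract", {
  flat <- spectrum_from_fn(function(ppm) rep(0, length(ppm)))
  f0 <- fit_window(flat, list(name = "Cho", lo_ppm = 3.14, hi_ppm = 3.34))
  expect_true(f0$converged)
  expect_lt(abs(f0$amplitude), 1e-8)
  expect_lt(abs(f0$area), 1e-8)

  # peak outside the window: the centre clamps to the bound and is flagged
  off <- spectrum_from_fn(function(ppm) {
    100 * exp(-(ppm - 3.10)^2 / (2 * 0.02^2))
  })
  fe <- fit_window(off, list(name = "Cho", lo_ppm = 3.14, hi_ppm = 3.34))
  expect_true(fe$at_bound)
  expect_equal(fe$center_ppm, 3.14, tolerance = 1e-6)

  expect_error(fit_window(flat, list(name = "far", lo_ppm = 30, hi_ppm = 31)),
               "outside")
})

test_that("the joint Glx fit resolves the overlapping pair", {
  two <- spectrum_from_fn(function(ppm) {
    300 * exp(-(ppm - 2.29)^2 / (2 * 0.02^2)) +
      400 * exp(-(ppm - 2.35)^2 / (2 * 0.02^2))
  })
  pair <- fit_glx_pair(two)
  a3_true <- 300 * 0.02 * sqrt(2 * pi)
  a4_true <- 400 * 0.02 * sqrt(2 * pi)
  expect_equal(pair$glx3$area, a3_true, tolerance = 0.02)
  expect_equal(pair$glx4$area, a4_true, tolerance = 0.02)
  expect_true(pair$glx3$converged && pair$glx4$converged)

  # absent Glx3 signal: its fitted area is negligible next to Glx4
  solo <- spectrum_from_fn(function(ppm) {
    400 * exp(-(ppm - 2.35)^2 / (2 * 0.02^2))
  })
  ps <- fit_glx_pair(solo)
  expect_lt(ps$glx3$area, 0.01 * ps$glx4$area)

  # swapping starting centres does not swap the assigned areas
  swapped <- fit_glx_pair(two, init = list(center_glx3 = 2.33,
                                           center_glx4 = 2.33))
  expect_equal(swapped$glx3$area, pair$glx3$area, tolerance = 0.02)
  expect_equal(swapped$glx4$area, pair$glx4$area, tolerance = 0.02)
})

test_that("the panel fit recovers all eight relative areas on a clean voxel", {
  acq <- mrs_acq()
  spec <- process(simulate_fid(gm_truth(), acq, seed = 14))
  panel <- fit_panel(spec, voxel = "clean")
  expect_s3_class(panel, "mrs_panel")
  expect_equal(nrow(panel), 8)
  expect_setequal(panel$window, default_windows()$name)
  expect_true(attr(panel, "all_converged"))

  # with equal linewidths, fitted areas relative to NAA must match the
  # simulated effective amplitudes relative to NAA
  b <- build_basis("gray")
  conc <- default_concentrations("gray")
  eff <- c(conc, Glx = unname(conc["Glu"] + conc["Gln"]))
  amp <- vapply(seq_len(nrow(b)), function(i) {
    eff[[b$metabolite[i]]] * b$rel_signal[i]
  }, numeric(1))
  names(amp) <- b$window
  area_naa <- panel$area[panel$window == "NAA"]
  # 2.5%: the adjacent Ins1/Ins2 windows cross-talk by about 2% because
  # each is fitted independently and their tails overlap slightly
  for (wn in c("Cr2", "Ins2", "Ins1", "Cho", "Cr1", "Glx3", "Glx4")) {
    expect_equal(panel$area[panel$window == wn] / area_naa,
                 unname(amp[wn] / amp["NAA"]),
                 tolerance = 0.025, label = wn)
  }
})

test_that("area error grows with the noise level", {
  acq <- mrs_acq()
  ratio_err <- function(noise_sd, seeds) {
    vapply(seeds, function(s) {
      spec <- process(simulate_fid(gm_truth(noise_sd = noise_sd), acq,
                                   seed = s))
      pair <- fit_glx_pair(spec)
      pair$glx3$area / pair$glx4$area - 0.81
    }, numeric(1))
  }
  seeds <- 101:108
  rmse_lo <- sqrt(mean(ratio_err(0.05, seeds)^2))
  rmse_hi <- sqrt(mean(ratio_err(0.5, seeds)^2))
  expect_gt(rmse_hi, rmse_lo)
})

test_that("panels serialize to CSV and back", {
  acq <- mrs_acq()
  panel <- fit_panel(process(simulate_fid(gm_truth(), acq, seed = 15)),
                     voxel = "v1")
  path <- tempfile(fileext = ".csv")
  write_panel_csv(panel, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 8)
  expect_equal(back$area, panel$area, tolerance = 1e-12)
})
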