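test_that("Hanning apodization has the prescribed window values", {
  acq <- mrs_acq(n_points = 600L, dwell_ms = 1)
  fid <- mrs_fid(rep(1 + 0i, 600), acq)
  ap <- apodize(fid)
  t_ms <- time_axis_ms(fid)
  expect_equal(Re(ap$samples[t_ms == 0]), 1)            # w(0) = 1
  expect_equal(Re(ap$samples[t_ms == 256]), 0.5)        # w(256) = 0.5
  expect_equal(Re(ap$samples[t_ms == 512]), 0, tolerance = 1e-15)
  expect_true(all(Mod(ap$samples[t_ms > 512]) == 0))
  expect_length(ap$samples, 600)
})

test_that("zero filling appends exact zeros and preserves energy", {
  acq <- mrs_acq(n_points = 1024L)
  fid <- simulate_fid(gm_truth(noise_sd = 0.1), acq, seed = 8)
  zf <- zero_fill(fid)
  expect_length(zf$samples, 2048)
  expect_identical(zf$samples[1:1024], fid$samples)
  expect_true(all(zf$samples[1025:2048] == 0))
  expect_equal(sum(Mod(zf$samples)^2), sum(Mod(fid$samples)^2))
  expect_identical(zero_fill(fid, target = 1024L)$samples, fid$samples)
  expect_error(zero_fill(fid, target = 512L), "smaller")
})

test_that("the Fourier stage matches a brute-force DFT and Parseval", {
  for (n in c(16L, 64L, 256L)) {
    acq <- mrs_acq(n_points = n)
    set.seed(n)
    x <- complex(real = rnorm(n), imaginary = rnorm(n))
    spec <- to_spectrum(mrs_fid(x, acq))
    oracle <- hgmrs:::fftshift(dft_oracle(x))
    expect_lt(max(Mod(spec$values - oracle)) / max(Mod(oracle)), 1e-9)
    expect_equal(sum(Mod(spec$values)^2), n * sum(Mod(x)^2))
  }
  zero <- mrs_fid(complex(real = numeric(64)), mrs_acq(n_points = 64L))
  expect_true(all(to_spectrum(zero)$values == 0))
  expect_error(to_spectrum(to_spectrum(zero)), "time-domain")
})

test_that("eddy correction is phase-only and invertible by construction", {
  acq <- mrs_acq()
  fid <- simulate_fid(gm_truth(), acq, seed = 2)
  flat_water <- mrs_fid(rep(1 + 0i, acq$n_points), acq)
  expect_equal(eddy_correct(fid, flat_water)$samples, fid$samples)

  # distort with a known smooth phase function, correct with matching water
  t_ms <- time_axis_ms(fid)
  phi <- 0.4 * sin(2 * pi * t_ms / 300) + 0.2
  distorted <- mrs_fid(fid$samples * exp(1i * phi), acq)
  water <- mrs_fid(exp(1i * phi), acq)
  rec <- eddy_correct(distorted, water)
  expect_equal(rec$samples, fid$samples, tolerance = 1e-6)
  expect_equal(Mod(rec$samples), Mod(distorted$samples))

  short <- mrs_fid(fid$samples[1:512], mrs_acq(n_points = 512L))
  expect_error(eddy_correct(fid, short), "equal length")
})

test_that("frequency alignment recovers an injected shift and flags noise", {
  acq <- mrs_acq()
  spec0 <- frequency_align(to_spectrum(zero_fill(apodize(
    simulate_fid(gm_truth(), acq, seed = 4)))))
  expect_lte(abs(attr(spec0, "shift_ppm_applied")), ppm_per_bin(spec0))
  expect_false(attr(spec0, "alignment_failed"))

  shifted <- to_spectrum(zero_fill(apodize(
    simulate_fid(gm_truth(shift_ppm = 0.05), acq, seed = 4))))
  al <- frequency_align(shifted)
  expect_lt(abs(attr(al, "shift_ppm_applied") - (-0.05)),
            1.5 * ppm_per_bin(shifted))

  set.seed(99)
  noise <- mrs_fid(complex(real = rnorm(1024, 0, 1),
                           imaginary = rnorm(1024, 0, 1)), acq)
  fl <- frequency_align(to_spectrum(noise))
  expect_true(attr(fl, "alignment_failed"))
  expect_equal(fl$values, to_spectrum(noise)$values)
})

test_that("baseline correction recovers an injected degree-6 polynomial", {
  coef <- c(5, -3, 2, 8, -6, 1.5, 4)
  poly_fn <- function(ppm) {
    x <- (ppm - 4.7) / 8
    drop(outer(x, 0:6, `^`) %*% coef)
  }
  spec <- spectrum_from_fn(poly_fn)
  bc <- baseline_correct(spec)
  expect_lt(sqrt(mean(Re(bc$values)^2)), 1e-8 * max(abs(poly_fn(spec$ppm))))
  expect_equal(attr(bc, "baseline_degree"), 6L)

  flat <- spectrum_from_fn(function(ppm) rep(0, length(ppm)))
  expect_lt(max(abs(Re(baseline_correct(flat)$values))), 1e-10)

  # an axis living entirely inside the metabolite windows has no support
  narrow <- mrs_spectrum(rep(1 + 0i, 32), seq(1.9, 2.1, length.out = 32),
                         mrs_acq(n_points = 32L))
  expect_error(baseline_correct(narrow), "14 baseline points")
})

test_that("phase correction recovers a known rotation and preserves magnitude", {
  acq <- mrs_acq()
  base <- baseline_correct(frequency_align(to_spectrum(zero_fill(apodize(
    simulate_fid(gm_truth(), acq, seed = 6))))))
  ref <- phase_correct(base)
  expect_lt(abs(attr(ref, "phase_applied_deg")), 0.5)

  rot <- base
  rot$values <- base$values * exp(1i * 37 * pi / 180)
  rec <- phase_correct(rot)
  expect_equal(attr(rec, "phase_applied_deg"), 37,
               tolerance = 0.5, ignore_attr = TRUE)
  expect_equal(rec$values, ref$values,
               tolerance = 1e-6 * max(Mod(ref$values)))
  expect_equal(Mod(rec$values), Mod(rot$values))
})

test_that("the full chain runs in the documented order", {
  acq <- mrs_acq()
  fid <- simulate_fid(gm_truth(phase0_deg = 10, shift_ppm = 0.02,
                               noise_sd = 0.05), acq, seed = 12)
  water <- simulate_water_reference(acq, seed = 13, phase0_deg = 10,
                                    shift_ppm = 0.02)
  spec <- process(fid, water_fid = water)
  expect_identical(spec$provenance,
                   c("eddy_correct", "apodize", "zero_fill", "fft",
                     "frequency_align", "baseline_correct", "phase_correct"))
  spec2 <- process(fid)
  expect_identical(spec2$provenance,
                   c("apodize", "zero_fill", "fft", "frequency_align",
                     "baseline_correct", "phase_correct"))

  zero <- mrs_fid(complex(real = numeric(1024)), acq)
  zspec <- process(zero)
  expect_true(all(zspec$values == 0))
  expect_true(attr(zspec, "alignment_failed"))
})
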