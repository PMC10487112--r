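# Shared fixtures: everything is generated in code, nothing is stored.

# Gray-matter voxel truth with a chosen 2-HG load.
gm_truth <- function(hg = 0, noise_sd = 0, ...) {
  conc <- default_concentrations("gray")
  conc[["2HG"]] <- hg
  voxel_truth(conc, noise_sd = noise_sd, ...)
}

# Brute-force O(N^2) discrete Fourier transform, the independent oracle for
# the FFT stage (same sign convention as stats::fft: forward, unscaled).
dft_oracle <- function(x) {
  n <- length(x)
  idx <- 0:(n - 1)
  vapply(idx, function(k) sum(x * exp(-2i * pi * k * idx / n)),
         complex(1))
}

# Spectrum built directly on a given acquisition's ppm axis from a function
# of ppm; bypasses the simulator so frequency-domain stages can be tested
# in isolation.
spectrum_from_fn <- function(fn, acq = mrs_acq(n_points = 2048L),
                             provenance = c("apodize", "zero_fill", "fft")) {
  ppm <- hgmrs:::ppm_axis(acq$n_points, acq)
  mrs_spectrum(as.complex(fn(ppm)), ppm, acq, provenance = provenance)
}

# Minimal fitted panel with a prescribed Glx3/Glx4 area ratio, for testing
# the quantification arithmetic without running fits.
fake_panel <- function(ratio, converged = TRUE, glx4_area = 1) {
  df <- data.frame(
    voxel = NA, window = c("Glx3", "Glx4"),
    amplitude = c(ratio * glx4_area, glx4_area) / (0.02 * sqrt(2 * pi)),
    center_ppm = c(2.29, 2.35), sigma_ppm = 0.02,
    area = c(ratio * glx4_area, glx4_area), rss = 0,
    converged = converged, at_bound = FALSE, stringsAsFactors = FALSE)
  structure(df, all_converged = all(converged),
            class = c("mrs_panel", "data.frame"))
}
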