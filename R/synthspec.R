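# Simulator calibration constants. The Glx3:Glx4 effective-signal ratio in
# healthy tissue is fixed at 0.81 (between-voxel SD 0.06), and the 2-HG
# resonance carries the same effective signal factor as the Glx3 component so
# that the injected percentage elevation equals 100 * [2-HG] / ([Glu]+[Gln]).
HEALTHY_GLX_RATIO <- 0.81
HEALTHY_GLX_RATIO_SD <- 0.06
GLX4_REL_SIGNAL <- 0.25

#' Resonance basis for the synthetic spectrum simulator
#'
#' Returns one Gaussian resonance group per fitted chemical-shift window:
#' NAA (2.008 ppm), creatine Cr1 (3.03) and Cr2 (3.91), choline (3.19),
#' myo-inositol Ins1 (3.55) and Ins2 (3.64), the combined glutamate +
#' glutamine C3 signal Glx3 (2.29), the C4 signal Glx4 (2.35), and
#' 2-hydroxyglutarate (2.25). Each centre lies strictly inside its fitting
#' window (see [default_windows()]). Effective signal factors (`rel_signal`)
#' absorb proton counts and relaxation weighting; they are set so that, at
#' zero 2-HG, the simulated Glx3/Glx4 area ratio equals the healthy-tissue
#' reference 0.81. J-coupling multiplets are not modelled: each group is a
#' single Gaussian, mirroring the one-Gaussian-per-window quantification.
#'
#' The resonance positions and signal factors do not depend on tissue type;
#' the argument selects which default concentration set
#' ([default_concentrations()]) the basis is intended to pair with and is
#' validated here.
#'
#' @param tissue `"gray"` or `"white"`.
#' @return data frame with columns `metabolite`, `window`, `center_ppm`,
#'   `rel_signal`, `linewidth_hz`, `lineshape`.
#' @export
#' @examples
#' b <- build_basis("gray")
#' subset(b, window %in% c("Glx3", "Glx4", "2HG"))
build_basis <- function(tissue = c("gray", "white")) {
  tissue <- match.arg(tissue)
  k4 <- GLX4_REL_SIGNAL
  k3 <- HEALTHY_GLX_RATIO * k4
  basis <- data.frame(
    metabolite = c("NAA", "Cr", "Cr", "Cho", "Ins", "Ins", "Glx", "Glx", "2HG"),
    window     = c("NAA", "Cr1", "Cr2", "Cho", "Ins1", "Ins2",
                   "Glx3", "Glx4", "2HG"),
    center_ppm = c(2.008, 3.03, 3.91, 3.19, 3.55, 3.64, 2.29, 2.35, 2.25),
    rel_signal = c(1.00, 0.60, 0.40, 2.40, 0.45, 0.35, k3, k4, k3),
    linewidth_hz = 6,
    lineshape  = "gaussian",
    stringsAsFactors = FALSE
  )
  stopifnot(all(basis$center_ppm > 0 & basis$center_ppm < 5),
            all(basis$rel_signal >= 0), all(basis$linewidth_hz > 0))
  basis
}

#' Default metabolite concentrations (mmoles/kg)
#'
#' Literature-typical in vivo concentrations. Glutamate/glutamine are 11.7
#' and 3.2 mmoles/kg in gray matter and 7.1 and 1.7 in white matter; the
#' remaining metabolites use canonical in vivo values. 2-HG defaults to 0
#' (healthy / IDH-wild-type tissue).
#'
#' @param tissue `"gray"` or `"white"`.
#' @return named numeric vector over NAA, Cr, Cho, Ins, Glu, Gln, 2HG.
#' @export
default_concentrations <- function(tissue = c("gray", "white")) {
  tissue <- match.arg(tissue)
  if (tissue == "gray") {
    c(NAA = 12.0, Cr = 8.0, Cho = 1.8, Ins = 6.0,
      Glu = 11.7, Gln = 3.2, "2HG" = 0)
  } else {
    c(NAA = 10.0, Cr = 7.0, Cho = 2.0, Ins = 5.5,
      Glu = 7.1, Gln = 1.7, "2HG" = 0)
  }
}

#' Ground-truth description of one simulated voxel
#'
#' @param concentrations named non-negative numeric vector with entries
#'   NAA, Cr, Cho, Ins, Glu, Gln, 2HG (mmoles/kg).
#' @param noise_sd standard deviation of the additive complex Gaussian
#'   time-domain noise (per real/imaginary channel).
#' @param baseline_coeffs exactly 7 coefficients of a degree-6 polynomial
#'   broad-background component, expressed in the scaled variable
#'   `(ppm - ref_ppm) / 8` (so the axis maps roughly to \[-1, 1\]).
#' @param phase0_deg zero-order phase error applied to the FID, degrees.
#' @param shift_ppm global frequency shift applied to every resonance, ppm.
#' @param glx3_scale multiplier on the Glx3 effective signal; a voxel whose
#'   intrinsic healthy Glx3/Glx4 ratio is `r` has `glx3_scale = r / 0.81`.
#' @param label `"tumor"`, `"contralateral"` or `"excluded"`.
#' @return an object of class `voxel_truth`.
#' @export
voxel_truth <- function(concentrations = default_concentrations("gray"),
                        noise_sd = 0, baseline_coeffs = rep(0, 7),
                        phase0_deg = 0, shift_ppm = 0, glx3_scale = 1,
                        label = c("contralateral", "tumor", "excluded")) {
  label <- match.arg(label)
  need <- c("NAA", "Cr", "Cho", "Ins", "Glu", "Gln", "2HG")
  if (!all(need %in% names(concentrations)))
    stop("concentrations must be named over: ", paste(need, collapse = ", "))
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  if (length(baseline_coeffs) != 7)
    stop("baseline_coeffs must have exactly 7 entries (degree 6)")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  structure(
    list(concentrations = concentrations[need], noise_sd = noise_sd,
         baseline_coeffs = baseline_coeffs, phase0_deg = phase0_deg,
         shift_ppm = shift_ppm, glx3_scale = glx3_scale, label = label),
    class = "voxel_truth"
  )
}

# Gaussian decay rate (1/s) giving the requested frequency-domain FWHM (Hz):
# exp(-(a t)^2) transforms to exp(-(pi f / a)^2), FWHM = 2 a sqrt(ln 2) / pi.
gauss_decay_rate <- function(fwhm_hz) pi * fwhm_hz / (2 * sqrt(log(2)))

#' Simulate a free-induction decay for one voxel
#'
#' Forward model: the FID is the sum over basis resonances of
#' `amp * exp(2i pi f t) * exp(-(a t)^2)` with `amp = concentration *
#' rel_signal`, `f` the resonance offset from the carrier and `a` the
#' Gaussian decay rate matching the resonance linewidth; a zero-order phase
#' `exp(i phase0)` and global frequency shift are applied, a smooth
#' polynomial background (inverse transform of the `baseline_coeffs`
#' polynomial on the ppm axis) is added, and finally complex white Gaussian
#' noise of standard deviation `noise_sd`. The FID is linear in the
#' concentrations at zero noise, and identical seeds give identical output.
#'
#' @param truth a [voxel_truth()].
#' @param acq an [mrs_acq()].
#' @param seed integer RNG seed (required; used even when `noise_sd = 0`
#'   so downstream code never depends on ambient RNG state).
#' @param basis resonance table from [build_basis()].
#' @return an [mrs_fid()].
#' @export
#' @examples
#' fid <- simulate_fid(voxel_truth(), mrs_acq(), seed = 1)
simulate_fid <- function(truth, acq = mrs_acq(), seed,
                         basis = build_basis("gray")) {
  if (missing(seed)) stop("seed is required")
  if (!inherits(truth, "voxel_truth")) stop("truth must be a voxel_truth")
  set.seed(as.integer(seed))
  conc <- truth$concentrations
  eff <- c(conc, Glx = unname(conc["Glu"] + conc["Gln"]))
  t_s <- (seq_len(acq$n_points) - 1) * acq$dwell_ms / 1000
  sig <- complex(real = numeric(acq$n_points))
  for (i in seq_len(nrow(basis))) {
    amp <- eff[[basis$metabolite[i]]] * basis$rel_signal[i]
    if (basis$window[i] == "Glx3") amp <- amp * truth$glx3_scale
    if (amp == 0) next
    f_hz <- (basis$center_ppm[i] + truth$shift_ppm - acq$ref_ppm) * acq$f0_mhz
    a <- gauss_decay_rate(basis$linewidth_hz[i])
    sig <- sig + amp * exp(2i * pi * f_hz * t_s) * exp(-(a * t_s)^2)
  }
  sig <- sig * exp(1i * truth$phase0_deg * pi / 180)
  if (any(truth$baseline_coeffs != 0)) {
    ppm <- ppm_axis(acq$n_points, acq)
    x <- (ppm - acq$ref_ppm) / 8
    bl <- as.complex(drop(outer(x, 0:6, `^`) %*% truth$baseline_coeffs))
    sig <- sig + stats::fft(ifftshift(bl), inverse = TRUE) / acq$n_points
  }
  if (truth$noise_sd > 0) {
    sig <- sig + complex(real = stats::rnorm(acq$n_points, 0, truth$noise_sd),
                         imaginary = stats::rnorm(acq$n_points, 0, truth$noise_sd))
  }
  mrs_fid(sig, acq)
}

#' Simulate the unsuppressed water reference FID
#'
#' A single resonance at the water chemical shift (the carrier, 4.7 ppm)
#' with the acquisition's shim-limited linewidth, carrying the same
#' zero-order phase and frequency-shift distortions as the matching
#' metabolite FID so that [eddy_correct()] can remove them.
#'
#' @param acq an [mrs_acq()].
#' @param seed integer RNG seed.
#' @param phase0_deg,shift_ppm distortions shared with the metabolite FID.
#' @param noise_sd time-domain complex noise SD.
#' @param amplitude water signal amplitude (arbitrary units).
#' @param linewidth_hz water linewidth; 12 Hz is a typical shimmed in vivo
#'   value.
#' @return an [mrs_fid()].
#' @export
simulate_water_reference <- function(acq = mrs_acq(), seed, phase0_deg = 0,
                                     shift_ppm = 0, noise_sd = 0,
                                     amplitude = 50, linewidth_hz = 12) {
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  t_s <- (seq_len(acq$n_points) - 1) * acq$dwell_ms / 1000
  f_hz <- (4.7 + shift_ppm - acq$ref_ppm) * acq$f0_mhz
  a <- gauss_decay_rate(linewidth_hz)
  sig <- amplitude * exp(2i * pi * f_hz * t_s) * exp(-(a * t_s)^2)
  sig <- sig * exp(1i * phase0_deg * pi / 180)
  if (noise_sd > 0) {
    sig <- sig + complex(real = stats::rnorm(acq$n_points, 0, noise_sd),
                         imaginary = stats::rnorm(acq$n_points, 0, noise_sd))
  }
  mrs_fid(sig, acq)
}

# Normal(mean, sd) truncated to (0, Inf) by rejection.
rtruncnorm_pos <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out <= 0)) out[bad] <- stats::rnorm(sum(bad), mean, sd)
  out
}

#' Simulate a patient cohort with known 2-HG ground truth
#'
#' For each patient a true 2-HG concentration is drawn uniformly from
#' `hg_range` and placed in a tumor voxel; the true percentage elevation is
#' `100 * [2-HG] / ([Glu] + [Gln])` exactly. The paired contralateral voxel
#' has no 2-HG and an intrinsic Glx3/Glx4 ratio drawn from
#' Normal(0.81, 0.06) truncated positive, emulating the between-voxel
#' spread of the healthy reference ratio.
#'
#' @param n_patients number of patients (>= 2).
#' @param hg_range range (mmoles/kg) for the uniform true 2-HG draw; the
#'   default 0-8 spans the concentrations observed ex vivo in lower-grade
#'   glioma.
#' @param tissue `"gray"` or `"white"`: selects the Glu/Gln pool.
#' @param noise_sd time-domain noise SD for every simulated FID.
#' @param seed integer RNG seed; per-voxel sub-seeds are derived from it.
#' @param acq an [mrs_acq()].
#' @return an object of class `mrs_cohort`: a list with `truth` (data frame
#'   with columns patient, hg_true, glu, gln, elevation_true,
#'   ref_ratio_true, noise_sd, seed_tumor, seed_contra) and `fids` (a list
#'   of `list(tumor =, contralateral =)` [mrs_fid()] pairs).
#' @export
simulate_cohort <- function(n_patients, hg_range = c(0, 8),
                            tissue = c("gray", "white"), noise_sd = 0.4,
                            seed, acq = mrs_acq()) {
  tissue <- match.arg(tissue)
  if (n_patients < 2) stop("n_patients must be >= 2")
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  hg <- stats::runif(n_patients, hg_range[1], hg_range[2])
  rc <- rtruncnorm_pos(n_patients, HEALTHY_GLX_RATIO, HEALTHY_GLX_RATIO_SD)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_patients)
  conc0 <- default_concentrations(tissue)
  glx_pool <- unname(conc0["Glu"] + conc0["Gln"])
  basis <- build_basis(tissue)
  truth <- data.frame(
    patient = seq_len(n_patients),
    hg_true = hg, glu = conc0[["Glu"]], gln = conc0[["Gln"]],
    elevation_true = 100 * hg / glx_pool,
    ref_ratio_true = rc, noise_sd = noise_sd,
    seed_tumor = sub_seeds[seq_len(n_patients)],
    seed_contra = sub_seeds[n_patients + seq_len(n_patients)]
  )
  fids <- lapply(seq_len(n_patients), function(i) {
    ct <- conc0; ct[["2HG"]] <- hg[i]
    tum <- voxel_truth(ct, noise_sd = noise_sd, label = "tumor")
    ref <- voxel_truth(conc0, noise_sd = noise_sd,
                       glx3_scale = rc[i] / HEALTHY_GLX_RATIO,
                       label = "contralateral")
    list(tumor = simulate_fid(tum, acq, seed = truth$seed_tumor[i],
                              basis = basis),
         contralateral = simulate_fid(ref, acq, seed = truth$seed_contra[i],
                                      basis = basis))
  })
  structure(list(truth = truth, fids = fids, tissue = tissue, seed = seed),
            class = "mrs_cohort")
}

#' Lay out a chemical-shift-imaging voxel grid
#'
#' Returns the bookkeeping for a multivoxel CSI measurement: a 16 x 16 grid
#' of 10 x 10 x 20 mm voxels by default, with a tumor block on one side,
#' its mirror-image contralateral block on the other, and the remainder
#' excluded (outside the volume of interest).
#'
#' @param nx,ny grid dimensions.
#' @param voxel_size_mm three spatial extents in mm.
#' @param tumor_cols columns (1-based) labelled tumor; their mirror columns
#'   are labelled contralateral.
#' @param tumor_rows rows labelled tumor/contralateral.
#' @return data frame with columns `ix`, `iy`, `label`, plus attributes
#'   `voxel_size_mm` and dimensions; class `csi_grid`.
#' @export
csi_grid <- function(nx = 16, ny = 16, voxel_size_mm = c(10, 10, 20),
                     tumor_cols = 3:5, tumor_rows = 7:10) {
  if (length(voxel_size_mm) != 3) stop("voxel_size_mm must have 3 extents")
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  g$label <- "excluded"
  g$label[g$ix %in% tumor_cols & g$iy %in% tumor_rows] <- "tumor"
  mirror <- nx + 1 - tumor_cols
  g$label[g$ix %in% mirror & g$iy %in% tumor_rows] <- "contralateral"
  structure(g, voxel_size_mm = voxel_size_mm, nx = nx, ny = ny,
            class = c("csi_grid", "data.frame"))
}

#' Fitted Glx3/Glx4 ratios over simulated healthy voxels
#'
#' Calibration run for the contralateral reference: simulates `n_voxels`
#' healthy voxels whose intrinsic Glx3/Glx4 ratio is drawn from
#' Normal(0.81, 0.06) truncated positive, pushes each through the full
#' processing chain and the joint Glx-pair fit, and returns the injected
#' and recovered ratios. Over many voxels the fitted ratios should average
#' 0.81 with SD 0.06.
#'
#' @param n_voxels number of voxels to simulate.
#' @param noise_sd time-domain noise SD per voxel.
#' @param seed integer RNG seed.
#' @param acq an [mrs_acq()].
#' @param tissue `"gray"` or `"white"`.
#' @return data frame with columns `true_ratio`, `fitted_ratio`.
#' @export
simulate_healthy_ratios <- function(n_voxels = 500, noise_sd = 0.05, seed,
                                    acq = mrs_acq(),
                                    tissue = c("gray", "white")) {
  tissue <- match.arg(tissue)
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  r_true <- rtruncnorm_pos(n_voxels, HEALTHY_GLX_RATIO, HEALTHY_GLX_RATIO_SD)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_voxels)
  conc <- default_concentrations(tissue)
  basis <- build_basis(tissue)
  fitted <- vapply(seq_len(n_voxels), function(i) {
    vt <- voxel_truth(conc, noise_sd = noise_sd,
                      glx3_scale = r_true[i] / HEALTHY_GLX_RATIO)
    spec <- process(simulate_fid(vt, acq, seed = sub_seeds[i], basis = basis))
    pair <- fit_glx_pair(spec)
    pair$glx3$area / pair$glx4$area
  }, numeric(1))
  data.frame(true_ratio = r_true, fitted_ratio = fitted)
}
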