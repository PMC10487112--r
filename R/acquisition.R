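#' Acquisition parameters for a PRESS spectroscopy measurement
#'
#' Bundles the timing and frequency metadata needed to interpret a raw
#' free-induction decay (FID): number of complex samples, dwell time,
#' spectrometer frequency, the ppm value of the carrier, and the sequence
#' timing. Defaults describe a 3 T 2D-CSI PRESS acquisition with
#' TR/TE = 1500/40 ms, 1024 complex points at a 0.5 ms dwell (2000 Hz
#' spectral width, 512 ms acquisition), carrier on water at 4.7 ppm.
#'
#' @param n_points number of complex time-domain samples (>= 2).
#' @param dwell_ms sampling interval in milliseconds (> 0).
#' @param f0_mhz proton spectrometer frequency in MHz (> 0); 123.25 at 3 T.
#' @param ref_ppm chemical shift (ppm) at the carrier frequency.
#' @param te_ms echo time in milliseconds.
#' @param tr_ms repetition time in milliseconds.
#' @return an object of class `mrs_acq`.
#' @export
#' @examples
#' acq <- mrs_acq()
#' sweep_width_hz(acq)
mrs_acq <- function(n_points = 1024L, dwell_ms = 0.5, f0_mhz = 123.25,
                    ref_ppm = 4.7, te_ms = 40, tr_ms = 1500) {
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L) stop("n_points must be >= 2")
  if (!is.finite(dwell_ms) || dwell_ms <= 0) stop("dwell_ms must be > 0")
  if (!is.finite(f0_mhz) || f0_mhz <= 0) stop("f0_mhz must be > 0")
  structure(
    list(n_points = n_points, dwell_ms = dwell_ms, f0_mhz = f0_mhz,
         ref_ppm = ref_ppm, te_ms = te_ms, tr_ms = tr_ms),
    class = "mrs_acq"
  )
}

#' @export
print.mrs_acq <- function(x, ...) {
  cat(sprintf(
    "<mrs_acq> %d pts, dwell %.4g ms (SW %.4g Hz), f0 %.4g MHz, ref %.3g ppm, TR/TE %g/%g ms\n",
    x$n_points, x$dwell_ms, sweep_width_hz(x), x$f0_mhz, x$ref_ppm,
    x$tr_ms, x$te_ms))
  invisible(x)
}

#' Spectral width in Hz implied by the dwell time
#' @param acq an `mrs_acq`.
#' @return sweep width in Hz (1 / dwell).
#' @export
sweep_width_hz <- function(acq) 1000 / acq$dwell_ms

#' Free-induction decay container
#'
#' A complex time-domain MR signal together with its acquisition metadata.
#' The sample count must equal `acq$n_points`; [zero_fill()] updates both.
#'
#' @param samples complex vector of time-domain samples.
#' @param acq an [mrs_acq()] whose `n_points` equals `length(samples)`.
#' @return an object of class `mrs_fid`.
#' @export
mrs_fid <- function(samples, acq) {
  samples <- as.complex(samples)
  if (!inherits(acq, "mrs_acq")) stop("acq must be an mrs_acq object")
  if (length(samples) != acq$n_points)
    stop("length(samples) must equal acq$n_points")
  structure(list(samples = samples, acq = acq), class = "mrs_fid")
}

#' @export
print.mrs_fid <- function(x, ...) {
  cat(sprintf("<mrs_fid> %d complex samples, dwell %.4g ms\n",
              length(x$samples), x$acq$dwell_ms))
  invisible(x)
}

#' @export
length.mrs_fid <- function(x) length(x$samples)

#' Time axis of an FID in milliseconds
#' @param fid an `mrs_fid`.
#' @return numeric vector, `t = (0, dwell, 2*dwell, ...)` ms.
#' @export
time_axis_ms <- function(fid) {
  (seq_len(length(fid$samples)) - 1) * fid$acq$dwell_ms
}

#' Frequency-domain spectrum container
#'
#' Complex spectral values on a strictly monotone (ascending) ppm axis,
#' plus a provenance record of the processing steps that produced it.
#' Chemical shift increases downfield; plotting routines reverse the axis
#' for display, storage is ascending.
#'
#' @param values complex spectral values.
#' @param ppm numeric ppm axis, strictly increasing, same length as `values`.
#' @param acq the originating [mrs_acq()].
#' @param provenance character vector of applied processing step names.
#' @return an object of class `mrs_spectrum`.
#' @export
mrs_spectrum <- function(values, ppm, acq, provenance = character()) {
  values <- as.complex(values)
  if (length(values) != length(ppm))
    stop("values and ppm must have equal length")
  if (any(diff(ppm) <= 0)) stop("ppm axis must be strictly increasing")
  structure(
    list(values = values, ppm = ppm, acq = acq,
         provenance = as.character(provenance)),
    class = "mrs_spectrum"
  )
}

#' @export
print.mrs_spectrum <- function(x, ...) {
  cat(sprintf("<mrs_spectrum> %d points, %.2f..%.2f ppm\n",
              length(x$values), min(x$ppm), max(x$ppm)))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
length.mrs_spectrum <- function(x) length(x$values)

#' ppm spacing of a spectrum
#' @param spec an `mrs_spectrum`.
#' @return ppm per frequency bin.
#' @export
ppm_per_bin <- function(spec) spec$ppm[2] - spec$ppm[1]

# Swap halves so DC moves to the centre (even or odd N).
fftshift <- function(x) {
  n <- length(x)
  h <- floor(n / 2)
  c(x[(h + 1):n], x[1:h])
}

ifftshift <- function(x) {
  n <- length(x)
  h <- ceiling(n / 2)
  c(x[(h + 1):n], x[1:h])
}

# ppm axis for an N-point spectrum after fftshift: bin j holds frequency
# (j - 1 - floor(N/2)) / (N * dwell) Hz relative to the carrier.
ppm_axis <- function(n, acq) {
  freq_hz <- (seq_len(n) - 1 - floor(n / 2)) / (n * acq$dwell_ms / 1000)
  acq$ref_ppm + freq_hz / acq$f0_mhz
}

#' Write an FID or spectrum to the CSV + JSON-sidecar interchange format
#'
#' The package's on-disk format is plain text: `<base>.csv` holds the
#' complex samples (`index,real,imag` for a time-domain FID;
#' `index,ppm,real,imag` for a spectrum) and `<base>.json` holds the
#' acquisition metadata `{n_points, dwell_ms, f0_mhz, ref_ppm, te_ms,
#' tr_ms, domain}` plus the provenance list for spectra.
#'
#' @param x an `mrs_fid` or `mrs_spectrum`.
#' @param base path without extension; `.csv` and `.json` are appended.
#' @param extra optional named list merged into the sidecar (e.g. seed,
#'   config hash).
#' @return `base`, invisibly.
#' @export
write_mrs <- function(x, base, extra = list()) {
  csv <- paste0(base, ".csv")
  json <- paste0(base, ".json")
  if (inherits(x, "mrs_fid")) {
    df <- data.frame(index = seq_along(x$samples) - 1L,
                     real = Re(x$samples), imag = Im(x$samples))
    meta <- c(unclass(x$acq), list(domain = "time"))
  } else if (inherits(x, "mrs_spectrum")) {
    df <- data.frame(index = seq_along(x$values) - 1L, ppm = x$ppm,
                     real = Re(x$values), imag = Im(x$values))
    meta <- c(unclass(x$acq),
              list(domain = "frequency", provenance = I(x$provenance)))
  } else stop("x must be an mrs_fid or mrs_spectrum")
  meta <- c(meta, extra)
  utils::write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA)
  invisible(base)
}

#' Read an FID or spectrum written by [write_mrs()]
#'
#' @param base path without extension.
#' @return an `mrs_fid` or `mrs_spectrum` according to the sidecar `domain`.
#' @export
read_mrs <- function(base) {
  csv <- paste0(base, ".csv")
  json <- paste0(base, ".json")
  if (!file.exists(csv)) stop("missing spectrum file: ", csv)
  if (!file.exists(json)) stop("missing sidecar file: ", json)
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  df <- utils::read.csv(csv)
  need <- c("n_points", "dwell_ms", "f0_mhz", "ref_ppm", "domain")
  if (!all(need %in% names(meta)))
    stop("malformed sidecar (missing keys) in: ", json)
  acq <- mrs_acq(n_points = nrow(df), dwell_ms = meta$dwell_ms,
                 f0_mhz = meta$f0_mhz, ref_ppm = meta$ref_ppm,
                 te_ms = meta$te_ms %||% 40, tr_ms = meta$tr_ms %||% 1500)
  vals <- complex(real = df$real, imaginary = df$imag)
  if (identical(meta$domain, "time")) {
    mrs_fid(vals, acq)
  } else if (identical(meta$domain, "frequency")) {
    mrs_spectrum(vals, df$ppm, acq,
                 provenance = as.character(meta$provenance %||% character()))
  } else stop("malformed sidecar (unknown domain) in: ", json)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
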