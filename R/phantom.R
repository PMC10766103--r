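#' Parameters for the nonlinear RF phantom
#'
#' Describes one simulated acquisition: a sparse point-scatterer medium imaged
#' by a Gaussian pulse, followed by a memoryless quadratic distortion that
#' injects second-harmonic (phase-coupled) energy, and additive white noise.
#' The quadratic term is what gives the two tissue classes distinguishable
#' bispectral band energies downstream.
#'
#' @param f0_norm Pulse center frequency as a fraction of the sampling rate.
#'   The default 0.125 mimics a 5 MHz probe sampled at 40 MHz and keeps the
#'   second harmonic (2 f0) well inside Nyquist.
#' @param rel_bandwidth Fractional -6 dB two-sided bandwidth of the pulse.
#' @param beta Quadratic nonlinearity coefficient in y = s + beta * s^2
#'   (dimensionless, applied to the unit-power scatterer signal).
#' @param scatterer_rate Expected number of scatterers per 256 axial samples.
#' @param snr_db Additive white Gaussian noise level in dB relative to a unit
#'   reference signal power; `Inf` disables noise.
#' @param n_samples Axial samples per scanline.
#' @param n_lines Number of scanlines.
#' @param label Optional class tag, `"benign"` or `"malignant"`.
#' @return An object of class `phantom_params`.
#' @seealso [simulate_frame()], [phantom_preset()]
#' @export
phantom_params <- function(f0_norm = 0.125, rel_bandwidth = 0.6, beta = 0,
                           scatterer_rate = 8, snr_db = 20,
                           n_samples = 2048, n_lines = 128, label = NULL) {
  if (!is.numeric(f0_norm) || f0_norm <= 0 || f0_norm >= 0.25)
    stop("f0_norm must lie in (0, 0.25)", call. = FALSE)
  if (!is.numeric(rel_bandwidth) || rel_bandwidth <= 0)
    stop("rel_bandwidth must be positive", call. = FALSE)
  if (!is.numeric(beta) || beta < 0)
    stop("beta must be >= 0", call. = FALSE)
  if (!is.numeric(scatterer_rate) || scatterer_rate < 0)
    stop("scatterer_rate must be >= 0", call. = FALSE)
  if (!is.numeric(n_samples) || n_samples < 256)
    stop("n_samples must be >= 256", call. = FALSE)
  if (!is.numeric(n_lines) || n_lines < 1)
    stop("n_lines must be >= 1", call. = FALSE)
  if (!is.null(label)) label <- match.arg(label, c("benign", "malignant"))
  structure(list(f0_norm = f0_norm, rel_bandwidth = rel_bandwidth,
                 beta = beta, scatterer_rate = scatterer_rate,
                 snr_db = snr_db, n_samples = as.integer(n_samples),
                 n_lines = as.integer(n_lines), label = label),
            class = "phantom_params")
}

#' Built-in phantom class presets
#'
#' Two fixed parameter sets emulating a benign-like medium (weak nonlinearity,
#' sparse scatterers) and a malignant-like medium (strong nonlinearity, dense
#' scatterers). The malignant preset produces systematically larger
#' high-frequency bispectral band energy (BS_S3), which is the class signal
#' every end-to-end experiment in this package relies on.
#'
#' @param class Either `"benign"` or `"malignant"`.
#' @param ... Overrides passed on to [phantom_params()] (e.g. `n_samples`).
#' @return A `phantom_params` object with `beta = 0.05, scatterer_rate = 4`
#'   (benign) or `beta = 0.3, scatterer_rate = 12` (malignant).
#' @export
phantom_preset <- function(class = c("benign", "malignant"), ...) {
  class <- match.arg(class)
  defaults <- switch(class,
    benign    = list(beta = 0.05, scatterer_rate = 4),
    malignant = list(beta = 0.30, scatterer_rate = 12))
  args <- utils::modifyList(c(defaults, list(label = class)), list(...))
  do.call(phantom_params, args)
}

#' Gaussian-modulated acoustic pulse kernel
#'
#' Builds the transmit/receive pulse used by the phantom: a cosine at
#' `f0_norm` under a Gaussian envelope whose spectral -6 dB width equals
#' `rel_bandwidth * f0_norm`. The envelope has unit peak and is even-symmetric
#' about the kernel center.
#'
#' @param f0_norm Center frequency in cycles/sample, in (0, 0.25).
#' @param rel_bandwidth Fractional -6 dB bandwidth (> 0).
#' @param length Odd kernel length in samples.
#' @return Numeric vector of length `length`.
#' @export
make_pulse <- function(f0_norm = 0.125, rel_bandwidth = 0.6, length = 65) {
  if (rel_bandwidth <= 0) stop("rel_bandwidth must be positive", call. = FALSE)
  if (f0_norm <= 0 || f0_norm >= 0.25)
    stop("f0_norm must lie in (0, 0.25)", call. = FALSE)
  if (length %% 2 == 0) stop("length must be odd", call. = FALSE)
  # -6 dB (half-amplitude) full width of a Gaussian amplitude spectrum
  # exp(-(f - f0)^2 / (2 sf^2)) is 2 sf sqrt(2 log 2).
  sf <- rel_bandwidth * f0_norm / (2 * sqrt(2 * log(2)))
  st <- 1 / (2 * pi * sf)
  t <- seq.int(-(length - 1) / 2, (length - 1) / 2)
  env <- exp(-t^2 / (2 * st^2))
  env * cos(2 * pi * f0_norm * t)
}

#' Ultrasound RF frame container
#'
#' A 2-D array of raw echo samples (axial x lateral) with acquisition
#' metadata. This is the unit every downstream stage consumes.
#'
#' @param samples Numeric matrix, axial samples x scanlines. Must be finite.
#' @param fs_hz Sampling frequency in Hz.
#' @param f0_hz Pulse center frequency in Hz.
#' @param frame_id Identifier string.
#' @param label Optional class tag.
#' @return An object of class `rf_frame`.
#' @export
rf_frame <- function(samples, fs_hz, f0_hz, frame_id = "frame", label = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!all(is.finite(samples))) stop("samples must be finite", call. = FALSE)
  if (!is.null(label)) label <- match.arg(label, c("benign", "malignant"))
  structure(list(samples = samples, fs_hz = fs_hz, f0_hz = f0_hz,
                 frame_id = as.character(frame_id), label = label),
            class = "rf_frame")
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("<rf_frame '%s'> %d samples x %d lines, fs = %.3g MHz, f0 = %.3g MHz%s\n",
              x$frame_id, nrow(x$samples), ncol(x$samples),
              x$fs_hz / 1e6, x$f0_hz / 1e6,
              if (is.null(x$label)) "" else paste0(", label = ", x$label)))
  invisible(x)
}

#' Simulate one RF frame
#'
#' Per scanline: a Poisson number of point scatterers at uniform axial
#' positions with zero-mean Gaussian amplitudes is convolved with the pulse;
#' the frame is scaled to unit mean power, distorted by the memoryless
#' quadratic y = s + beta s^2, and white Gaussian noise at `snr_db` (relative
#' to the unit reference power) is added. The function is a pure function of
#' `(params, seed)`.
#'
#' @param params A [phantom_params()] object.
#' @param seed Integer seed.
#' @param pulse_length Odd pulse kernel length (default 65).
#' @return An [rf_frame()] with `fs_hz = 40e6` and `f0_hz = f0_norm * fs_hz`.
#' @export
simulate_frame <- function(params, seed = 0, pulse_length = 65) {
  stopifnot(inherits(params, "phantom_params"))
  pulse <- make_pulse(params$f0_norm, params$rel_bandwidth, pulse_length)
  n <- params$n_samples
  m <- params$n_lines
  half <- (pulse_length - 1) / 2
  frame <- with_seed(seed, {
    s <- matrix(0, n, m)
    for (j in seq_len(m)) {
      count <- rpois(1, params$scatterer_rate * n / 256)
      tr <- numeric(n)
      if (count > 0) {
        pos <- sample.int(n, count, replace = TRUE)
        amp <- rnorm(count)
        add <- tapply(amp, pos, sum)
        tr[as.integer(names(add))] <- add
      }
      # centered linear convolution with the pulse
      full <- convolve(tr, rev(pulse), type = "open")
      s[, j] <- full[(half + 1):(half + n)]
    }
    pw <- mean(s^2)
    if (pw > 0) s <- s / sqrt(pw)
    y <- s + params$beta * s^2
    if (is.finite(params$snr_db)) {
      sd_noise <- sqrt(10^(-params$snr_db / 10))
      y <- y + matrix(rnorm(n * m, sd = sd_noise), n, m)
    }
    y
  })
  fs <- 40e6
  rf_frame(frame, fs_hz = fs, f0_hz = params$f0_norm * fs,
           frame_id = sprintf("sim_seed%d", seed), label = params$label)
}

# Deterministic per-frame seed derivation from a master seed. Documented
# scheme: seeds are (master * 1000003 + index) mod (2^31 - 1).
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 1000003 + index) %% 2147483647)
}

#' Simulate a labeled two-class RF dataset
#'
#' Writes `2 * n_per_class` RF container files (raw float32 + JSON sidecar,
#' see [write_rf_frame()]) and a CSV manifest with stratified
#' train/val/test1 splits. Per-frame seeds are derived deterministically from
#' the master seed, so the same call reproduces byte-identical files.
#'
#' @param n_per_class Frames per class (>= 1).
#' @param benign,malignant `phantom_params` for each class; defaults are the
#'   built-in presets.
#' @param seed Master seed.
#' @param out_dir Output directory (created if missing).
#' @param split_fracs Named fractions for the manifest `split` column,
#'   applied per class in order.
#' @return Invisibly, the manifest `data.frame` (frame_id, label, split) with
#'   an attribute `"paths"` giving the written frame files.
#' @export
simulate_dataset <- function(n_per_class,
                             benign = phantom_preset("benign"),
                             malignant = phantom_preset("malignant"),
                             seed = 0, out_dir,
                             split_fracs = c(train = 0.7, val = 0.15,
                                             test1 = 0.15)) {
  if (n_per_class < 1) stop("n_per_class must be >= 1", call. = FALSE)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  classes <- list(benign = benign, malignant = malignant)
  rows <- list(); paths <- character(0); idx <- 0
  for (cl in names(classes)) {
    p <- classes[[cl]]
    splits <- split_assign(n_per_class, split_fracs, derive_seed(seed, -1L))
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1
      fid <- sprintf("%s_%03d", cl, i)
      fr <- simulate_frame(p, seed = derive_seed(seed, idx))
      fr$frame_id <- fid
      fr$label <- cl
      path <- file.path(out_dir, paste0(fid, ".rf"))
      write_rf_frame(fr, path, force = TRUE)
      paths <- c(paths, path)
      rows[[idx]] <- data.frame(frame_id = fid, label = cl,
                                split = splits[i])
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"), force = TRUE)
  attr(manifest, "paths") <- paths
  invisible(manifest)
}

# Deterministic stratified split labels for n items (largest-remainder
# apportionment, then a seeded shuffle).
split_assign <- function(n, fracs, seed) {
  target <- fracs * n
  counts <- floor(target)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(target - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  lab <- rep(names(fracs), counts)
  with_seed(seed, sample(lab))
}
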