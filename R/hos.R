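#' Higher-order spectral analysis configuration
#'
#' Settings shared by the cumulant/bispectrum engine and the feature-map
#' builder.
#'
#' @param window Segment length in samples (default 256).
#' @param max_lag Maximum cumulant lag (default 63; must be < `window`).
#' @param nfft Bispectrum grid size (default 128; must be >= `2 * max_lag + 1`).
#' @param energy_mode `"power"` (sum of squared magnitudes, default) or
#'   `"magnitude"` (sum of magnitudes).
#' @param split_axis Which bifrequency axis is cut into the three equal bands:
#'   `"f1"` (horizontal, default) or `"f2"`.
#' @param demean Subtract the segment mean before cumulant estimation
#'   (default `TRUE`; disable only for unit testing against hand sums).
#' @param lag_window `"none"` (default) or `"parzen"` lag-domain taper.
#' @return An object of class `hos_config`.
#' @export
hos_config <- function(window = 256, max_lag = 63, nfft = 128,
                       energy_mode = c("power", "magnitude"),
                       split_axis = c("f1", "f2"), demean = TRUE,
                       lag_window = c("none", "parzen")) {
  energy_mode <- match.arg(energy_mode)
  split_axis <- match.arg(split_axis)
  lag_window <- match.arg(lag_window)
  if (max_lag >= window)
    stop("max_lag must be smaller than the segment window", call. = FALSE)
  if (nfft < 2 * max_lag + 1)
    stop("nfft must be >= 2 * max_lag + 1", call. = FALSE)
  structure(list(window = as.integer(window), max_lag = as.integer(max_lag),
                 nfft = as.integer(nfft), energy_mode = energy_mode,
                 split_axis = split_axis, demean = demean,
                 lag_window = lag_window),
            class = "hos_config")
}

#' Third-order cumulant lattice of an RF segment
#'
#' Estimates C3(k, l) = (1/N) sum_n x(n) x(n+k) x(n+l) over all n for which
#' the three indices fall inside the segment (biased estimate, 1/N
#' normalization), after subtracting the segment mean. The lattice is
#' symmetric under lag exchange, C3(k, l) = C3(l, k).
#'
#' @param x Numeric vector, the RF segment (length >= 8, finite).
#' @param max_lag Maximum lag; output covers lags `-max_lag..max_lag`.
#' @param demean Subtract the sample mean first (default `TRUE`).
#' @return An object of class `c3_lattice`: list with `values`
#'   (a `(2*max_lag+1)` square matrix, lag 0 at the center) and `max_lag`.
#' @export
estimate_c3 <- function(x, max_lag, demean = TRUE) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("segment must have length >= 2", call. = FALSE)
  if (!all(is.finite(x))) stop("segment must be finite", call. = FALSE)
  if (max_lag >= length(x))
    stop("max_lag must be smaller than the segment length", call. = FALSE)
  if (demean) x <- x - mean(x)
  vals <- c3_lattice_cpp(x, as.integer(max_lag))
  lags <- seq.int(-max_lag, max_lag)
  dimnames(vals) <- list(lags, lags)
  structure(list(values = vals, max_lag = as.integer(max_lag)),
            class = "c3_lattice")
}

# Parzen lag window on |k| <= L, evaluated at integer lags.
parzen_window <- function(L) {
  k <- abs(seq.int(-L, L)) / (L + 1)
  w <- ifelse(k <= 0.5, 1 - 6 * k^2 + 6 * k^3, 2 * (1 - k)^3)
  w
}

fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  i1 <- c((floor(n1 / 2) + 1):n1, 1:floor(n1 / 2))
  i2 <- c((floor(n2 / 2) + 1):n2, 1:floor(n2 / 2))
  m[i1, i2, drop = FALSE]
}

# Normalized frequency axis of an fftshifted nfft grid, in [-1/2, 1/2).
grid_freqs <- function(nfft) seq.int(-floor(nfft / 2), ceiling(nfft / 2) - 1) / nfft

#' Bispectrum by the indirect (cumulant Fourier) method
#'
#' Evaluates BS(f1, f2) = sum_k sum_l C3(k, l) exp(-j2\eqn{\pi} f1 k)
#' exp(-j2\eqn{\pi} f2 l) on an `nfft` x `nfft` grid via a zero-padded 2-D
#' FFT of the lag lattice. The result inherits the lag-exchange symmetry
#' BS(f1, f2) = BS(f2, f1).
#'
#' @param c3 A [estimate_c3()] result.
#' @param nfft Grid size, >= `2 * max_lag + 1`.
#' @param lag_window `"none"` or `"parzen"` taper applied to the lattice.
#' @return An object of class `bispectrum_grid`: complex `values`
#'   (rows = f1, columns = f2, both fftshifted to `[-1/2, 1/2)`), `freqs`,
#'   `nfft`.
#' @export
bispectrum_indirect <- function(c3, nfft, lag_window = "none") {
  stopifnot(inherits(c3, "c3_lattice"))
  L <- c3$max_lag
  if (nfft < 2 * L + 1)
    stop("nfft must be >= 2 * max_lag + 1", call. = FALSE)
  vals <- c3$values
  if (lag_window == "parzen") {
    w <- parzen_window(L)
    vals <- vals * outer(w, w)
  }
  padded <- matrix(0, nfft, nfft)
  idx <- (seq.int(-L, L) %% nfft) + 1  # lag k goes to row (k mod nfft) + 1
  padded[idx, idx] <- vals
  bs <- fftshift2(fft(padded))
  structure(list(values = bs, freqs = grid_freqs(nfft),
                 nfft = as.integer(nfft)),
            class = "bispectrum_grid")
}

#' Bispectrum by the direct (block FFT) method
#'
#' Classical direct estimator: the segment is cut into `n_blocks` contiguous
#' blocks, each demeaned and transformed, and
#' X(f1) X(f2) conj(X(f1 + f2)) is averaged over blocks. Serves as an
#' independent cross-check on quadratic-phase-coupling peak locations found
#' by the indirect path.
#'
#' @param x Numeric segment.
#' @param nfft Grid size; blocks are truncated/zero-padded to `nfft` samples.
#' @param n_blocks Number of blocks (>= 1).
#' @return A `bispectrum_grid` on the same fftshifted axes as
#'   [bispectrum_indirect()].
#' @export
bispectrum_direct <- function(x, nfft, n_blocks = 1) {
  x <- as.numeric(x)
  if (n_blocks < 1) stop("n_blocks must be >= 1", call. = FALSE)
  blen <- floor(length(x) / n_blocks)
  if (blen < 1) stop("segment too short for n_blocks", call. = FALSE)
  acc <- matrix(0 + 0i, nfft, nfft)
  sum_idx <- outer(seq_len(nfft) - 1, seq_len(nfft) - 1, `+`) %% nfft + 1
  for (b in seq_len(n_blocks)) {
    seg <- x[((b - 1) * blen + 1):(b * blen)]
    seg <- seg - mean(seg)
    buf <- numeric(nfft)
    buf[seq_len(min(blen, nfft))] <- seg[seq_len(min(blen, nfft))]
    X <- fft(buf)
    acc <- acc + outer(X, X) * Conj(X[sum_idx])
  }
  structure(list(values = fftshift2(acc / n_blocks), freqs = grid_freqs(nfft),
                 nfft = as.integer(nfft)),
            class = "bispectrum_grid")
}

#' Principal (non-redundant) domain of the bispectrum
#'
#' Builds the boolean mask of the standard non-overlapping triangle
#' S0 = \{0 <= f2 <= f1, f1 + f2 <= 1/2\} on the fftshifted grid. The twelve
#' symmetry regions of a real signal's bispectrum make this triangle carry
#' all the information.
#'
#' @param nfft Grid size (>= 4).
#' @return An object of class `region_masks` with `S0` filled and
#'   `S1`/`S2`/`S3` unset; see [subdivide_bands()].
#' @export
principal_domain <- function(nfft) {
  if (nfft < 4) stop("nfft must be >= 4", call. = FALSE)
  f <- grid_freqs(nfft)
  f1 <- matrix(f, nfft, nfft)          # rows index f1
  f2 <- matrix(f, nfft, nfft, byrow = TRUE)
  eps <- 1e-12
  S0 <- (f2 >= -eps) & (f2 <= f1 + eps) & (f1 + f2 <= 0.5 + eps)
  structure(list(S0 = S0, S1 = NULL, S2 = NULL, S3 = NULL,
                 freqs = f, nfft = as.integer(nfft),
                 band_edges = NULL, split_axis = NULL),
            class = "region_masks")
}

#' Subdivide the principal domain into frequency bands
#'
#' Cuts `[0, 1/2]` of the chosen axis into `n_bands` equal-width bands
#' A1..A3 and intersects each with S0: S1 = S0 & A1 is the low-frequency
#' non-overlapping region, S3 = S0 & A3 the high-frequency one. Bands are
#' half-open `[lo, hi)` except the last, closed at 1/2, so boundary bins are
#' assigned unambiguously and S1, S2, S3 partition S0 exactly.
#'
#' @param masks A [principal_domain()] result.
#' @param n_bands Number of bands; only 3 is supported.
#' @param split_axis `"f1"` (default, horizontal direction) or `"f2"`.
#' @return The `region_masks` object with `S1`, `S2`, `S3` and `band_edges`
#'   filled.
#' @export
subdivide_bands <- function(masks, n_bands = 3, split_axis = c("f1", "f2")) {
  stopifnot(inherits(masks, "region_masks"))
  split_axis <- match.arg(split_axis)
  if (n_bands != 3) stop("only n_bands = 3 is supported", call. = FALSE)
  nfft <- masks$nfft
  edges <- seq(0, 0.5, length.out = n_bands + 1)
  f <- masks$freqs
  coord <- if (split_axis == "f1") matrix(f, nfft, nfft)
           else matrix(f, nfft, nfft, byrow = TRUE)
  band <- matrix(findInterval(coord, edges, rightmost.closed = TRUE),
                 nfft, nfft)
  for (k in 1:3) masks[[paste0("S", k)]] <- masks$S0 & (band == k)
  masks$band_edges <- edges
  masks$split_axis <- split_axis
  masks
}

#' Energy of a bispectral region
#'
#' Sums `|BS(f1, f2)|^2` (or `|BS|` in magnitude mode) over the masked bins.
#'
#' @param grid A `bispectrum_grid`.
#' @param mask Logical matrix aligned with the grid.
#' @param energy_mode `"power"` or `"magnitude"`.
#' @return Nonnegative scalar.
#' @export
region_energy <- function(grid, mask, energy_mode = c("power", "magnitude")) {
  energy_mode <- match.arg(energy_mode)
  v <- if (inherits(grid, "bispectrum_grid")) grid$values else grid
  if (!identical(dim(v), dim(mask)))
    stop("mask shape does not match the bispectrum grid", call. = FALSE)
  a <- abs(v[mask])
  if (energy_mode == "power") sum(a^2) else sum(a)
}

# Region masks are a pure function of (nfft, split_axis); cache them so
# per-segment feature extraction does not rebuild the geometry.
.mask_cache <- new.env(parent = emptyenv())
get_region_masks <- function(nfft, split_axis) {
  key <- paste(nfft, split_axis, sep = "_")
  if (is.null(.mask_cache[[key]]))
    .mask_cache[[key]] <- subdivide_bands(principal_domain(nfft),
                                          split_axis = split_axis)
  .mask_cache[[key]]
}

#' Bispectral band-energy features of one RF segment
#'
#' Composes [estimate_c3()], [bispectrum_indirect()] and the region geometry
#' into the four energies E_S1 (low band), E_S2 (mid), E_S3 (high) and E_S0
#' (whole principal domain). Because S1, S2, S3 partition S0,
#' `E_S1 + E_S2 + E_S3 == E_S0` holds exactly.
#'
#' @param x Numeric segment of length >= `cfg$window`; the first
#'   `cfg$window` samples are used.
#' @param cfg A [hos_config()].
#' @return Named numeric vector `c(E_S1, E_S2, E_S3, E_S0)`.
#' @export
segment_features <- function(x, cfg = hos_config()) {
  stopifnot(inherits(cfg, "hos_config"))
  if (length(x) < cfg$window)
    stop("segment shorter than the configured window", call. = FALSE)
  x <- x[seq_len(cfg$window)]
  c3 <- estimate_c3(x, cfg$max_lag, demean = cfg$demean)
  grid <- bispectrum_indirect(c3, cfg$nfft, lag_window = cfg$lag_window)
  masks <- get_region_masks(cfg$nfft, cfg$split_axis)
  e <- vapply(paste0("S", 1:3), function(s)
    region_energy(grid, masks[[s]], cfg$energy_mode), numeric(1))
  c(E_S1 = unname(e[1]), E_S2 = unname(e[2]), E_S3 = unname(e[3]),
    E_S0 = unname(e[1]) + unname(e[2]) + unname(e[3]))
}
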