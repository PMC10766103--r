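#' Segment tiling geometry for feature maps
#'
#' How 1-D RF segments tile a frame: an axial sliding window of `window`
#' samples advanced by `hop`, one map column per scanline (every
#' `lateral_stride`-th line).
#'
#' @param window Samples per segment; must match the HOS window.
#' @param hop Axial stride in samples, `1 <= hop <= window` for gapless cover.
#' @param lateral_stride Lines per map column (default 1).
#' @return An object of class `map_geometry`.
#' @export
map_geometry <- function(window = 256, hop = 64, lateral_stride = 1) {
  if (hop < 1 || hop > window)
    stop("hop must lie in [1, window]", call. = FALSE)
  if (lateral_stride < 1) stop("lateral_stride must be >= 1", call. = FALSE)
  structure(list(window = as.integer(window), hop = as.integer(hop),
                 lateral_stride = as.integer(lateral_stride)),
            class = "map_geometry")
}

#' Build the four bispectral energy feature maps of a frame
#'
#' Runs [segment_features()] on every tiled segment of the frame and
#' assembles the per-frame maps BS_S1, BS_S2, BS_S3 (band energies) and BS_A
#' (whole principal domain). Row r, column c of each map is the energy of the
#' segment starting at axial sample `(r-1) * hop + 1` on line c; trailing
#' windows that do not fit are dropped, so each map has
#' `floor((n_samples - window) / hop) + 1` rows. The raw maps satisfy
#' `BS_S1 + BS_S2 + BS_S3 == BS_A` elementwise.
#'
#' @param frame An [rf_frame()].
#' @param geometry A [map_geometry()]; its window must equal `hos_cfg$window`.
#' @param hos_cfg A [hos_config()].
#' @param normalize Image normalization mode, `"log"` (default) or
#'   `"linear"`; see [normalize_map()].
#' @return An object of class `feature_map_set`: `maps` (list of four raw
#'   matrices), `images` (8-bit versions via [normalize_map()]), `geometry`,
#'   `hos_cfg`, `frame_id`, `label`.
#' @export
build_feature_maps <- function(frame, geometry = map_geometry(),
                               hos_cfg = hos_config(),
                               normalize = c("log", "linear")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(frame, "rf_frame"), inherits(geometry, "map_geometry"))
  if (geometry$window != hos_cfg$window)
    stop("geometry window must match hos_cfg window", call. = FALSE)
  n <- nrow(frame$samples)
  if (n < geometry$window)
    stop("frame axial length is shorter than one window", call. = FALSE)
  n_rows <- (n - geometry$window) %/% geometry$hop + 1
  lines <- seq(1, ncol(frame$samples), by = geometry$lateral_stride)
  bands <- matrix(0, n_rows * length(lines), 4)
  i <- 0
  for (c_idx in seq_along(lines)) {
    line <- frame$samples[, lines[c_idx]]
    for (r in seq_len(n_rows)) {
      start <- (r - 1) * geometry$hop + 1
      i <- i + 1
      bands[i, ] <- segment_features(line[start:(start + geometry$window - 1)],
                                     hos_cfg)
    }
  }
  shape <- c(n_rows, length(lines))
  maps <- list(BS_S1 = matrix(bands[, 1], shape[1], shape[2]),
               BS_S2 = matrix(bands[, 2], shape[1], shape[2]),
               BS_S3 = matrix(bands[, 3], shape[1], shape[2]),
               BS_A  = matrix(bands[, 4], shape[1], shape[2]))
  images <- lapply(maps, normalize_map, mode = normalize)
  structure(list(maps = maps, images = images, geometry = geometry,
                 hos_cfg = hos_cfg, frame_id = frame$frame_id,
                 label = frame$label),
            class = "feature_map_set")
}

#' @export
print.feature_map_set <- function(x, ...) {
  cat(sprintf("<feature_map_set '%s'> 4 maps of %d x %d (window %d, hop %d)%s\n",
              x$frame_id, nrow(x$maps$BS_A), ncol(x$maps$BS_A),
              x$geometry$window, x$geometry$hop,
              if (is.null(x$label)) "" else paste0(", label = ", x$label)))
  invisible(x)
}

#' Normalize a raw energy map to an 8-bit image
#'
#' Optional log compression `log10(1 + E)` followed by min-max scaling to
#' 0..255. A constant map (degenerate range) maps to all zeros. The transform
#' is monotone, so the pixel ordering of the raw map is preserved.
#'
#' @param m Numeric matrix with finite entries.
#' @param mode `"linear"` (default) or `"log"`.
#' @return Integer matrix with values in 0..255.
#' @export
normalize_map <- function(m, mode = c("linear", "log")) {
  mode <- match.arg(mode)
  if (!all(is.finite(m))) stop("map must be finite", call. = FALSE)
  if (mode == "log") m <- log10(1 + m)
  rng <- range(m)
  out <- if (rng[2] == rng[1]) array(0, dim(m))
         else round(255 * (m - rng[1]) / (rng[2] - rng[1]))
  storage.mode(out) <- "integer"
  out
}

# Shared binning for the histogram-based statistics: each image is binned
# over its own range into `bins` equal cells (constant image -> all in cell 1).
bin_index <- function(x, bins) {
  rng <- range(x)
  if (rng[2] == rng[1]) return(rep(1L, length(x)))
  pmin(bins, floor((x - rng[1]) / (rng[2] - rng[1]) * bins) + 1L)
}

#' Mutual information between two images
#'
#' MI in bits from the joint histogram with `bins` bins per axis (each image
#' binned over its own range). Symmetric, nonnegative; `MI(A, A)` equals the
#' histogram entropy of A.
#'
#' @param a,b Equal-shape numeric arrays.
#' @param bins Bins per axis (default 64).
#' @return MI in bits.
#' @export
mutual_information <- function(a, b, bins = 64) {
  if (!identical(dim(a), dim(b)))
    stop("images must share one shape", call. = FALSE)
  ia <- bin_index(as.numeric(a), bins)
  ib <- bin_index(as.numeric(b), bins)
  joint <- matrix(tabulate(ia + (ib - 1L) * bins, bins * bins), bins, bins)
  p <- joint / sum(joint)
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(pa, pb)[nz]))
}

#' Root mean square error between two images
#'
#' @param a,b Equal-shape numeric arrays.
#' @return `sqrt(mean((a - b)^2))`.
#' @export
rmse <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("images must share one shape", call. = FALSE)
  sqrt(mean((as.numeric(a) - as.numeric(b))^2))
}

#' Pairwise comparison statistics of the four feature maps
#'
#' Computes the full 4x4 mutual-information and RMSE matrices over the 8-bit
#' images, 256-cell gray histograms per map, and each map's average MI/RMSE
#' versus the other three maps (the quantities used to argue which bands
#' carry independent information).
#'
#' @param set A [build_feature_maps()] result.
#' @param bins Histogram bins per axis for MI (default 64).
#' @return An object of class `map_stats_report` with `mi`, `rmse`
#'   (symmetric 4x4 matrices; RMSE diagonal zero, MI diagonal = entropy),
#'   `histograms`, `avg_mi`, `avg_rmse`.
#' @export
pairwise_stats <- function(set, bins = 64) {
  stopifnot(inherits(set, "feature_map_set"))
  imgs <- set$images
  nm <- names(imgs)
  k <- length(imgs)
  mi <- matrix(0, k, k, dimnames = list(nm, nm))
  rm_ <- matrix(0, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in i:k) {
    mi[i, j] <- mi[j, i] <- mutual_information(imgs[[i]], imgs[[j]], bins)
    rm_[i, j] <- rm_[j, i] <- rmse(imgs[[i]], imgs[[j]])
  }
  hist_counts <- lapply(imgs, function(im)
    tabulate(as.integer(im) + 1L, 256L))
  off <- function(m) vapply(seq_len(k), function(i) mean(m[i, -i]), numeric(1))
  structure(list(mi = mi, rmse = rm_, histograms = hist_counts,
                 avg_mi = stats::setNames(off(mi), nm),
                 avg_rmse = stats::setNames(off(rm_), nm)),
            class = "map_stats_report")
}

#' @export
print.map_stats_report <- function(x, ...) {
  cat("<map_stats_report>\n  average MI vs other maps (bits):\n")
  print(round(x$avg_mi, 3))
  cat("  average RMSE vs other maps:\n")
  print(round(x$avg_rmse, 3))
  invisible(x)
}

# Discrete analytic signal of one line via the FFT half-spectrum method.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' B-mode grayscale stand-in from an RF frame
#'
#' Conventional envelope display: per-line analytic-signal envelope, log
#' compression over a configurable dynamic range, min-max scaling to 8 bits.
#' This is a simple reference reconstruction, not any vendor's processing
#' chain.
#'
#' @param frame An [rf_frame()].
#' @param dynamic_range_db Displayed dynamic range in dB (default 60).
#' @return Integer matrix (0..255) with the frame's shape.
#' @export
bmode_from_rf <- function(frame, dynamic_range_db = 60) {
  stopifnot(inherits(frame, "rf_frame"))
  env <- apply(frame$samples, 2, function(col) Mod(analytic_signal(col)))
  mx <- max(env)
  if (mx == 0) {
    out <- array(0L, dim(env))
    return(out)
  }
  db <- 20 * log10(pmax(env, mx * 10^(-dynamic_range_db / 20 - 1)) / mx)
  db <- pmax(db, -dynamic_range_db)
  out <- round(255 * (db + dynamic_range_db) / dynamic_range_db)
  storage.mode(out) <- "integer"
  out
}
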