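#' Generate a balanced synthetic cohort of network-ready samples
#'
#' Convenience wrapper tying the phantom simulator to the feature-map
#' pipeline: simulates `n_per_class` frames per class with the built-in
#' presets, extracts the four bispectral energy maps and returns prepared
#' samples. Per-frame seeds are derived deterministically from `seed`
#' (benign frames use indices `offset + 1..n`, malignant
#' `offset + 10000 + 1..n`), so disjoint cohorts are obtained by disjoint
#' offsets under one master seed.
#'
#' The default problem size (1024 x 32 frames, window 256, hop 128,
#' max_lag 31, nfft 64) is the package's desk-scale experiment setting:
#' 7 x 32 maps per frame, small enough that a full train/test cycle runs in
#' minutes on one CPU.
#'
#' @param n_per_class Frames per class.
#' @param seed Master seed.
#' @param offset Seed-index offset separating cohorts (e.g. train vs test).
#' @param n_samples,n_lines Frame dimensions.
#' @param geometry A [map_geometry()].
#' @param hos_cfg A [hos_config()].
#' @return List of `2 * n_per_class` [prepare_sample()] samples
#'   (benign first).
#' @export
synthetic_cohort <- function(n_per_class, seed = 0, offset = 0,
                             n_samples = 1024, n_lines = 32,
                             geometry = map_geometry(window = 256, hop = 128),
                             hos_cfg = hos_config(window = 256, max_lag = 31,
                                                  nfft = 64)) {
  one <- function(cls, idx) {
    p <- phantom_preset(cls, n_samples = n_samples, n_lines = n_lines)
    fr <- simulate_frame(p, seed = derive_seed(seed, idx))
    fr$frame_id <- sprintf("%s_%04d", cls, idx)
    prepare_sample(build_feature_maps(fr, geometry, hos_cfg))
  }
  c(lapply(seq_len(n_per_class), function(i) one("benign", offset + i)),
    lapply(seq_len(n_per_class), function(i) one("malignant",
                                                 offset + 10000 + i)))
}
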