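#' Write an RF frame container
#'
#' Canonical on-disk dialect: a raw little-endian float32 binary holding the
#' column-major sample matrix, plus a JSON sidecar (`<path base>.json`) with
#' the dataset name, shape and acquisition attributes `fs_hz`, `f0_hz`,
#' `frame_id` and (when present) `label`.
#'
#' @param frame An [rf_frame()].
#' @param path Output file (conventionally `.rf`).
#' @param force Overwrite an existing file (default `FALSE`: refuse).
#' @return Invisibly, `path`.
#' @export
write_rf_frame <- function(frame, path, force = FALSE) {
  stopifnot(inherits(frame, "rf_frame"))
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!force && (file.exists(path) || file.exists(sidecar)))
    stop("refusing to overwrite existing file (use force = TRUE): ", path,
         call. = FALSE)
  meta <- list(dataset = "rf", dtype = "float32", byte_order = "little",
               shape = dim(frame$samples), fs_hz = frame$fs_hz,
               f0_hz = frame$f0_hz, frame_id = frame$frame_id)
  if (!is.null(frame$label)) meta$label <- frame$label
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(frame$samples), con, size = 4, endian = "little")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an RF frame container
#'
#' Reads the raw float32 + JSON sidecar dialect written by
#' [write_rf_frame()]; samples are widened to double. Missing required
#' attributes produce an error naming the attribute.
#'
#' @param path Path to the binary file (the sidecar is `<path base>.json`).
#' @return An [rf_frame()].
#' @export
read_rf_frame <- function(path) {
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (!file.exists(sidecar))
    stop("missing JSON sidecar: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (attr_ in c("shape", "fs_hz", "f0_hz", "frame_id"))
    if (is.null(meta[[attr_]]))
      stop("RF container sidecar is missing required attribute '", attr_,
           "'", call. = FALSE)
  n <- prod(meta$shape)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  vals <- readBin(con, numeric(), n = n, size = 4, endian = "little")
  if (length(vals) != n)
    stop("RF file shorter than the sidecar shape promises", call. = FALSE)
  rf_frame(matrix(vals, meta$shape[1], meta$shape[2]),
           fs_hz = meta$fs_hz, f0_hz = meta$f0_hz,
           frame_id = meta$frame_id, label = meta$label)
}

manifest_splits <- c("train", "val", "test1", "test2")

#' Read and validate a dataset manifest
#'
#' CSV with exact header `frame_id,label,split`; frame ids must be unique,
#' labels in \{benign, malignant\}, splits in
#' \{train, val, test1, test2\}.
#'
#' @param path CSV path.
#' @return data.frame with the three character columns.
#' @export
read_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!identical(names(df), c("frame_id", "label", "split")))
    stop("manifest header must be exactly 'frame_id,label,split'",
         call. = FALSE)
  validate_manifest(df)
  df
}

validate_manifest <- function(df) {
  if (anyDuplicated(df$frame_id))
    stop("duplicate frame_id in manifest", call. = FALSE)
  bad <- setdiff(unique(df$label), c("benign", "malignant"))
  if (length(bad)) stop("unknown label: ", bad[1], call. = FALSE)
  bad <- setdiff(unique(df$split), manifest_splits)
  if (length(bad)) stop("unknown split token: ", bad[1], call. = FALSE)
  invisible(df)
}

#' Write a dataset manifest
#' @param rows data.frame with columns frame_id, label, split.
#' @param path Output CSV path.
#' @param force Overwrite existing file.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(rows, path, force = FALSE) {
  validate_manifest(rows)
  if (!force && file.exists(path))
    stop("refusing to overwrite existing manifest: ", path, call. = FALSE)
  write.csv(rows[c("frame_id", "label", "split")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

# --- run configuration -----------------------------------------------------

#' Default pipeline configuration tree
#'
#' Nested list of every tunable key with its documented default, covering
#' the phantom, the HOS engine, map geometry, the network and training.
#' Serializes round-trip-stable to JSON.
#'
#' @return Named nested list.
#' @export
default_run_config <- function() {
  list(
    phantom = list(f0_norm = 0.125, rel_bandwidth = 0.6, snr_db = 20,
                   n_samples = 2048, n_lines = 128,
                   benign = list(beta = 0.05, scatterer_rate = 4),
                   malignant = list(beta = 0.3, scatterer_rate = 12)),
    hos = list(window = 256, max_lag = 63, nfft = 128,
               energy_mode = "power", split_axis = "f1", demean = TRUE,
               lag_window = "none"),
    maps = list(hop = 64, lateral_stride = 1, normalize = "log",
                mi_bins = 64, bmode_dynamic_range_db = 60),
    net = list(backbone = "resnet50", K = 4, L = 256, share_weights = TRUE,
               use_fatt = TRUE, use_sm = TRUE, lambda_sm = 0.1, tau = 0.1,
               pretrained = FALSE),
    train = list(batch_size = 8, lr_init = 0.002, lr_final = 1e-4,
                 max_epochs = 30, patience = 5, seed = 0, threshold = 0.5))
}

merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base))
      stop("unknown configuration key: ", key, call. = FALSE)
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], key)
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a run configuration
#'
#' Reads a JSON document and merges it over [default_run_config()]; unknown
#' keys are rejected with the offending dotted path.
#'
#' @param path JSON file, or `NULL` for pure defaults.
#' @return Full configuration list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  merge_config(cfg, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Save a run configuration as JSON
#' @param cfg Configuration list.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_run_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# --- checkpoints and images ------------------------------------------------

#' Save / load a fitted classifier
#'
#' Single-file serialized weights plus a JSON configuration sidecar.
#'
#' @param fit An `msnet` fit.
#' @param path Checkpoint path (conventionally `.ckpt`).
#' @return Invisibly, `path`.
#' @export
save_msnet <- function(fit, path) {
  stopifnot(inherits(fit, "msnet"))
  saveRDS(fit, path)
  jsonlite::write_json(unclass(fit$cfg),
                       paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_msnet
#' @export
load_msnet <- function(path) {
  fit <- readRDS(path)
  stopifnot(inherits(fit, "msnet"))
  fit
}

#' Write the four feature-map images as PNG
#'
#' 8-bit grayscale PNGs plus one JSON sidecar carrying frame id, map names,
#' geometry and HOS configuration.
#'
#' @param set A [build_feature_maps()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written PNG paths.
#' @export
write_map_images <- function(set, dir) {
  stopifnot(inherits(set, "feature_map_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(set$images)) {
    p <- file.path(dir, sprintf("%s_%s.png", set$frame_id, nm))
    png::writePNG(set$images[[nm]] / 255, p)
    paths <- c(paths, p)
  }
  meta <- list(frame_id = set$frame_id, maps = names(set$images),
               label = set$label,
               geometry = unclass(set$geometry),
               hos = unclass(set$hos_cfg))
  jsonlite::write_json(meta,
                       file.path(dir, sprintf("%s_maps.json", set$frame_id)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
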