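# Backbone registry: feature dimension M after global average pooling and
# closed-form trainable-parameter counts of the convolutional feature
# extractor (no classifier head). Only tinycnn is runnable in this package;
# the large architectures are registered for parameter accounting.

# Bottleneck ResNet (bias-free convs + batch norm, as in the canonical
# 50/101-layer definitions).
resnet_feature_params <- function(blocks) {
  widths <- c(64, 128, 256, 512)
  total <- 7 * 7 * 3 * 64 + 2 * 64          # stem conv + bn
  in_ch <- 64
  for (s in seq_along(widths)) {
    w <- widths[s]
    for (b in seq_len(blocks[s])) {
      total <- total +
        in_ch * w + 2 * w +                 # 1x1 reduce + bn
        9 * w * w + 2 * w +                 # 3x3 + bn
        w * 4 * w + 2 * 4 * w               # 1x1 expand + bn
      if (b == 1)
        total <- total + in_ch * 4 * w + 2 * 4 * w  # projection shortcut + bn
      in_ch <- 4 * w
    }
  }
  total
}

# VGG-19 convolutional part (biased convs, no batch norm).
vgg19_feature_params <- function() {
  cfg <- c(64, 64, NA, 128, 128, NA, 256, 256, 256, 256, NA,
           512, 512, 512, 512, NA, 512, 512, 512, 512, NA)
  total <- 0; in_ch <- 3
  for (v in cfg) {
    if (is.na(v)) next
    total <- total + 9 * in_ch * v + v
    in_ch <- v
  }
  total
}

tinycnn_channels <- c(16L, 32L, 64L, 128L)

tinycnn_feature_params <- function(channels = tinycnn_channels) {
  in_ch <- 3; total <- 0
  for (ch in channels) {
    total <- total + 9 * in_ch * ch + ch
    in_ch <- ch
  }
  total
}

#' Backbone architecture registry
#'
#' Feature dimension and feature-extractor parameter count per supported
#' backbone. `tinycnn` (four 3x3 stride-2 conv blocks, M = 128) is the only
#' backbone with a native forward/backward implementation and exists to keep
#' end-to-end experiments desk-scale; `resnet50` (default for parameter
#' accounting), `resnet101` and `vgg19` are counted by closed-form
#' architecture arithmetic. `inceptionv3` and `swin` are recognized names but
#' raise an error, as no implementation of them ships with this package.
#'
#' @param name Backbone name.
#' @return List with `M` (pooled feature dimension), `params`
#'   (feature-extractor trainable parameters) and `runnable`.
#' @export
backbone_info <- function(name) {
  switch(name,
    tinycnn  = list(M = 128L,  params = tinycnn_feature_params(),
                    runnable = TRUE),
    resnet50 = list(M = 2048L, params = resnet_feature_params(c(3, 4, 6, 3)),
                    runnable = FALSE),
    resnet101 = list(M = 2048L,
                     params = resnet_feature_params(c(3, 4, 23, 3)),
                     runnable = FALSE),
    vgg19    = list(M = 512L,  params = vgg19_feature_params(),
                    runnable = FALSE),
    inceptionv3 = ,
    swin = stop("backbone '", name, "' is registered but not implemented ",
                "in this package", call. = FALSE),
    stop("unknown backbone: ", name, call. = FALSE))
}

# --- tinycnn weights and forward/backward ---------------------------------

# He-initialized weights for the 4-block CNN. Each layer is a 3x3 stride-2
# pad-1 convolution followed by ReLU; global average pooling yields M = 128.
init_tinycnn <- function(seed, channels = tinycnn_channels) {
  with_seed(seed, {
    in_ch <- 3L
    layers <- vector("list", length(channels))
    for (i in seq_along(channels)) {
      fan_in <- 9L * in_ch
      layers[[i]] <- list(
        W = matrix(rnorm(channels[i] * fan_in, sd = sqrt(2 / fan_in)),
                   channels[i], fan_in),
        b = numeric(channels[i]))
      in_ch <- channels[i]
    }
    layers
  })
}

# Forward pass through the CNN. x is an (H, W, 3) array scaled to [0, 1].
# Returns the pooled feature vector h and (optionally) the caches needed for
# the backward pass.
tinycnn_forward <- function(x, layers, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    fw <- conv2d_forward_cpp(x, layers[[i]]$W, layers[[i]]$b, 3L, 3L, 2L, 1L)
    pre <- fw$out
    post <- pre * (pre > 0)
    if (keep_cache)
      caches[[i]] <- list(cols = fw$cols, mask = pre > 0, in_dim = dim(x))
    x <- post
  }
  d <- dim(x)
  h <- apply(x, 3, mean)
  list(h = h, caches = caches, out_dim = d)
}

# Backward pass: dh is dLoss/dh. Returns per-layer gradients (same shapes as
# the weights).
tinycnn_backward <- function(fwd, dh, layers) {
  d <- fwd$out_dim
  dX <- array(rep(dh / (d[1] * d[2]), each = d[1] * d[2]), dim = d)
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    cache <- fwd$caches[[i]]
    dPre <- dX * cache$mask
    bw <- conv2d_backward_cpp(dPre, cache$cols, layers[[i]]$W,
                              cache$in_dim[1], cache$in_dim[2],
                              cache$in_dim[3], 3L, 3L, 2L, 1L)
    grads[[i]] <- list(W = bw$dW, b = as.numeric(bw$db))
    dX <- bw$dX
  }
  grads
}
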