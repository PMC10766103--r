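#' Network configuration
#'
#' Configuration of the multi-map classifier: a backbone shared (or not)
#' across the K input feature maps, a gated feature-map attention pool
#' (F-ATT) fusing the K pooled feature vectors, a 2-way linear head, and an
#' auxiliary cosine-similarity constraint (SM) loss.
#'
#' @param backbone Backbone name; see [backbone_info()]. `"tinycnn"` is the
#'   runnable desk-scale backbone, `"resnet50"` the default for parameter
#'   accounting.
#' @param K Number of input maps (default 4).
#' @param L Attention hidden width (default 256).
#' @param share_weights Route all K maps through one backbone instance
#'   (default `TRUE`).
#' @param use_fatt Use gated attention fusion; if `FALSE` the unweighted mean
#'   of the K feature vectors is used.
#' @param use_sm Add the similarity-constraint loss.
#' @param lambda_sm Weight of the SM loss in the total objective.
#' @param tau Temperature of the SM softmax over cosine similarities.
#' @param pretrained Must be `FALSE`; no pretrained weights ship with this
#'   package.
#' @param attention_bias Add biases to the attention projections (default
#'   `FALSE`).
#' @param literal_negative Treat the classifier probability as that of the
#'   negative class inside the cross-entropy (default `FALSE`; see
#'   [attention_loss()]).
#' @return An object of class `net_config`; `M` is filled from the backbone.
#' @export
net_config <- function(backbone = "resnet50", K = 4, L = 256,
                       share_weights = TRUE, use_fatt = TRUE, use_sm = TRUE,
                       lambda_sm = 0.1, tau = 0.1, pretrained = FALSE,
                       attention_bias = FALSE, literal_negative = FALSE) {
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (L < 1) stop("L must be >= 1", call. = FALSE)
  if (lambda_sm < 0) stop("lambda_sm must be >= 0", call. = FALSE)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (isTRUE(pretrained))
    stop("no pretrained weights are available in this package", call. = FALSE)
  info <- backbone_info(backbone)
  structure(list(backbone = backbone, K = as.integer(K), M = info$M,
                 L = as.integer(L), share_weights = share_weights,
                 use_fatt = use_fatt, use_sm = use_sm,
                 lambda_sm = lambda_sm, tau = tau, pretrained = FALSE,
                 attention_bias = attention_bias,
                 literal_negative = literal_negative),
            class = "net_config")
}

#' Count trainable parameters of a configuration
#'
#' Closed-form count over the backbone feature extractor(s) (one instance if
#' `share_weights`, else K), the gated attention block (two L x M
#' projections plus the L-vector scoring layer, bias-free by default) and the
#' M -> 2 linear head.
#'
#' @param cfg A [net_config()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(cfg) {
  stopifnot(inherits(cfg, "net_config"))
  info <- backbone_info(cfg$backbone)
  n_backbones <- if (cfg$share_weights) 1L else cfg$K
  att <- if (cfg$use_fatt) {
    2 * cfg$L * cfg$M + cfg$L +
      if (cfg$attention_bias) 2 * cfg$L + 1 else 0
  } else 0
  head <- cfg$M * 2 + 2
  n_backbones * info$params + att + head
}

#' Parameter ratio of weight sharing versus independent branches
#'
#' `100 * params(share_weights = TRUE) / params(share_weights = FALSE)` for
#' the same configuration: how much of the K-independent-backbone model's
#' parameter budget the weight-sharing model needs.
#'
#' @param cfg A [net_config()].
#' @return Percentage.
#' @export
shared_ratio <- function(cfg) {
  stopifnot(inherits(cfg, "net_config"))
  shared <- cfg; shared$share_weights <- TRUE
  indep <- cfg; indep$share_weights <- FALSE
  100 * count_parameters(shared) / count_parameters(indep)
}

# --- model construction ----------------------------------------------------

#' Initialize a multi-map classifier model
#'
#' Random (seeded) initialization of the backbone(s), attention parameters
#' and classifier head for a runnable configuration.
#'
#' @param cfg A [net_config()] whose backbone is runnable (`"tinycnn"`).
#' @param seed Integer seed.
#' @return An object of class `msnet_model`.
#' @export
msnet_init <- function(cfg, seed = 0) {
  stopifnot(inherits(cfg, "net_config"))
  info <- backbone_info(cfg$backbone)
  if (!info$runnable)
    stop("backbone '", cfg$backbone, "' has no native implementation; ",
         "use 'tinycnn' for runnable models", call. = FALSE)
  backbones <- if (cfg$share_weights) list(init_tinycnn(derive_seed(seed, 1)))
               else lapply(seq_len(cfg$K),
                           function(k) init_tinycnn(derive_seed(seed, k)))
  att <- if (cfg$use_fatt) with_seed(derive_seed(seed, 101), {
    sd0 <- sqrt(1 / cfg$M)
    a <- list(V = matrix(rnorm(cfg$L * cfg$M, sd = sd0), cfg$L, cfg$M),
              U = matrix(rnorm(cfg$L * cfg$M, sd = sd0), cfg$L, cfg$M),
              w = rnorm(cfg$L, sd = sqrt(1 / cfg$L)))
    if (cfg$attention_bias) {
      a$bV <- numeric(cfg$L); a$bU <- numeric(cfg$L); a$bw <- 0
    }
    a
  }) else NULL
  head <- with_seed(derive_seed(seed, 102),
    list(W = matrix(rnorm(2 * cfg$M, sd = sqrt(1 / cfg$M)), 2, cfg$M),
         b = numeric(2)))
  structure(list(cfg = cfg, backbones = backbones, att = att, head = head),
            class = "msnet_model")
}

#' Backbone features for the K input maps
#'
#' Routes each preprocessed map through the (shared or per-branch) backbone
#' and global-average-pools the final convolutional features into one
#' M-vector per map.
#'
#' @param images List of K arrays of shape (224, 224, 3) in `[0, 1]`.
#' @param model An [msnet_init()] model.
#' @param keep_cache Keep intermediates for the backward pass.
#' @return List with `H` (K x M matrix of feature vectors) and `fwd` (caches).
#' @export
backbone_features <- function(images, model, keep_cache = FALSE) {
  cfg <- model$cfg
  if (length(images) != cfg$K)
    stop("expected ", cfg$K, " input maps", call. = FALSE)
  H <- matrix(0, cfg$K, cfg$M)
  fwd <- vector("list", cfg$K)
  for (k in seq_len(cfg$K)) {
    x <- images[[k]]
    if (length(dim(x)) != 3 || dim(x)[3] != 3)
      stop("each input must be an (H, W, 3) array", call. = FALSE)
    wts <- if (cfg$share_weights) model$backbones[[1]] else model$backbones[[k]]
    fwd[[k]] <- tinycnn_forward(x, wts, keep_cache = keep_cache)
    H[k, ] <- fwd[[k]]$h
  }
  list(H = H, fwd = fwd)
}

# --- gated attention -------------------------------------------------------

softmax <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

#' Gated feature-map attention pooling
#'
#' Scores each feature vector h_k with
#' `s_k = w' (tanh(V h_k) * sigmoid(U h_k))`, turns the scores into simplex
#' weights `a = softmax(s)` and fuses `z = sum_k a_k h_k`. The gate (tanh
#' times sigmoid) tempers the near-linear regime of tanh; the softmax
#' guarantees `a_k > 0`, `sum a_k = 1`, so fusion never changes the feature
#' dimension.
#'
#' @param H K x M matrix of feature vectors (rows = maps).
#' @param params List with `V`, `U` (L x M), `w` (length L) and optional
#'   biases `bV`, `bU`, `bw`.
#' @return List with `a` (K weights), `z` (fused M-vector) and `cache` for
#'   the backward pass.
#' @export
gated_attention <- function(H, params) {
  H <- as.matrix(H)
  if (ncol(params$V) != ncol(H) || ncol(params$U) != ncol(H) ||
      length(params$w) != nrow(params$V))
    stop("attention parameter shapes do not match the features", call. = FALSE)
  bV <- params$bV %||% 0; bU <- params$bU %||% 0; bw <- params$bw %||% 0
  TT <- tanh(params$V %*% t(H) + bV)        # L x K
  G <- 1 / (1 + exp(-(params$U %*% t(H) + bU)))
  s <- as.numeric(crossprod(params$w, TT * G)) + bw
  a <- softmax(s)
  z <- as.numeric(crossprod(H, a))
  list(a = a, z = z, cache = list(H = H, TT = TT, G = G, a = a))
}

# Gradients of the attention block. dz is dLoss/dz (M), da_extra an optional
# direct gradient on the weights. Returns dH (K x M) and parameter grads.
gated_attention_backward <- function(out, params, dz) {
  H <- out$cache$H; TT <- out$cache$TT; G <- out$cache$G; a <- out$cache$a
  K <- nrow(H)
  da <- as.numeric(H %*% dz)                    # dL/da_k = h_k . dz
  ds <- a * (da - sum(a * da))                  # softmax jacobian
  dH <- a %o% dz                                # z-path: a_k * dz
  dV <- matrix(0, nrow(params$V), ncol(params$V))
  dU <- dV
  dw <- numeric(length(params$w))
  dbV <- numeric(length(params$w)); dbU <- dbV; dbw <- 0
  for (k in seq_len(K)) {
    tk <- TT[, k]; gk <- G[, k]
    dw <- dw + ds[k] * (tk * gk)
    dpre_t <- ds[k] * params$w * gk * (1 - tk^2)
    dpre_g <- ds[k] * params$w * tk * gk * (1 - gk)
    dV <- dV + dpre_t %o% H[k, ]
    dU <- dU + dpre_g %o% H[k, ]
    dbV <- dbV + dpre_t
    dbU <- dbU + dpre_g
    dbw <- dbw + ds[k]
    dH[k, ] <- dH[k, ] + as.numeric(crossprod(params$V, dpre_t)) +
      as.numeric(crossprod(params$U, dpre_g))
  }
  g <- list(V = dV, U = dU, w = dw)
  if (!is.null(params$bV)) { g$bV <- dbV; g$bU <- dbU; g$bw <- dbw }
  list(dH = dH, grads = g)
}

# --- losses ----------------------------------------------------------------

#' Classification (attention-branch) loss
#'
#' Mean binary cross-entropy over the batch,
#' `-(1/N) sum [ y log p + (1 - y) log(1 - p) ]`, with `p` the predicted
#' probability of the positive (malignant) class. Probabilities outside
#' (0, 1) are clamped to `[1e-7, 1 - 1e-7]` with a warning. With
#' `literal_negative = TRUE` the roles of `p` and `1 - p` are swapped,
#' reading `p` as the negative-class probability.
#'
#' @param p Predicted probabilities.
#' @param y Labels in \{0, 1\}.
#' @param literal_negative Swap the probability convention.
#' @return Nonnegative scalar.
#' @export
attention_loss <- function(p, y, literal_negative = FALSE) {
  if (length(p) != length(y)) stop("length mismatch", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (any(p <= 0 | p >= 1)) {
    warning("probabilities outside (0, 1) clamped at 1e-7")
    p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  }
  if (literal_negative) p <- 1 - p
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Cosine similarity of two embeddings
#'
#' Dot product after L2 normalization; in `[-1, 1]`.
#'
#' @param f_i,f_j Nonzero numeric vectors of equal length.
#' @return Scalar.
#' @export
cosine_similarity <- function(f_i, f_j) {
  ni <- sqrt(sum(f_i^2)); nj <- sqrt(sum(f_j^2))
  if (ni == 0 || nj == 0) stop("zero vector has no direction", call. = FALSE)
  sum(f_i * f_j) / (ni * nj)
}

l2_normalize_rows <- function(F_) {
  nrm <- sqrt(rowSums(F_^2))
  if (any(nrm == 0)) stop("zero embedding vector", call. = FALSE)
  F_ / nrm
}

# Internal: SM forward pieces shared by loss and gradient.
sm_forward <- function(F_, types, tau) {
  types <- as.integer(factor(types))
  K <- max(types)
  if (K < 2) stop("at least 2 map types are required", call. = FALSE)
  Fn <- l2_normalize_rows(as.matrix(F_))
  C <- t(vapply(seq_len(K),
                function(j) colMeans(Fn[types == j, , drop = FALSE]),
                numeric(ncol(Fn))))
  C <- l2_normalize_rows(C)
  cosm <- Fn %*% t(C)                      # n x K
  E <- exp(cosm / tau - apply(cosm / tau, 1, max))
  P <- E / rowSums(E)
  list(Fn = Fn, C = C, P = P, types = types, K = K)
}

#' Similarity-constraint (SM) loss
#'
#' Prototype-based contrastive constraint on the per-map embeddings. Each
#' map type's prototype is the re-normalized batch mean of its L2-normalized
#' embeddings; `P(j | x) = softmax_j(cos(f_x, c_j) / tau)`. The loss is the
#' sum of negative logarithms
#' `-sum_x log P(type(x) | x) - sum_x sum_(j != type(x)) log(1 - P(j | x))`,
#' driving same-type embeddings together and different types apart.
#'
#' @param embeddings n x M matrix of branch embeddings (rows are normalized
#'   internally).
#' @param types Map-type label per row (>= 2 distinct types required).
#' @param tau Temperature (default 0.1).
#' @param reduce `"sum"` (the defining form) or `"mean"` (per-instance
#'   average, used inside training batches).
#' @return Nonnegative scalar.
#' @export
sm_loss <- function(embeddings, types, tau = 0.1,
                    reduce = c("sum", "mean")) {
  reduce <- match.arg(reduce)
  sf <- sm_forward(embeddings, types, tau)
  n <- nrow(sf$P)
  pos <- sf$P[cbind(seq_len(n), sf$types)]
  neg <- 1 - sf$P
  neg[cbind(seq_len(n), sf$types)] <- 1     # exclude own-type term
  loss <- -sum(log(pmax(pos, 1e-300))) - sum(log(pmax(neg, 1e-300)))
  if (reduce == "mean") loss / n else loss
}

# Gradient of sm_loss w.r.t. the raw (pre-normalization) embeddings.
# Prototypes are treated as constants (stop-gradient).
sm_loss_grad <- function(embeddings, types, tau = 0.1,
                         reduce = c("sum", "mean")) {
  reduce <- match.arg(reduce)
  F_ <- as.matrix(embeddings)
  sf <- sm_forward(F_, types, tau)
  n <- nrow(sf$P); K <- sf$K
  # dL/dP
  dP <- 1 / pmax(1 - sf$P, 1e-12)
  dP[cbind(seq_len(n), sf$types)] <-
    -1 / pmax(sf$P[cbind(seq_len(n), sf$types)], 1e-12)
  # through the row softmax: dcos_l = (1/tau) * P_l * (dP_l - sum_j dP_j P_j)
  inner <- rowSums(dP * sf$P)
  dcos <- (sf$P * (dP - inner)) / tau
  dFn <- dcos %*% sf$C                       # n x M
  # through L2 row normalization: d f / d h = (I - f f') / ||h||
  nrm <- sqrt(rowSums(F_^2))
  dF <- (dFn - sf$Fn * rowSums(dFn * sf$Fn)) / nrm
  if (reduce == "mean") dF / n else dF
}

#' Combine the classification and similarity losses
#'
#' `total = loss_att + lambda_sm * loss_sm` when the SM module is enabled,
#' else `total = loss_att`.
#'
#' @param loss_att,loss_sm Finite loss components.
#' @param cfg A [net_config()].
#' @return List with `loss_att`, `loss_sm`, `total`.
#' @export
total_loss <- function(loss_att, loss_sm, cfg) {
  stopifnot(inherits(cfg, "net_config"))
  total <- if (cfg$use_sm) loss_att + cfg$lambda_sm * loss_sm else loss_att
  list(loss_att = loss_att, loss_sm = if (cfg$use_sm) loss_sm else 0,
       total = total)
}

# --- full forward ----------------------------------------------------------

#' Forward pass of the multi-map classifier
#'
#' Backbone features for the K maps, attention fusion (or the unweighted
#' mean when `use_fatt = FALSE`), linear head and 2-way softmax.
#' Deterministic: repeated calls on the same input agree bitwise.
#'
#' @param images List of K preprocessed map arrays (224, 224, 3).
#' @param model An [msnet_init()] or trained model.
#' @param keep_cache Keep intermediates (training use).
#' @return List with `prob` (positive-class probability), `a` (attention
#'   weights, uniform when attention is disabled), `z`, `H`, and caches when
#'   requested.
#' @export
forward_msnet <- function(images, model, keep_cache = FALSE) {
  cfg <- model$cfg
  bf <- backbone_features(images, model, keep_cache = keep_cache)
  if (cfg$use_fatt) {
    att <- gated_attention(bf$H, model$att)
  } else {
    att <- list(a = rep(1 / cfg$K, cfg$K),
                z = colMeans(bf$H), cache = NULL)
  }
  logits <- as.numeric(model$head$W %*% att$z + model$head$b)
  pr <- softmax(logits)
  list(prob = pr[2], a = att$a, z = att$z, H = bf$H,
       logits = logits, att = att, fwd = if (keep_cache) bf$fwd)
}
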