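#' Training configuration
#'
#' @param batch_size Frames per batch (default 8).
#' @param lr_init Initial learning rate (default 0.002).
#' @param lr_final Final learning rate of the cosine annealing schedule
#'   (default 1e-4).
#' @param max_epochs Maximum epochs (also the annealing horizon).
#' @param patience Early-stopping patience on validation loss, in epochs.
#' @param seed Seed controlling initialization and shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 8, lr_init = 0.002, lr_final = 1e-4,
                         max_epochs = 30, patience = 5, seed = 0) {
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  if (lr_final > lr_init) stop("lr_final must be <= lr_init", call. = FALSE)
  structure(list(batch_size = as.integer(batch_size), lr_init = lr_init,
                 lr_final = lr_final, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine annealing learning rate
#'
#' `lr(t) = lr_final + (lr_init - lr_final) * (1 + cos(pi t / T)) / 2` for
#' epoch `t` in `0..T`: starts at `lr_init`, ends at `lr_final`.
#'
#' @param epoch Zero-based epoch index.
#' @param cfg A [train_config()].
#' @return Learning rate.
#' @export
cosine_lr <- function(epoch, cfg) {
  t_ <- min(epoch, cfg$max_epochs)
  cfg$lr_final + (cfg$lr_init - cfg$lr_final) *
    (1 + cos(pi * t_ / cfg$max_epochs)) / 2
}

# Separable bilinear interpolation of a matrix to (out_h, out_w).
resize_bilinear <- function(m, out_h, out_w) {
  m <- as.matrix(m) * 1.0
  xi <- seq(1, nrow(m), length.out = out_h)
  yi <- seq(1, ncol(m), length.out = out_w)
  rows <- apply(m, 2, function(col)
    if (nrow(m) == 1) rep(col, out_h)
    else stats::approx(seq_len(nrow(m)), col, xout = xi)$y)
  rows <- matrix(rows, out_h, ncol(m))
  out <- t(apply(rows, 1, function(row)
    if (ncol(m) == 1) rep(row, out_w)
    else stats::approx(seq_len(ncol(m)), row, xout = yi)$y))
  matrix(out, out_h, out_w)
}

#' Preprocess one feature-map image for the network
#'
#' Bilinear resize to 256 x 256, center crop to 224 x 224 (rows/columns
#' 17..240 of the resized image), scaling to `[0, 1]`, and replication to
#' three channels.
#'
#' @param img 8-bit grayscale image (any 2-D size).
#' @return Array of shape (224, 224, 3).
#' @export
preprocess_map <- function(img) {
  if (length(img) == 0) stop("empty image", call. = FALSE)
  r <- resize_bilinear(img, 256, 256)
  crop <- r[17:240, 17:240] / 255
  array(crop, dim = c(224, 224, 3))
}

map_order <- c("BS_S1", "BS_S2", "BS_S3", "BS_A")

#' Assemble a network sample from a feature-map set
#'
#' Preprocesses the four 8-bit map images (order BS_S1, BS_S2, BS_S3, BS_A)
#' and attaches the 0/1 label (malignant = 1).
#'
#' @param set A [build_feature_maps()] result with a label.
#' @return List with `x` (list of four (224, 224, 3) arrays), `y`,
#'   `frame_id`.
#' @export
prepare_sample <- function(set) {
  stopifnot(inherits(set, "feature_map_set"))
  if (is.null(set$label)) stop("feature_map_set has no label", call. = FALSE)
  list(x = lapply(set$images[map_order], preprocess_map),
       y = as.integer(set$label == "malignant"),
       frame_id = set$frame_id)
}

# --- Adam ------------------------------------------------------------------

# Flat-list parameter utilities: a model's trainable tensors as a named list.
model_params <- function(model) {
  p <- list()
  for (i in seq_along(model$backbones))
    for (j in seq_along(model$backbones[[i]])) {
      p[[sprintf("bb%d_W%d", i, j)]] <- model$backbones[[i]][[j]]$W
      p[[sprintf("bb%d_b%d", i, j)]] <- model$backbones[[i]][[j]]$b
    }
  if (!is.null(model$att)) for (nm in names(model$att))
    p[[paste0("att_", nm)]] <- model$att[[nm]]
  p$head_W <- model$head$W
  p$head_b <- model$head$b
  p
}

set_model_params <- function(model, p) {
  for (i in seq_along(model$backbones))
    for (j in seq_along(model$backbones[[i]])) {
      model$backbones[[i]][[j]]$W <- p[[sprintf("bb%d_W%d", i, j)]]
      model$backbones[[i]][[j]]$b <- p[[sprintf("bb%d_b%d", i, j)]]
    }
  if (!is.null(model$att)) for (nm in names(model$att))
    model$att[[nm]] <- p[[paste0("att_", nm)]]
  model$head$W <- p$head_W
  model$head$b <- p$head_b
  model
}

adam_init <- function(params)
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# --- batch forward/backward ------------------------------------------------

# Forward + backward over one batch of samples; returns loss components and
# the gradient list aligned with model_params().
batch_grad <- function(model, batch) {
  cfg <- model$cfg
  K <- cfg$K
  n <- length(batch)
  outs <- lapply(batch, function(s) forward_msnet(s$x, model,
                                                  keep_cache = TRUE))
  y <- vapply(batch, `[[`, numeric(1), "y")
  p <- vapply(outs, `[[`, numeric(1), "prob")
  loss_att <- attention_loss(pmin(pmax(p, 1e-7), 1 - 1e-7), y,
                             literal_negative = cfg$literal_negative)
  # SM over all branch embeddings of the batch
  loss_sm <- 0; dF_all <- NULL
  if (cfg$use_sm) {
    F_ <- do.call(rbind, lapply(outs, `[[`, "H"))
    types <- rep(seq_len(K), times = n)
    loss_sm <- sm_loss(F_, types, tau = cfg$tau, reduce = "mean")
    dF_all <- cfg$lambda_sm * sm_loss_grad(F_, types, tau = cfg$tau,
                                           reduce = "mean")
  }
  # accumulate gradients
  zeros <- lapply(model_params(model), function(x) x * 0)
  grads <- zeros
  add <- function(nm, g) grads[[nm]] <<- grads[[nm]] + g
  for (i in seq_len(n)) {
    o <- outs[[i]]
    pr <- softmax(o$logits)
    tgt <- c(1 - y[i], y[i])
    if (cfg$literal_negative) tgt <- rev(tgt)
    dlogits <- (pr - tgt) / n
    add("head_W", dlogits %o% o$z)
    add("head_b", dlogits)
    dz <- as.numeric(crossprod(model$head$W, dlogits))
    if (cfg$use_fatt) {
      ab <- gated_attention_backward(o$att, model$att, dz)
      dH <- ab$dH
      for (nm in names(ab$grads)) add(paste0("att_", nm), ab$grads[[nm]])
    } else {
      dH <- matrix(rep(dz / K, each = K), K)
    }
    if (cfg$use_sm) dH <- dH + dF_all[((i - 1) * K + 1):(i * K), ,
                                      drop = FALSE]
    for (k in seq_len(K)) {
      bi <- if (cfg$share_weights) 1 else k
      wts <- model$backbones[[bi]]
      g <- tinycnn_backward(o$fwd[[k]], dH[k, ], wts)
      for (j in seq_along(g)) {
        add(sprintf("bb%d_W%d", bi, j), g[[j]]$W)
        add(sprintf("bb%d_b%d", bi, j), g[[j]]$b)
      }
    }
  }
  tl <- total_loss(loss_att, loss_sm, cfg)
  list(grads = grads, loss = tl)
}

# Mean total loss (and scores) of a dataset under the current weights.
eval_dataset <- function(model, data) {
  cfg <- model$cfg
  outs <- lapply(data, function(s) forward_msnet(s$x, model))
  y <- vapply(data, `[[`, numeric(1), "y")
  p <- vapply(outs, `[[`, numeric(1), "prob")
  loss_att <- attention_loss(pmin(pmax(p, 1e-7), 1 - 1e-7), y,
                             literal_negative = cfg$literal_negative)
  loss_sm <- 0
  if (cfg$use_sm) {
    F_ <- do.call(rbind, lapply(outs, `[[`, "H"))
    types <- rep(seq_len(cfg$K), times = length(data))
    loss_sm <- sm_loss(F_, types, tau = cfg$tau, reduce = "mean")
  }
  a <- t(vapply(outs, `[[`, numeric(cfg$K), "a"))
  list(loss = total_loss(loss_att, loss_sm, cfg)$total, scores = p,
       labels = y, attention = a)
}

#' Train the multi-map classifier
#'
#' Seeded, deterministic training with the Adam optimizer under a cosine
#' annealing schedule from `lr_init` to `lr_final`. Training stops when the
#' validation loss has not improved for `patience` epochs (or at
#' `max_epochs`); the returned model is the best-validation checkpoint.
#'
#' @param train_data,val_data Lists of [prepare_sample()] samples; both
#'   classes must be present in the training data.
#' @param cfg A [net_config()] with a runnable backbone.
#' @param train_cfg A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return An object of class `msnet`: the fitted model, configs, and a
#'   per-epoch `history` data.frame (lr, train/val loss, val AUC).
#' @export
train_msnet <- function(train_data, val_data, cfg = net_config("tinycnn"),
                        train_cfg = train_config(), verbose = FALSE) {
  y_tr <- vapply(train_data, `[[`, numeric(1), "y")
  if (length(unique(y_tr)) < 2)
    stop("training data must contain both classes", call. = FALSE)
  model <- msnet_init(cfg, seed = train_cfg$seed)
  params <- model_params(model)
  state <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0)
  hist <- list()
  for (epoch in seq_len(train_cfg$max_epochs)) {
    lr <- cosine_lr(epoch - 1, train_cfg)
    ord <- with_seed(derive_seed(train_cfg$seed, 1000 + epoch),
                     sample(length(train_data)))
    tr_loss <- 0; nb <- 0
    for (start in seq(1, length(ord), by = train_cfg$batch_size)) {
      idx <- ord[start:min(start + train_cfg$batch_size - 1, length(ord))]
      bg <- batch_grad(model, train_data[idx])
      st <- adam_step(params, bg$grads, state, lr)
      params <- st$params; state <- st$state
      model <- set_model_params(model, params)
      tr_loss <- tr_loss + bg$loss$total; nb <- nb + 1
    }
    ev <- eval_dataset(model, val_data)
    val_auc <- if (length(unique(ev$labels)) > 1)
      roc_auc(ev$scores, ev$labels)$auc else NA_real_
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                train_loss = tr_loss / nb,
                                val_loss = ev$loss, val_auc = val_auc)
    if (verbose)
      message(sprintf("epoch %d lr %.5f train %.4f val %.4f auc %s",
                      epoch, lr, tr_loss / nb, ev$loss,
                      ifelse(is.na(val_auc), "NA", sprintf("%.3f", val_auc))))
    if (ev$loss < best$loss - 1e-8)
      best <- list(loss = ev$loss, params = params, epoch = epoch)
    if (epoch - best$epoch >= train_cfg$patience) break
  }
  model <- set_model_params(model, best$params)
  structure(list(model = model, cfg = cfg, train_cfg = train_cfg,
                 history = do.call(rbind, hist),
                 best_epoch = best$epoch, best_val_loss = best$loss),
            class = "msnet")
}

#' @export
print.msnet <- function(x, ...) {
  cat(sprintf("<msnet> backbone %s, K=%d, %s%s%s\n",
              x$cfg$backbone, x$cfg$K,
              if (x$cfg$share_weights) "weight-sharing" else "independent branches",
              if (x$cfg$use_fatt) " + F-ATT" else "",
              if (x$cfg$use_sm) " + SM" else ""))
  cat(sprintf("  trained %d epochs, best epoch %d (val loss %.4f)\n",
              nrow(x$history), x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' @export
summary.msnet <- function(object, ...) {
  print(object)
  cat(sprintf("  trainable parameters: %d\n", count_parameters(object$cfg)))
  cat("  history (last rows):\n")
  print(utils::tail(object$history, 3), row.names = FALSE)
  invisible(object)
}

#' Predict scores for a dataset
#'
#' Positive-class probabilities and per-frame attention weights under the
#' fitted model. Evaluation is deterministic.
#'
#' @param object An `msnet` fit.
#' @param newdata List of [prepare_sample()] samples.
#' @param ... Unused.
#' @return data.frame with `frame_id`, `score`, `label` (if present) and the
#'   K attention weights `a_1..a_K`.
#' @export
predict.msnet <- function(object, newdata, ...) {
  ev <- eval_dataset(object$model, newdata)
  out <- data.frame(
    frame_id = vapply(newdata, function(s) s$frame_id %||% NA_character_,
                      character(1)),
    score = ev$scores, label = ev$labels)
  colnames(ev$attention) <- paste0("a_", seq_len(ncol(ev$attention)))
  cbind(out, ev$attention)
}

#' Mean attention weight per feature map over a dataset
#'
#' The per-map importance coefficients: means of the attention simplex
#' weights, which again sum to 1.
#'
#' @param fit An `msnet` fit.
#' @param data List of samples.
#' @return Named numeric vector over BS_S1, BS_S2, BS_S3, BS_A.
#' @export
importance_report <- function(fit, data) {
  ev <- eval_dataset(fit$model, data)
  stats::setNames(colMeans(ev$attention), map_order[seq_len(fit$cfg$K)])
}

#' Evaluate a fitted model on a dataset
#'
#' Scores the dataset, applies the decision threshold, and assembles the full
#' metrics report including ROC/AUC.
#'
#' @param fit An `msnet` fit.
#' @param data List of samples.
#' @param threshold Decision threshold (default 0.5).
#' @return A `metrics_report` with `auc` and `roc_points` filled.
#' @export
evaluate_model <- function(fit, data, threshold = 0.5) {
  ev <- eval_dataset(fit$model, data)
  rep_ <- compute_metrics(confusion_at_threshold(ev$scores, ev$labels,
                                                 threshold))
  if (length(unique(ev$labels)) > 1) {
    ra <- roc_auc(ev$scores, ev$labels)
    rep_$auc <- ra$auc
    rep_$roc_points <- ra$roc_points
  }
  rep_
}
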