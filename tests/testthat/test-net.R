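rand_att <- function(L, M, seed = 0) {
  set.seed(seed)
  list(V = matrix(rnorm(L * M), L, M), U = matrix(rnorm(L * M), L, M),
       w = rnorm(L))
}

test_that("gated attention outputs a simplex and fuses by weighted sum", {
  # 1000 random trials: positivity, unit sum, z = sum a_k h_k
  params <- rand_att(6, 10)
  set.seed(1)
  for (trial in 1:1000) {
    K <- sample(2:6, 1)
    H <- matrix(rnorm(K * 10), K, 10)
    out <- gated_attention(H, params)
    expect_true(all(out$a > 0))
    expect_equal(sum(out$a), 1, tolerance = 1e-6)
    expect_equal(out$z, as.numeric(crossprod(H, out$a)), tolerance = 1e-12)
  }
})

test_that("attention degenerate cases: singleton and identical instances", {
  params <- rand_att(8, 12, seed = 2)
  h <- matrix(rnorm(12), 1, 12)
  out1 <- gated_attention(h, params)
  expect_equal(out1$a, 1)
  expect_equal(out1$z, as.numeric(h))
  H <- matrix(rep(rnorm(12), each = 4), 4, 12)
  out4 <- gated_attention(H, params)
  expect_equal(out4$a, rep(0.25, 4), tolerance = 1e-12)
})

test_that("attention is permutation-equivariant and z is invariant", {
  params <- rand_att(8, 12, seed = 3)
  set.seed(4)
  H <- matrix(rnorm(4 * 12), 4, 12)
  perm <- c(3, 1, 4, 2)
  out <- gated_attention(H, params)
  outp <- gated_attention(H[perm, ], params)
  expect_equal(outp$a, out$a[perm], tolerance = 1e-12)
  expect_equal(outp$z, out$z, tolerance = 1e-12)
})

test_that("attention loss is standard batch BCE with clamping", {
  expect_lt(attention_loss(1 - 1e-7, 1), 1e-6)  # near-perfect prediction
  expect_equal(attention_loss(0.5, 1), log(2), tolerance = 1e-12)
  set.seed(5)
  p <- runif(20); y <- rbinom(20, 1, 0.5)
  expect_gte(attention_loss(p, y), 0)
  expect_warning(attention_loss(c(0.5, 1), c(1, 1)), "clamped")
  # literal negative-probability reading flips the convention
  expect_equal(attention_loss(0.2, 1, literal_negative = TRUE),
               attention_loss(0.8, 1))
})

test_that("cosine similarity is the normalized dot product", {
  f <- c(3, 4)
  expect_equal(cosine_similarity(f, f), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 2)), 0)
  expect_equal(cosine_similarity(f, -f), -1)
  expect_error(cosine_similarity(f, c(0, 0)), "zero")
})

test_that("SM loss matches its closed form for identical embeddings", {
  for (K in c(2, 4)) for (n_rep in c(1, 3)) {
    n <- K * n_rep
    f <- matrix(rep(c(1, 2, 3), each = n), n, 3)
    types <- rep(seq_len(K), times = n_rep)
    got <- sm_loss(f, types, tau = 0.1)
    want <- -n * log(1 / K) - n * (K - 1) * log(1 - 1 / K)
    expect_equal(got, want, tolerance = 1e-10)
  }
  expect_error(sm_loss(matrix(1, 2, 3), c(1, 1)), "2 map types")
})

test_that("SM loss prefers separated prototypes over permuted labels", {
  K <- 4; n_rep <- 8
  protos <- diag(K)  # mutually orthogonal prototypes
  f <- protos[rep(seq_len(K), times = n_rep), ]
  types <- rep(seq_len(K), times = n_rep)
  aligned <- sm_loss(f, types, tau = 0.1)
  permuted_types <- local({ set.seed(0); sample(types) })
  permuted <- sm_loss(f, permuted_types, tau = 0.1)
  expect_lt(aligned, permuted)
  expect_gte(aligned, 0)
})

test_that("total loss combines the two objectives linearly", {
  cfg <- net_config("tinycnn", lambda_sm = 0.1)
  expect_equal(total_loss(0.5, 2.0, cfg)$total, 0.7)
  cfg0 <- net_config("tinycnn", lambda_sm = 0)
  expect_equal(total_loss(0.5, 2.0, cfg0)$total, 0.5)
  cfg_nosm <- net_config("tinycnn", use_sm = FALSE)
  expect_equal(total_loss(0.5, 99, cfg_nosm)$total, 0.5)
})

test_that("weight sharing routes identical inputs to identical embeddings", {
  cfg <- net_config("tinycnn", K = 3)
  model <- msnet_init(cfg, seed = 1)
  set.seed(6)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  bf <- backbone_features(list(img, img, img), model)
  expect_equal(bf$H[1, ], bf$H[2, ], tolerance = 1e-14)
  expect_equal(bf$H[1, ], bf$H[3, ], tolerance = 1e-14)
  expect_equal(length(bf$H[1, ]), 128)
  # independent branches generally disagree
  model2 <- msnet_init(net_config("tinycnn", K = 3, share_weights = FALSE),
                       seed = 1)
  bf2 <- backbone_features(list(img, img, img), model2)
  expect_false(isTRUE(all.equal(bf2$H[1, ], bf2$H[2, ])))
})

test_that("full forward is deterministic and returns valid probabilities", {
  cfg <- net_config("tinycnn")
  model <- msnet_init(cfg, seed = 2)
  s <- random_samples(1, K = 4, hw = 16, seed = 7)[[1]]
  o1 <- forward_msnet(s$x, model)
  o2 <- forward_msnet(s$x, model)
  expect_identical(o1$prob, o2$prob)
  expect_identical(o1$a, o2$a)
  expect_gt(o1$prob, 0); expect_lt(o1$prob, 1)
  expect_equal(sum(o1$a), 1, tolerance = 1e-6)
})

test_that("parameter accounting follows the architecture arithmetic", {
  # linear M=2048 -> 2 head alone
  expect_equal(2048 * 2 + 2, 4098)
  # canonical 50-layer residual feature extractor
  expect_equal(backbone_info("resnet50")$params, 23508032)
  # sharing removes exactly (K - 1) backbone copies
  for (bb in c("tinycnn", "resnet50", "vgg19", "resnet101")) {
    cfg_s <- net_config(bb, K = 4)
    cfg_i <- net_config(bb, K = 4, share_weights = FALSE)
    expect_equal(count_parameters(cfg_i) - count_parameters(cfg_s),
                 3 * backbone_info(bb)$params)
  }
  # tinycnn count equals the actual number of initialized weights
  model <- msnet_init(net_config("tinycnn"), seed = 0)
  n_actual <- sum(vapply(bisqus:::model_params(model), length, numeric(1)))
  expect_equal(n_actual, count_parameters(net_config("tinycnn")))
  expect_error(backbone_info("swin"), "not implemented")
  expect_error(backbone_info("nonesuch"), "unknown")
})

test_that("weight-sharing ratio for the pinned ResNet-50 setup is 25.83%", {
  cfg <- net_config("resnet50", K = 4, L = 256)
  expect_equal(round(shared_ratio(cfg), 2), 25.83)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- net_config("tinycnn", K = 3, L = 8, use_sm = FALSE)
  model <- msnet_init(cfg, seed = 1)
  batch <- random_samples(2, K = 3, hw = 16, seed = 8)
  bg <- bisqus:::batch_grad(model, batch)
  loss_of <- function(m) {
    outs <- lapply(batch, function(s) forward_msnet(s$x, m))
    attention_loss(vapply(outs, `[[`, numeric(1), "prob"),
                   vapply(batch, `[[`, numeric(1), "y"))
  }
  p0 <- bisqus:::model_params(model)
  eps <- 1e-5
  set.seed(9)
  for (nm in c("bb1_W1", "bb1_W3", "att_V", "att_w", "head_W")) {
    i <- sample(length(p0[[nm]]), 1)
    pp <- p0; pp[[nm]][i] <- pp[[nm]][i] + eps
    lp <- loss_of(bisqus:::set_model_params(model, pp))
    pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
    lm <- loss_of(bisqus:::set_model_params(model, pp))
    expect_equal(bg$grads[[nm]][i], (lp - lm) / (2 * eps), tolerance = 1e-4)
  }
})
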