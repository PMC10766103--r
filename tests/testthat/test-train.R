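test_that("preprocessing yields a 3 x 224 x 224-equivalent tensor in [0, 1]", {
  set.seed(0)
  img <- matrix(sample.int(256, 40 * 12, TRUE) - 1, 40, 12)
  x <- preprocess_map(img)
  expect_equal(dim(x), c(224, 224, 3))
  expect_true(all(x >= 0) && all(x <= 1))
  expect_identical(x[, , 1], x[, , 3])
  # constant 255 -> constant 1.0
  expect_true(all(preprocess_map(matrix(255, 7, 9)) == 1))
  # a 256 x 256 input skips resampling, so the crop keeps rows/cols 17..240
  big <- matrix(runif(256 * 256, 0, 255), 256)
  expect_equal(preprocess_map(big)[, , 1], big[17:240, 17:240] / 255,
               tolerance = 1e-12)
  expect_error(preprocess_map(matrix(numeric(0), 0, 0)), "empty")
})

test_that("cosine annealing runs from lr_init to lr_final", {
  cfg <- train_config(max_epochs = 20)
  expect_equal(cosine_lr(0, cfg), 0.002)
  expect_equal(cosine_lr(20, cfg), 1e-4)
  lrs <- vapply(0:20, cosine_lr, numeric(1), cfg = cfg)
  expect_true(all(diff(lrs) < 0))
  expect_equal(cosine_lr(10, cfg), 1e-4 + (0.002 - 1e-4) / 2)
  expect_error(train_config(lr_init = 1e-5, lr_final = 1e-3), "lr_final")
})

test_that("confusion counting at a threshold is exact", {
  cc <- confusion_at_threshold(c(0.9, 0.1), c(1, 0), 0.5)
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 1, TN = 1, FP = 0, FN = 0))
  set.seed(1)
  sc <- runif(50); y <- rbinom(50, 1, 0.4)
  cc2 <- confusion_at_threshold(sc, y, 0.3)
  expect_equal(cc2$TP + cc2$TN + cc2$FP + cc2$FN, 50)
  # threshold 0 predicts everything positive
  cc0 <- confusion_at_threshold(sc, y, 0)
  expect_equal(cc0$FN, 0); expect_equal(cc0$TN, 0)
  expect_error(confusion_at_threshold(sc, y[-1]), "length")
})

test_that("metric ratios match independent arithmetic on random tables", {
  set.seed(2)
  for (i in 1:25) {
    cc <- confusion_counts(TP = rpois(1, 20), FP = rpois(1, 10),
                           TN = rpois(1, 20), FN = rpois(1, 10))
    m <- compute_metrics(cc)
    n <- cc$TP + cc$TN + cc$FP + cc$FN
    if (n > 0) expect_equal(m$accuracy, 100 * (cc$TP + cc$TN) / n)
    if (cc$TP + cc$FN > 0)
      expect_equal(m$sensitivity, 100 * cc$TP / (cc$TP + cc$FN))
    if (cc$TP + cc$FP > 0)
      expect_equal(m$ppv, 100 * cc$TP / (cc$TP + cc$FP))
  }
  # degenerate: a perfect 2-sample table; undefined metrics surface as NA
  m1 <- compute_metrics(confusion_counts(1, 0, 1, 0))
  expect_equal(c(m1$accuracy, m1$sensitivity, m1$specificity, m1$ppv, m1$npv),
               rep(100, 5))
  m2 <- compute_metrics(confusion_counts(0, 0, 5, 0))
  expect_true(is.na(m2$sensitivity))
  expect_true(is.na(m2$ppv))
})

test_that("rank AUC counts concordant pairs with tie correction", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  # 3 of 4 pos-neg pairs concordant
  ra <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(ra$auc, 0.75)
  expect_equal(ra$roc_points$fpr[1], 0)
  expect_equal(ra$roc_points$tpr[nrow(ra$roc_points)], 1)
  # invariance under strictly monotone transforms
  set.seed(3)
  sc <- runif(40); y <- rbinom(40, 1, 0.5)
  expect_equal(roc_auc(sc, y)$auc, roc_auc(qlogis(sc), y)$auc)
  expect_equal(roc_auc(sc, y)$auc, roc_auc(sc^3, y)$auc)
  expect_error(roc_auc(sc, rep(1, 40)), "both classes")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  sc <- c(runif(25), runif(25, 0.3, 1.2))
  y <- rep(c(0, 1), each = 25)
  want <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE)))
  expect_equal(roc_auc(sc, y)$auc, want, tolerance = 1e-12)
})

test_that("training is deterministic, learns, and stops early", {
  samples <- random_samples(12, K = 2, hw = 16, seed = 10)
  cfg <- net_config("tinycnn", K = 2, L = 8)
  tcfg <- train_config(batch_size = 4, max_epochs = 4, patience = 2, seed = 1)
  fit1 <- train_msnet(samples, samples, cfg, tcfg)
  fit2 <- train_msnet(samples, samples, cfg, tcfg)
  expect_identical(fit1$history, fit2$history)
  expect_equal(fit1$history$lr[1], 0.002)
  expect_lt(fit1$history$train_loss[4], fit1$history$train_loss[1])
  # single-class data refused
  one_class <- lapply(samples, function(s) { s$y <- 1; s })
  expect_error(train_msnet(one_class, one_class, cfg, tcfg), "both classes")
  # early stopping: patience epochs after the best validation epoch
  tcfg2 <- train_config(batch_size = 4, max_epochs = 50, patience = 2,
                        seed = 1)
  fit3 <- train_msnet(samples, samples, cfg, tcfg2)
  expect_lte(nrow(fit3$history), fit3$best_epoch + 2)
  # predict: one score per sample, in (0, 1), repeatable
  pr1 <- predict(fit1, samples)
  pr2 <- predict(fit1, samples)
  expect_identical(pr1, pr2)
  expect_equal(nrow(pr1), length(samples))
  expect_true(all(pr1$score > 0 & pr1$score < 1))
  # importance report is a mean over the attention simplex
  imp <- importance_report(fit1, samples)
  expect_equal(sum(imp), 1, tolerance = 1e-6)
  # evaluation report carries AUC
  rep_ <- evaluate_model(fit1, samples)
  expect_true(rep_$auc >= 0 && rep_$auc <= 1)
})
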