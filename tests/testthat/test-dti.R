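test_that("pair featurization enforces the 363 + 996 block contract", {
  drug <- list(features = stats::rnorm(363))
  target <- list(features = stats::rnorm(996))
  w <- featurize_pair(drug, target)
  expect_length(w, 1359L)
  expect_equal(w, c(drug$features, target$features))
  expect_error(featurize_pair(list(features = stats::rnorm(10)), target),
               "expected \\(363, 996\\)")
})

test_that("negative sampling is balanced, disjoint and deterministic", {
  pos <- data.frame(drug_id = c("D1", "D1", "D2"),
                    target_id = c("T1", "T2", "T1"))
  neg <- sample_negatives(pos, paste0("D", 1:5), paste0("T", 1:5), seed = 3)
  expect_equal(nrow(neg), nrow(pos))
  expect_equal(anyDuplicated(paste(neg$drug_id, neg$target_id)), 0L)
  expect_length(intersect(paste(neg$drug_id, neg$target_id),
                          paste(pos$drug_id, pos$target_id)), 0L)
  expect_identical(neg, sample_negatives(pos, paste0("D", 1:5),
                                         paste0("T", 1:5), seed = 3))
  expect_error(sample_negatives(data.frame(drug_id = "D1", target_id = "T1"),
                                "D1", "T1", seed = 1), "universe")
})

test_that("splits partition the data exactly with stratification", {
  y <- rep(c(0L, 1L), c(60L, 40L))
  sp <- split_dataset(y, seed = 5)
  idx <- c(sp$train, sp$validation, sp$test)
  expect_identical(sort(idx), seq_along(y))       # exact partition
  expect_equal(anyDuplicated(idx), 0L)
  expect_equal(length(sp$test), 30L)              # 30% of 100, stratified
  expect_equal(sum(y[sp$test]), 12L)              # 30% of the 40 positives
  expect_equal(length(sp$validation), 10L)
  expect_equal(sum(y[sp$validation]), 4L)
  expect_identical(sp, split_dataset(y, seed = 5))
  expect_false(identical(sp, split_dataset(y, seed = 6)))
  expect_error(split_dataset(rep(0L, 5), seed = 1), "at least 10")
})

test_that("preprocessing is fitted on training rows only and frozen", {
  set.seed(71)
  X <- matrix(stats::rnorm(120 * 40), 120, 40)
  X[, 7] <- 3                                      # zero-variance feature
  prep <- fit_preprocess(X[1:80, ], n_components = 10)
  expect_s3_class(prep, "dti_preprocess")
  expect_false(7L %in% prep$keep)
  expect_equal(prep$center, colMeans(X[1:80, ])[prep$keep])
  expect_equal(prep$scale, apply(X[1:80, ], 2, stats::sd)[prep$keep])
  expect_equal(crossprod(prep$rotation), diag(10), tolerance = 1e-10,
               ignore_attr = TRUE)
  tr <- apply_preprocess(prep, X[1:80, ])
  expect_equal(dim(tr), c(80L, 10L))
  expect_equal(colMeans(tr), rep(0, 10), tolerance = 1e-10,
               ignore_attr = TRUE)
  # transforming new rows uses the frozen statistics: no refitting
  te1 <- apply_preprocess(prep, X[81:120, ])
  prep2 <- fit_preprocess(X[1:80, ], n_components = 10)
  expect_identical(apply_preprocess(prep2, X[81:120, ]), te1)
  # non-default width falls back to the variance rule
  prep_v <- fit_preprocess(X[1:80, ], variance_threshold = 0.5)
  cum <- cumsum(stats::prcomp(scale(X[1:80, prep_v$keep]))$sdev^2)
  expect_lte(prep_v$n_components, 40L)
  expect_error(fit_preprocess(X[1:20, ], n_components = 30), "exceeds")
})

test_that("the default 1359-wide featurization reduces to 618 components", {
  set.seed(8)
  X <- matrix(stats::rnorm(700 * 1359), 700, 1359)
  prep <- fit_preprocess(X)
  expect_identical(prep$n_components, 618L)
  expect_equal(ncol(apply_preprocess(prep, X[1:5, ])), 618L)
  # fewer rows than 618: capped at rows - 1
  prep_small <- fit_preprocess(X[1:100, ])
  expect_identical(prep_small$n_components, 99L)
})

test_that("network construction matches the declared architecture", {
  cfg <- dti_config(seed = 2)
  net <- build_dti_network(618L, cfg)
  expect_identical(net$widths, c(618L, 512L, 256L, 128L, 64L, 1L))
  expect_length(net$layers, 5L)
  expect_identical(dim(net$layers[[1]]$W), c(512L, 618L))
  expect_identical(net, build_dti_network(618L, cfg))
  # the all-zero network outputs exactly 0.5
  zero <- build_dti_network(10L, cfg, init = "zero")
  p <- gwgendrug:::forward_pass(zero, matrix(stats::rnorm(30), 3, 10))[[6]]
  expect_equal(as.numeric(p), rep(0.5, 3))
  expect_error(dti_config(dropout = 1), "dropout")
  expect_error(dti_config(hidden = c(8, 0)), "positive")
})

test_that("binary cross-entropy matches hand values and clips", {
  expect_equal(bce_loss(c(1, 0), c(0.8, 0.2)), -log(0.8))
  expect_equal(bce_loss(1, 0.5), log(2))
  expect_true(is.finite(bce_loss(c(1, 0), c(0, 1))))
  expect_equal(bce_loss(c(1, 0), c(1, 0)), -log(1 - 1e-7))
  expect_error(bce_loss(c(1, 0), 0.5), "length")
})

test_that("backpropagation matches numerical gradients", {
  cfg <- dti_config(hidden = c(4L, 3L), dropout = 0, seed = 9)
  net <- build_dti_network(5L, cfg)
  set.seed(10)
  X <- matrix(stats::rnorm(6 * 5), 6, 5)
  y <- c(1, 0, 1, 1, 0, 0)
  lr <- 1e-3
  stepped <- gwgendrug:::gd_step(net, X, y, lr, dropout = 0, use_rng = FALSE)
  loss_at <- function(n) {
    p <- gwgendrug:::forward_pass(n, X)[[length(n$layers) + 1L]]
    bce_loss(y, as.numeric(p))
  }
  eps <- 1e-6
  for (l in seq_along(net$layers)) {
    for (probe in list(c(1, 1), c(nrow(net$layers[[l]]$W),
                                  ncol(net$layers[[l]]$W)))) {
      analytic <- (net$layers[[l]]$W[probe[1], probe[2]] -
                     stepped$layers[[l]]$W[probe[1], probe[2]]) / lr
      plus <- net; plus$layers[[l]]$W[probe[1], probe[2]] <-
        plus$layers[[l]]$W[probe[1], probe[2]] + eps
      minus <- net; minus$layers[[l]]$W[probe[1], probe[2]] <-
        minus$layers[[l]]$W[probe[1], probe[2]] - eps
      numeric_g <- (loss_at(plus) - loss_at(minus)) / (2 * eps)
      expect_equal(analytic, numeric_g, tolerance = 1e-4)
    }
  }
})

test_that("a gradient step reduces the training loss", {
  cfg <- dti_config(hidden = c(8L), dropout = 0, seed = 4)
  net <- build_dti_network(6L, cfg)
  set.seed(12)
  X <- matrix(stats::rnorm(40 * 6), 40, 6)
  y <- as.integer(X[, 1] + X[, 2] > 0)
  before <- bce_loss(y, as.numeric(gwgendrug:::forward_pass(net, X)[[3]]))
  for (i in 1:50) {
    net <- gwgendrug:::gd_step(net, X, y, 0.05, dropout = 0, use_rng = FALSE)
  }
  after <- bce_loss(y, as.numeric(gwgendrug:::forward_pass(net, X)[[3]]))
  expect_lt(after, before)
})

test_that("training early-stops on the validation loss and restores the best weights", {
  set.seed(33)
  n <- 200L
  X <- matrix(stats::rnorm(n * 8), n, 8)
  y <- as.integer(X[, 1] - X[, 2] > 0)
  cfg <- dti_config(hidden = c(16L, 8L), dropout = 0, learning_rate = 0.05,
                    max_epochs = 100L, patience = 5L, batch_size = 32L,
                    seed = 3)
  net <- train_dti_network(X[1:140, ], y[1:140], X[141:200, ], y[141:200],
                           cfg)
  h <- net$history
  expect_lte(nrow(h), 100L)
  expect_gte(net$best_epoch, 1L)
  # the restored weights reproduce the best recorded validation loss
  va <- bce_loss(y[141:200],
                 as.numeric(gwgendrug:::forward_pass(
                   net, X[141:200, ])[[length(net$layers) + 1L]]))
  expect_equal(va, min(h$val_loss), tolerance = 1e-10)
  # stopping happened `patience` epochs after the best one (unless budget hit)
  if (nrow(h) < 100L) expect_equal(nrow(h), net$best_epoch + 5L)
  expect_identical(net$history,
                   train_dti_network(X[1:140, ], y[1:140], X[141:200, ],
                                     y[141:200], cfg)$history)
})

test_that("end-to-end training separates a separable dataset", {
  # The class signal is one direction in 1359 features, so the dataset must
  # be large enough for any learner to estimate it: with ~100 training rows
  # even the Bayes-direction estimate is noise-dominated (its sampling error
  # has norm ~ sqrt(2 * 1359 / n_per_class), versus signal norm 6). 1000
  # pairs give 700 training rows, and the budgeted gradient-descent schedule
  # then reaches the generator's Bayes rate (~Phi(3)) comfortably.
  ds <- generate_dti_dataset(500, class_separation = 6, seed = 14)
  cfg <- dti_config(max_epochs = 300L, learning_rate = 0.01,
                    batch_size = 64L, seed = 14)
  model <- dti_train(ds, cfg)
  expect_s3_class(model, "dti_model")
  expect_gte(model$metrics[["test_accuracy"]], 0.9)
  expect_gte(model$metrics[["test_auc"]], 0.95)
  # preprocessing statistics come from the training rows only (no leakage)
  tr_rows <- ds$features[model$splits$train, model$preprocess$keep]
  expect_equal(model$preprocess$center, colMeans(tr_rows),
               ignore_attr = TRUE)
  expect_output(print(model), "test accuracy")
  # predict() reproduces the test-set probabilities
  p <- predict(model, ds$features[model$splits$test, , drop = FALSE])
  acc <- mean((p > 0.5) == (ds$pairs$label[model$splits$test] == 1L))
  expect_equal(acc, unname(model$metrics["test_accuracy"]))
})

test_that("the rank AUC matches the pROC oracle", {
  set.seed(20)
  for (i in 1:5) {
    scores <- stats::rnorm(60)
    labels <- stats::rbinom(60, 1, 0.4)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_rank(scores, labels), ref, tolerance = 1e-12)
  }
  expect_equal(auc_rank(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc_rank(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0)
  expect_equal(auc_rank(c(1, 1), c(0, 1)), 0.5)  # ties count half
  expect_true(is.na(auc_rank(1:3, c(1, 1, 1))))
})

test_that("cross-validation folds partition and report per-fold metrics", {
  ds <- generate_dti_dataset(30, class_separation = 6, seed = 22)
  cfg <- dti_config(hidden = c(16L, 8L), max_epochs = 15L, batch_size = 16L,
                    seed = 22)
  cv <- dti_cross_validate(ds, cfg, folds = 4L)
  expect_s3_class(cv, "dti_cv")
  expect_equal(nrow(cv$per_fold), 4L)
  expect_identical(sort(unique(cv$fold_id)), 1:4)
  # stratified: each class spreads 8/8/7/7 over the folds
  expect_equal(tabulate(cv$fold_id), c(16L, 16L, 14L, 14L))
  expect_true(all(tapply(ds$pairs$label, cv$fold_id, mean) == 0.5))
  expect_equal(cv$accuracy_mean, mean(cv$per_fold$accuracy))
  expect_output(print(cv), "4-fold CV")
  expect_error(dti_cross_validate(ds, cfg, folds = 40L), "too few")
  # accuracy property on a dataset large enough to estimate the class
  # direction (see the end-to-end test for the sizing argument)
  big <- generate_dti_dataset(240, class_separation = 6, seed = 22)
  cv_big <- dti_cross_validate(big, dti_config(hidden = c(64L, 32L),
                                               max_epochs = 100L,
                                               learning_rate = 0.01,
                                               batch_size = 64L, seed = 22),
                               folds = 4L)
  expect_gte(cv_big$accuracy_mean, 0.8)
})

test_that("candidate selection is strictly above the threshold", {
  cfg <- dti_config(seed = 1)
  X <- matrix(stats::rnorm(40 * 20), 40, 20)
  prep <- fit_preprocess(X, n_components = 5)
  zero <- build_dti_network(5L, cfg, init = "zero")
  model <- structure(list(network = zero, preprocess = prep, config = cfg),
                     class = "dti_model")
  pairs <- data.frame(drug_id = paste0("D", 1:40),
                      target_id = rep(paste0("T", 1:4), 10))
  # the zero network scores every pair exactly 0.5: none strictly exceeds it
  expect_equal(nrow(predict_candidates(model, pairs, X)), 0L)
  got <- predict_candidates(model, pairs, X, threshold = 0.4)
  expect_equal(nrow(got), 40L)
  expect_true(all(got$probability > 0.4))
  # sorted by target then decreasing probability
  expect_identical(got$target_id, got$target_id[order(got$target_id)])
})
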