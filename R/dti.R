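# Chemogenomic drug-target interaction (DTI) classifier: a fully connected
# feed-forward network on concatenated drug + protein descriptor vectors.
# Architecture: input -> 512 -> 256 -> 128 -> 64 -> 1 with ReLU hidden
# activations, dropout on each hidden layer, sigmoid output; binary
# cross-entropy loss minimized by mini-batch gradient descent (learning rate
# 0.001) with early stopping on a validation split.

DRUG_BLOCK <- 363L
TARGET_BLOCK <- 996L

#' Build a drug-target pair feature vector
#'
#' Applies a featurizer to a drug record and a target record and
#' concatenates the two blocks, `w = [d_1..d_X, t_1..t_Y]`. The default
#' block-size contract is X = 363 drug descriptors and Y = 996 protein
#' descriptors (1359 total); a plugged featurizer must match the declared
#' sizes or the call errors.
#'
#' @param drug,target records understood by `featurizer`.
#' @param featurizer function(drug, target) returning
#'   `list(drug = <numeric>, target = <numeric>)`; the default expects each
#'   record to carry its descriptor vector in `$features`.
#' @param sizes integer pair of expected block lengths.
#' @return numeric vector of length `sum(sizes)`.
#' @export
featurize_pair <- function(drug, target,
                           featurizer = default_featurizer,
                           sizes = c(DRUG_BLOCK, TARGET_BLOCK)) {
  blocks <- featurizer(drug, target)
  if (length(blocks$drug) != sizes[1] || length(blocks$target) != sizes[2]) {
    stop_input("featurizer emitted blocks (%d, %d); expected (%d, %d)",
               length(blocks$drug), length(blocks$target),
               sizes[1], sizes[2])
  }
  c(blocks$drug, blocks$target)
}

#' @rdname featurize_pair
#' @export
default_featurizer <- function(drug, target) {
  list(drug = drug$features, target = target$features)
}

#' Sample negative drug-target pairs
#'
#' Draws, uniformly at random, exactly as many unknown pairs (pairs absent
#' from the positive set) as there are positives, so classes are balanced.
#' Unknown pairs are treated as negatives by convention; they are not
#' experimentally verified non-interactions.
#'
#' @param positives data.frame with `drug_id`, `target_id`.
#' @param drug_ids,target_ids the pair universe.
#' @param seed integer seed.
#' @return data.frame of negative pairs (`drug_id`, `target_id`).
#' @export
sample_negatives <- function(positives, drug_ids, target_ids, seed) {
  n <- nrow(positives)
  universe <- as.double(length(drug_ids)) * length(target_ids)
  if (universe - n < n) stop_input("pair universe too small")
  pos_key <- paste(positives$drug_id, positives$target_id, sep = "\r")
  with_seed(seed, {
    got <- character(0); di <- character(0); ti <- character(0)
    while (length(got) < n) {
      need <- n - length(got)
      d <- drug_ids[sample.int(length(drug_ids), need * 2L, replace = TRUE)]
      t <- target_ids[sample.int(length(target_ids), need * 2L,
                                 replace = TRUE)]
      k <- paste(d, t, sep = "\r")
      keep <- !(k %in% pos_key) & !(k %in% got) & !duplicated(k)
      d <- d[keep][seq_len(min(need, sum(keep)))]
      t <- t[keep][seq_len(min(need, sum(keep)))]
      k <- k[keep][seq_len(min(need, sum(keep)))]
      di <- c(di, d); ti <- c(ti, t); got <- c(got, k)
    }
    data.frame(drug_id = di, target_id = ti, stringsAsFactors = FALSE)
  })
}

#' Stratified train / validation / test split
#'
#' 70% of the data train the model, of which 10 percentage points of the
#' whole dataset are carved out as the validation set for early stopping;
#' the remaining 30% are the test set. Splits are label-stratified and
#' disjoint, and their union is the input.
#'
#' @param labels 0/1 vector.
#' @param seed integer seed.
#' @param test_frac,val_frac fractions of the whole dataset.
#' @return list of integer index vectors `train`, `validation`, `test`.
#' @export
split_dataset <- function(labels, seed, test_frac = 0.3, val_frac = 0.1) {
  n <- length(labels)
  if (n < 10L) stop_input("need at least 10 pairs to split")
  with_seed(seed, {
    train <- integer(0); val <- integer(0); test <- integer(0)
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      n_c <- length(idx)
      n_test <- round(test_frac * n_c)
      n_val <- round(val_frac * n_c)
      test <- c(test, idx[seq_len(n_test)])
      val <- c(val, idx[n_test + seq_len(n_val)])
      train <- c(train, idx[-seq_len(n_test + n_val)])
    }
    if (!length(train) || !length(val) || (test_frac > 0 && !length(test))) {
      stop_input("a split came out empty; need more data")
    }
    list(train = sort(train), validation = sort(val), test = sort(test))
  })
}

#' Fit / apply feature preprocessing
#'
#' Z-scores every feature (zero-variance features are dropped) and projects
#' onto the leading principal components. Statistics and basis come from the
#' supplied (training) rows only; [apply_preprocess()] transforms any rows
#' with the frozen state. With the default 1359-wide featurization the
#' component count defaults to 618 (capped at rows - 1); otherwise the
#' smallest count explaining 95% of the variance is used.
#'
#' @param X numeric matrix (rows = training pairs).
#' @param n_components override for the projection dimension.
#' @param variance_threshold used when no default applies.
#' @return an object of class `dti_preprocess` with `center`, `scale`,
#'   `rotation`, `keep` (retained feature indices), `n_components`.
#' @export
fit_preprocess <- function(X, n_components = NULL,
                           variance_threshold = 0.95) {
  n <- nrow(X); p <- ncol(X)
  cap <- min(n - 1L, p)
  if (!is.null(n_components) && n_components > cap) {
    stop_input("n_components (%d) exceeds min(rows - 1, features) = %d",
               n_components, cap)
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  keep <- which(scl > 0)
  Xs <- scale(X[, keep, drop = FALSE], center = ctr[keep],
              scale = scl[keep])
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  if (is.null(n_components)) {
    if (p == DRUG_BLOCK + TARGET_BLOCK) {
      n_components <- min(618L, cap, ncol(pc$rotation))
    } else {
      cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
      n_components <- min(which(cum >= variance_threshold)[1L], cap)
    }
  }
  n_components <- min(n_components, ncol(pc$rotation))
  structure(list(center = ctr[keep], scale = scl[keep], keep = keep,
                 rotation = pc$rotation[, seq_len(n_components),
                                        drop = FALSE],
                 n_components = as.integer(n_components)),
            class = "dti_preprocess")
}

#' @rdname fit_preprocess
#' @param state a `dti_preprocess`.
#' @export
apply_preprocess <- function(state, X) {
  Xs <- scale(X[, state$keep, drop = FALSE], center = state$center,
              scale = state$scale)
  Xs %*% state$rotation
}

#' DTI model configuration
#'
#' @param hidden hidden-layer widths.
#' @param dropout dropout rate applied to each hidden layer during training.
#' @param learning_rate gradient-descent step size.
#' @param max_epochs,patience early-stopping budget: training stops once the
#'   validation loss has not improved for `patience` epochs.
#' @param batch_size mini-batch size.
#' @param threshold candidate-selection probability cutoff.
#' @param seed integer seed governing weight initialization, batch order and
#'   dropout masks.
#' @return list of class `dti_config`.
#' @export
dti_config <- function(hidden = c(512L, 256L, 128L, 64L), dropout = 0.2,
                       learning_rate = 0.001, max_epochs = 200L,
                       patience = 10L, batch_size = 128L, threshold = 0.5,
                       seed = 1L) {
  if (any(hidden <= 0)) stop_input("hidden widths must be positive")
  if (dropout < 0 || dropout >= 1) stop_input("dropout must be in [0, 1)")
  structure(list(hidden = as.integer(hidden), dropout = dropout,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 threshold = threshold, seed = as.integer(seed)),
            class = "dti_config")
}

#' Build an untrained DTI network
#'
#' Allocates the layer stack `input -> hidden ... -> 1`. Weights use scaled
#' normal (He) initialization drawn under the config seed; `init = "zero"`
#' gives the all-zero network (whose sigmoid output is identically 0.5).
#'
#' @param input_width width of the (preprocessed) input layer.
#' @param config a [dti_config()].
#' @param init `"he"` or `"zero"`.
#' @return list of class `dti_network` with `W`, `b` per layer.
#' @export
build_dti_network <- function(input_width, config = dti_config(),
                              init = c("he", "zero")) {
  init <- match.arg(init)
  widths <- c(as.integer(input_width), config$hidden, 1L)
  make <- function() {
    lapply(seq_len(length(widths) - 1L), function(l) {
      fan_in <- widths[l]
      W <- if (init == "zero") {
        matrix(0, widths[l + 1L], fan_in)
      } else {
        matrix(stats::rnorm(widths[l + 1L] * fan_in, 0,
                            sqrt(2 / fan_in)),
               widths[l + 1L], fan_in)
      }
      list(W = W, b = numeric(widths[l + 1L]))
    })
  }
  layers <- if (init == "zero") make() else with_seed(config$seed, make())
  structure(list(layers = layers, widths = widths, config = config),
            class = "dti_network")
}

relu <- function(x) x * (x > 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# forward pass; X is n x d. Returns activations per layer (post-activation),
# with inputs cached for backprop. Dropout masks (inverted dropout) are
# applied to hidden activations when `masks` is supplied.
forward_pass <- function(net, X, masks = NULL) {
  L <- length(net$layers)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (l in seq_len(L)) {
    lay <- net$layers[[l]]
    z <- acts[[l]] %*% t(lay$W) + matrix(lay$b, nrow(X), length(lay$b),
                                         byrow = TRUE)
    a <- if (l < L) relu(z) else sigmoid(z)
    if (l < L && !is.null(masks)) a <- a * masks[[l]]
    acts[[l + 1L]] <- a
  }
  acts
}

#' Binary cross-entropy loss
#'
#' Mean of `-(p * log(phat) + (1 - p) * log(1 - phat))`; predictions are
#' clipped to `[1e-7, 1 - 1e-7]` for numerical stability.
#'
#' @param labels 0/1 vector.
#' @param predictions probabilities in `[0, 1]`.
#' @return scalar loss.
#' @export
bce_loss <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop_input("labels and predictions differ in length")
  }
  p <- pmin(pmax(predictions, 1e-7), 1 - 1e-7)
  mean(-(labels * log(p) + (1 - labels) * log(1 - p)))
}

# one gradient step on a mini-batch; returns updated layers
gd_step <- function(net, X, y, lr, dropout, use_rng) {
  L <- length(net$layers)
  masks <- NULL
  if (dropout > 0 && use_rng) {
    masks <- lapply(seq_len(L - 1L), function(l) {
      m <- matrix(stats::rbinom(nrow(X) * nrow(net$layers[[l]]$W), 1L,
                                1 - dropout),
                  nrow(X), nrow(net$layers[[l]]$W))
      m / (1 - dropout)
    })
  }
  acts <- forward_pass(net, X, masks)
  n <- nrow(X)
  phat <- pmin(pmax(acts[[L + 1L]], 1e-7), 1 - 1e-7)
  # d(BCE)/d(z_out) with sigmoid output collapses to (phat - y) / n
  delta <- (phat - y) / n
  for (l in rev(seq_len(L))) {
    a_prev <- acts[[l]]
    gW <- t(delta) %*% a_prev
    gb <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% net$layers[[l]]$W
      a <- acts[[l]]
      if (!is.null(masks)) {
        delta <- delta * masks[[l - 1L]] * (a > 0)
      } else {
        delta <- delta * (a > 0)
      }
    }
    net$layers[[l]]$W <- net$layers[[l]]$W - lr * gW
    net$layers[[l]]$b <- net$layers[[l]]$b - lr * gb
  }
  net
}

#' Train the DTI network
#'
#' Mini-batch gradient descent on the binary cross-entropy with the
#' configured learning rate; after each epoch the validation loss is
#' evaluated, and training stops once it has failed to improve for
#' `patience` epochs, restoring the best-validation weights. Dropout
#' (inverted scaling) is active only during training.
#'
#' @param X_train,y_train preprocessed training features and labels.
#' @param X_val,y_val validation data for early stopping.
#' @param config a [dti_config()].
#' @param net optional pre-built `dti_network` (default: He-initialized from
#'   the config seed).
#' @return object of class `dti_network` with an added `history` element
#'   (per-epoch train/validation loss) and `best_epoch`.
#' @export
train_dti_network <- function(X_train, y_train, X_val, y_val,
                              config = dti_config(), net = NULL) {
  net <- net %||% build_dti_network(ncol(X_train), config)
  with_seed(child_seed(config$seed, 7L), {
    n <- nrow(X_train)
    best <- net; best_val <- Inf; best_epoch <- 0L; stall <- 0L
    hist <- NULL
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        net <- gd_step(net, X_train[idx, , drop = FALSE], y_train[idx],
                       config$learning_rate, config$dropout,
                       use_rng = TRUE)
      }
      tr_pred <- forward_pass(net, X_train)[[length(net$layers) + 1L]]
      va_pred <- forward_pass(net, X_val)[[length(net$layers) + 1L]]
      tr_loss <- bce_loss(y_train, as.numeric(tr_pred))
      va_loss <- bce_loss(y_val, as.numeric(va_pred))
      if (!is.finite(tr_loss) || !is.finite(va_loss)) {
        stop_input("training diverged (non-finite loss) at epoch %d", epoch)
      }
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tr_loss,
                                     val_loss = va_loss))
      if (va_loss < best_val - 1e-12) {
        best_val <- va_loss; best <- net; best_epoch <- epoch; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
    best$history <- hist
    best$best_epoch <- best_epoch
    best
  })
}

#' Train a DTI model end to end
#'
#' Splits the labeled pair set 70/10/30 (train/validation/test,
#' stratified), fits preprocessing (normalization + principal-component
#' projection) on the training rows only, trains the network with early
#' stopping, and evaluates on the untouched test rows.
#'
#' @param dataset a `dti_pairs` object (see [generate_dti_dataset()]) or a
#'   list with `features` (matrix) and `pairs$label`.
#' @param config a [dti_config()].
#' @param n_components passed to [fit_preprocess()].
#' @return object of class `dti_model`: `network`, `preprocess`, `config`,
#'   `splits`, and `metrics` (test accuracy and AUC).
#' @export
dti_train <- function(dataset, config = dti_config(), n_components = NULL) {
  y <- dataset$pairs$label
  X <- dataset$features
  splits <- split_dataset(y, seed = config$seed)
  prep <- fit_preprocess(X[splits$train, , drop = FALSE],
                         n_components = n_components)
  Xtr <- apply_preprocess(prep, X[splits$train, , drop = FALSE])
  Xva <- apply_preprocess(prep, X[splits$validation, , drop = FALSE])
  Xte <- apply_preprocess(prep, X[splits$test, , drop = FALSE])
  net <- train_dti_network(Xtr, y[splits$train], Xva, y[splits$validation],
                           config)
  pte <- as.numeric(forward_pass(net, Xte)[[length(net$layers) + 1L]])
  metrics <- c(
    test_accuracy = mean((pte > config$threshold) == (y[splits$test] == 1L)),
    test_auc = auc_rank(pte, y[splits$test]))
  structure(list(network = net, preprocess = prep, config = config,
                 splits = splits, metrics = metrics),
            class = "dti_model")
}

#' @export
print.dti_model <- function(x, ...) {
  cat("DTI classifier:", paste(x$network$widths, collapse = "-"),
      "feed-forward network\n")
  cat(sprintf("  input width %d after preprocessing (%d raw features kept)\n",
              x$preprocess$n_components, length(x$preprocess$keep)))
  cat(sprintf("  test accuracy %.3f, AUC %.3f (held-out 30%%)\n",
              x$metrics["test_accuracy"], x$metrics["test_auc"]))
  invisible(x)
}

#' @export
predict.dti_model <- function(object, features, ...) {
  Xp <- apply_preprocess(object$preprocess, features)
  as.numeric(forward_pass(object$network,
                          Xp)[[length(object$network$layers) + 1L]])
}

#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative (ties counted half).
#'
#' @param scores numeric scores.
#' @param labels 0/1 vector.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Stratified k-fold cross-validation of the DTI model
#'
#' Splits the labeled pairs into `folds` stratified folds; each fold in turn
#' is held out while the rest train a model (with its own internal
#' validation carve-out for early stopping). Reports per-fold accuracy and
#' AUC with their mean and standard deviation.
#'
#' @param dataset a `dti_pairs` object.
#' @param config a [dti_config()].
#' @param folds number of folds (study default 10).
#' @param n_components passed to [fit_preprocess()].
#' @return object of class `dti_cv`: `per_fold` data.frame, `accuracy_mean`,
#'   `accuracy_sd`, `auc_mean`.
#' @export
dti_cross_validate <- function(dataset, config = dti_config(), folds = 10L,
                               n_components = NULL) {
  y <- dataset$pairs$label
  X <- dataset$features
  if (length(y) < 2L * folds) stop_input("too few pairs for %d folds", folds)
  fold_id <- integer(length(y))
  with_seed(child_seed(config$seed, 11L), {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  if (any(tapply(y, fold_id, function(v) length(unique(v))) < 2L)) {
    stop_input("a fold is missing a class; use fewer folds")
  }
  rows <- lapply(seq_len(folds), function(k) {
    tr <- which(fold_id != k); te <- which(fold_id == k)
    inner <- split_dataset(y[tr], seed = child_seed(config$seed, 100L + k),
                           test_frac = 0, val_frac = 0.1)
    prep <- fit_preprocess(X[tr[inner$train], , drop = FALSE],
                           n_components = n_components)
    net <- train_dti_network(
      apply_preprocess(prep, X[tr[inner$train], , drop = FALSE]),
      y[tr[inner$train]],
      apply_preprocess(prep, X[tr[inner$validation], , drop = FALSE]),
      y[tr[inner$validation]], config)
    p <- as.numeric(forward_pass(
      net, apply_preprocess(prep, X[te, , drop = FALSE])
    )[[length(net$layers) + 1L]])
    data.frame(fold = k,
               accuracy = mean((p > config$threshold) == (y[te] == 1L)),
               auc = auc_rank(p, y[te]))
  })
  per_fold <- do.call(rbind, rows)
  structure(list(per_fold = per_fold, fold_id = fold_id,
                 accuracy_mean = mean(per_fold$accuracy),
                 accuracy_sd = stats::sd(per_fold$accuracy),
                 auc_mean = mean(per_fold$auc)),
            class = "dti_cv")
}

#' @export
print.dti_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV: accuracy %.3f (sd %.4f), AUC %.3f\n",
              nrow(x$per_fold), x$accuracy_mean, x$accuracy_sd, x$auc_mean))
  invisible(x)
}

#' Select candidate drugs per target
#'
#' Keeps pairs whose predicted interaction probability strictly exceeds the
#' threshold (study rule: greater than 0.5) and ranks them by decreasing
#' probability within each target.
#'
#' @param model a `dti_model`.
#' @param pairs data.frame with `drug_id`, `target_id`.
#' @param features matrix of raw pair features aligned with `pairs`.
#' @param threshold probability cutoff.
#' @return data.frame `drug_id`, `target_id`, `probability`, sorted by
#'   target then decreasing probability.
#' @export
predict_candidates <- function(model, pairs, features,
                               threshold = model$config$threshold) {
  p <- predict(model, features)
  keep <- p > threshold
  out <- data.frame(pairs[keep, c("drug_id", "target_id"), drop = FALSE],
                    probability = p[keep], stringsAsFactors = FALSE)
  out <- out[order(out$target_id, -out$probability, out$drug_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
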