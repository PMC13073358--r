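# Joint training of the classification and risk-regression heads ------------

#' Training configuration
#'
#' Defaults follow the study protocol: AdamW with learning rate 1e-4 and
#' weight decay 1e-2, batch size 32, at most 50 epochs with early stopping
#' on validation loss, class-weighted cross-entropy, and three seeds for
#' repeated runs. `lambda_reg` weighs the risk-regression MSE term against
#' the classification loss and is meant to be tuned on the validation set.
#'
#' @param lr Learning rate (> 0).
#' @param weight_decay AdamW decoupled weight decay.
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch cap.
#' @param patience Epochs without validation-loss improvement before stopping.
#' @param lambda_reg Weight of the regression loss term (>= 0).
#' @param seeds Integer seeds for [multi_seed_run()].
#' @param class_weighting Use inverse-frequency class weights in the CE term.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 1e-2, batch_size = 32L,
                         max_epochs = 50L, patience = 5L, lambda_reg = 0.5,
                         seeds = c(0L, 1L, 2L), class_weighting = TRUE) {
  if (lr <= 0) stopf("lr must be positive")
  if (lambda_reg < 0) stopf("lambda_reg must be non-negative")
  if (patience < 1) stopf("patience must be at least 1")
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), lambda_reg = lambda_reg,
                 seeds = as.integer(seeds), class_weighting = class_weighting),
            class = "train_config")
}

#' Inverse-frequency class weights
#'
#' `weight_c = N / (n_classes * n_c)`: inverse class frequency normalized so
#' the weights average to 1. Balanced labels give unit weights.
#'
#' @param labels Integer labels in 0..3.
#' @param n_classes Number of classes.
#' @return Numeric weight vector of length `n_classes`.
#' @export
class_weights <- function(labels, n_classes = 4L) {
  counts <- tabulate(labels + 1L, nbins = n_classes)
  if (any(counts == 0)) {
    stopf("class %d has no labeled examples", which(counts == 0)[1] - 1L)
  }
  length(labels) / (n_classes * counts)
}

#' Combined classification + risk-regression loss for one prediction
#'
#' `loss = w_label * CE(class_probs, label) + lambda_reg * (risk - label/3)^2`
#' with natural-log cross-entropy. The regression target of ordinal class k
#' is the equally spaced anchor `k/3` in \{0, 1/3, 2/3, 1\}. Probabilities
#' are clamped at 1e-12 before the log, so a zero probability at the true
#' class yields a large finite loss rather than an error.
#'
#' @param prediction A `stage_prediction` (or list with `class_probs` and
#'   `risk_score`).
#' @param label True ordinal class in 0..3.
#' @param lambda_reg Regression-loss weight.
#' @param weights Per-class CE weights (see [class_weights()]).
#' @return Scalar loss.
#' @export
combined_loss <- function(prediction, label, lambda_reg = 0.5,
                          weights = rep(1, 4)) {
  if (!(label %in% 0:3)) stopf("label must be in {0, 1, 2, 3}")
  p <- max(prediction$class_probs[label + 1L], 1e-12)
  weights[label + 1L] * (-log(p)) +
    lambda_reg * (prediction$risk_score - label / 3)^2
}

# Batch loss from logits via log-sum-exp, plus head gradients at 1/B scale.
batch_loss_grads <- function(logits, risk, labels, lambda_reg, cw) {
  B <- nrow(logits)
  m <- apply(logits, 1, max)
  lse <- log(rowSums(exp(logits - m))) + m
  li <- cbind(seq_len(B), labels + 1L)
  w <- cw[labels + 1L]
  tgt <- labels / 3
  ce <- w * (lse - logits[li])
  reg <- lambda_reg * (risk - tgt)^2
  probs <- exp(logits - lse)
  dlogits <- probs * w
  dlogits[li] <- dlogits[li] - w
  du <- lambda_reg * 2 * (risk - tgt) * risk * (1 - risk)
  list(loss = mean(ce + reg), dlogits = dlogits / B, du = du / B)
}

adamw_step <- function(params, grads, state, lr, wd, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) b2 * v + (1 - b2) * g * g, state$v, grads)
  c1 <- 1 / (1 - b1^state$t)
  c2 <- 1 / (1 - b2^state$t)
  upd <- tree_map2(function(m, v) (m * c1) / (sqrt(v * c2) + eps), state$m, state$v)
  params <- tree_map2(function(p, u) p - lr * u, params, upd)
  params <- tree_map(function(p) p - lr * wd * p, params)
  list(params = params, state = state)
}

# Early-stopping bookkeeping: improvement means a strictly lower validation
# loss; training stops once `patience` epochs pass without improvement.
early_stop_update <- function(state, epoch, val_loss, patience) {
  if (val_loss < state$best_loss) {
    state$best_loss <- val_loss
    state$best_epoch <- epoch
    state$stop <- FALSE
  } else {
    state$stop <- epoch - state$best_epoch >= patience
  }
  state
}

# Eval-mode loss + accuracy over a list of precomputed patch matrices.
eval_split <- function(model, plist, labels, lambda_reg, cw, batch_size = 64L) {
  n <- length(plist)
  tot <- 0; correct <- 0
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    fw <- forward_batch(model, plist[i:j], train = FALSE)
    lg <- batch_loss_grads(fw$logits, fw$risk, labels[i:j], lambda_reg, cw)
    tot <- tot + lg$loss * (j - i + 1L)
    correct <- correct + sum(max.col(fw$probs) - 1L == labels[i:j])
    i <- j + 1L
  }
  list(loss = tot / n, acc = correct / n)
}

#' Train a model with the study protocol
#'
#' AdamW on shuffled mini-batches with on-the-fly augmentation (training
#' split only), joint optimization of both heads from the outset, early
#' stopping on validation loss, and retention of the best-validation-loss
#' checkpoint. Fully deterministic given `seed`: batch order and dropout
#' draw from a run-level stream, and each image's augmentation stream is
#' seeded per epoch and image.
#'
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param train_records,val_records Lists of `image_record`s.
#' @param seed Run seed (initialization, shuffling, dropout, augmentation).
#' @param variant Architecture variant passed to [build_model()].
#' @param aug An [aug_config()] for the training split.
#' @param verbose Print one line per epoch.
#' @return List with `model` (best checkpoint) and `history` (data frame
#'   with per-epoch train/val loss and val accuracy, plus attributes
#'   `best_epoch` and `stopped_early`).
#' @export
train_model <- function(model_cfg, train_cfg, train_records, val_records,
                        seed = 0L, variant = "full", aug = aug_config(),
                        verbose = FALSE) {
  if (length(train_records) == 0 || length(val_records) == 0) {
    stopf("train and validation sets must be non-empty")
  }
  cfg <- model_cfg
  model <- build_model(cfg, variant, seed = seed)
  labels_tr <- vapply(train_records, function(r) r$label, integer(1))
  labels_va <- vapply(val_records, function(r) r$label, integer(1))
  cw <- if (train_cfg$class_weighting) class_weights(labels_tr, cfg$n_classes) else rep(1, cfg$n_classes)
  # deterministic preprocessing done once; augmentation is applied per epoch
  pre_tr <- lapply(train_records, function(r) preprocess(r$pixels, cfg$image_size))
  plist_va <- lapply(val_records, function(r) {
    patchify(preprocess(r$pixels, cfg$image_size), cfg$patch_size)
  })
  n <- length(train_records)
  state <- list(t = 0L, m = tree_zeros_like(model$params),
                v = tree_zeros_like(model$params))
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_acc = numeric())
  es <- list(best_loss = Inf, best_epoch = 0L, stop = FALSE)
  best_params <- model$params
  stopped_early <- FALSE
  set.seed(derive_seed(seed, 11L))
  for (epoch in seq_len(train_cfg$max_epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0
    starts <- seq(1L, n, by = train_cfg$batch_size)
    for (bi in seq_along(starts)) {
      idx <- perm[starts[bi]:min(starts[bi] + train_cfg$batch_size - 1L, n)]
      plist <- lapply(idx, function(i) {
        img <- augment(pre_tr[[i]], aug, seed = derive_seed(seed, epoch, i))
        patchify(img, cfg$patch_size)
      })
      fw <- forward_batch(model, plist, train = TRUE, keep_cache = TRUE)
      lg <- batch_loss_grads(fw$logits, fw$risk, labels_tr[idx],
                             train_cfg$lambda_reg, cw)
      if (!is.finite(lg$loss)) {
        stopf("training diverged (non-finite loss) at epoch %d, batch %d",
              epoch, bi)
      }
      grads <- backward_batch(model, fw, lg$dlogits, lg$du)
      st <- adamw_step(model$params, grads, state, train_cfg$lr,
                       train_cfg$weight_decay)
      model$params <- st$params
      state <- st$state
      ep_loss <- ep_loss + lg$loss * length(idx)
    }
    ev <- eval_split(model, plist_va, labels_va, train_cfg$lambda_reg, cw)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / n,
                                   val_loss = ev$loss, val_acc = ev$acc))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f",
                      epoch, ep_loss / n, ev$loss, ev$acc))
    }
    es <- early_stop_update(es, epoch, ev$loss, train_cfg$patience)
    if (es$best_epoch == epoch) best_params <- model$params
    if (es$stop) {
      stopped_early <- TRUE
      break
    }
  }
  model$params <- best_params
  attr(hist, "best_epoch") <- es$best_epoch
  attr(hist, "stopped_early") <- stopped_early
  list(model = model, history = hist)
}

#' Repeat training over several seeds and average the test metrics
#'
#' Runs [train_model()] once per seed (runs differ only in the seed),
#' evaluates each best checkpoint on the test records, and reports per-seed
#' scalar metrics together with their mean.
#'
#' @param model_cfg,train_cfg,train_records,val_records,variant,aug As in
#'   [train_model()].
#' @param test_records Held-out records to evaluate each run on.
#' @param seeds Integer seeds; defaults to `train_cfg$seeds`.
#' @return List with `per_seed` (data frame, one row per seed) and `mean`
#'   (named numeric vector averaging each scalar metric).
#' @export
multi_seed_run <- function(model_cfg, train_cfg, train_records, val_records,
                           test_records, seeds = train_cfg$seeds,
                           variant = "full", aug = aug_config()) {
  if (length(seeds) < 1) stopf("at least one seed is required")
  rows <- lapply(seeds, function(s) {
    fit <- train_model(model_cfg, train_cfg, train_records, val_records,
                       seed = s, variant = variant, aug = aug)
    rep <- evaluate_model(fit$model, test_records)
    data.frame(seed = s, accuracy = rep$accuracy, precision_w = rep$precision_w,
               recall_w = rep$recall_w, f1_w = rep$f1_w,
               micro_auc = rep$micro_auc,
               risk_monotone = as.numeric(rep$risk_monotone))
  })
  per_seed <- do.call(rbind, rows)
  means <- colMeans(per_seed[, setdiff(names(per_seed), "seed"), drop = FALSE])
  list(per_seed = per_seed, mean = means)
}

#' Grid search over the regression-loss weight
#'
#' Trains one model per candidate `lambda_reg` and reports the final
#' validation loss and accuracy of each, supporting validation-set tuning
#' of the classification/regression trade-off.
#'
#' @inheritParams train_model
#' @param lambdas Candidate regression-loss weights.
#' @return Data frame with one row per candidate.
#' @export
tune_lambda <- function(model_cfg, train_cfg, train_records, val_records,
                        lambdas = c(0.1, 0.25, 0.5, 1), seed = 0L) {
  rows <- lapply(lambdas, function(lam) {
    tc <- train_cfg
    tc$lambda_reg <- lam
    fit <- train_model(model_cfg, tc, train_records, val_records, seed = seed)
    h <- fit$history
    best <- attr(h, "best_epoch")
    data.frame(lambda_reg = lam, val_loss = h$val_loss[h$epoch == best],
               val_acc = h$val_acc[h$epoch == best])
  })
  do.call(rbind, rows)
}
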