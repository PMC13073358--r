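test_that("classification metrics match hand computation", {
  perfect <- classification_metrics(rep(0:3, 5), rep(0:3, 5))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision_w, 1)
  expect_equal(perfect$recall_w, 1)
  expect_equal(perfect$f1_w, 1)

  # two-class reduction with confusion [[2,0],[1,1]]
  truth <- c(0L, 0L, 1L, 1L)
  pred <- c(0L, 0L, 0L, 1L)
  m <- classification_metrics(pred, truth, n_classes = 2L)
  expect_equal(unname(m$confusion), matrix(c(2L, 1L, 0L, 1L), 2, 2))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$recall_w, 0.75)
  expect_equal(m$precision_w, 0.5 * (2 / 3) + 0.5 * 1)

  expect_error(classification_metrics(integer(0), integer(0)), "non-empty")
})

test_that("weighted recall equals accuracy for arbitrary predictions", {
  for (s in 1:10) {
    truth <- stagevit:::with_seed(s, sample(0:3, 60, replace = TRUE))
    pred <- stagevit:::with_seed(s + 20, sample(0:3, 60, replace = TRUE))
    m <- classification_metrics(pred, truth)
    expect_equal(m$recall_w, m$accuracy, tolerance = 1e-12)
    expect_equal(rowSums(m$confusion), tabulate(truth + 1L, 4), ignore_attr = TRUE)
    expect_equal(sum(diag(m$confusion)) / 60, m$accuracy)
  }
})

brute_force_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

test_that("one-vs-rest AUC matches exhaustive pair counting", {
  # perfectly separating scores
  truth <- rep(0:3, each = 3)
  probs <- t(vapply(truth, function(k) {
    p <- rep(0.05, 4); p[k + 1] <- 0.85; p
  }, numeric(4)))
  roc <- ovr_roc_auc(probs, truth)
  expect_equal(roc$per_class_auc, rep(1, 4))
  expect_equal(roc$micro_auc, 1)

  # 3-point toy set with a tie
  sc <- c(0.2, 0.5, 0.5)
  lab <- c(FALSE, TRUE, FALSE)
  expect_equal(stagevit:::auc_midrank(sc, lab), brute_force_auc(sc, lab))

  # random probabilities, <= 50 samples: midrank equals brute force to 1e-9
  for (s in 1:5) {
    n <- 30
    truth <- stagevit:::with_seed(s, sample(0:3, n, replace = TRUE))
    raw <- matrix(stagevit:::with_seed(s + 5, round(runif(n * 4), 2)), n, 4)
    probs <- raw / rowSums(raw)
    roc <- ovr_roc_auc(probs, truth)
    pooled_scores <- as.vector(probs)
    pooled_pos <- as.vector(outer(truth, 0:3, `==`))
    expect_equal(roc$micro_auc, brute_force_auc(pooled_scores, pooled_pos),
                 tolerance = 1e-9)
    for (k in 0:3) {
      if (any(truth == k) && any(truth != k)) {
        expect_equal(roc$per_class_auc[k + 1],
                     brute_force_auc(probs[, k + 1], truth == k),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("per-class AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  n <- 80
  truth <- stagevit:::with_seed(11, sample(0:3, n, replace = TRUE))
  raw <- matrix(stagevit:::with_seed(12, runif(n * 4)), n, 4)
  probs <- raw / rowSums(raw)
  roc <- ovr_roc_auc(probs, truth)
  for (k in 0:3) {
    ref <- as.numeric(pROC::auc(pROC::roc(truth == k, probs[, k + 1],
                                          quiet = TRUE, direction = "<")))
    expect_equal(roc$per_class_auc[k + 1], ref, tolerance = 1e-10)
  }
})

test_that("label-independent scores give chance-level micro AUC", {
  n <- 2000
  truth <- stagevit:::with_seed(21, sample(0:3, n, replace = TRUE))
  raw <- matrix(stagevit:::with_seed(22, runif(n * 4)), n, 4)
  probs <- raw / rowSums(raw)
  micro <- ovr_roc_auc(probs, truth)$micro_auc
  expect_lt(abs(micro - 0.5), 0.03)
})

test_that("absent classes yield NA per-class AUC but a defined micro AUC", {
  truth <- c(0L, 0L, 1L, 1L)
  probs <- matrix(c(0.7, 0.6, 0.2, 0.1,
                    0.1, 0.2, 0.6, 0.7,
                    0.1, 0.1, 0.1, 0.1,
                    0.1, 0.1, 0.1, 0.1), 4, 4)
  roc <- ovr_roc_auc(probs, truth)
  expect_true(is.na(roc$per_class_auc[3]))
  expect_true(is.na(roc$per_class_auc[4]))
  expect_false(is.na(roc$micro_auc))
})

test_that("risk monotonicity flags strict ordering only", {
  labels <- rep(0:3, each = 10)
  up <- rep(c(0.1, 0.3, 0.6, 0.8), each = 10)
  r1 <- risk_monotonicity(up, labels)
  expect_equal(r1$means, c(0.1, 0.3, 0.6, 0.8))
  expect_true(r1$monotone)
  expect_false(risk_monotonicity(rep(0.5, 40), labels)$monotone)
  exact <- risk_monotonicity(labels / 3, labels)
  expect_equal(exact$means, c(0, 1, 2, 3) / 3)
  expect_true(exact$monotone)
  # empty class
  r2 <- risk_monotonicity(c(0.1, 0.9), c(0L, 3L))
  expect_true(anyNA(r2$means))
  expect_false(r2$monotone)
})

test_that("adjacent-error fraction counts one-step confusions", {
  expect_equal(adjacency_confusion(c(2L, 1L), c(1L, 2L))$fraction, 1)
  expect_equal(adjacency_confusion(c(3L, 0L), c(0L, 0L))$fraction, 0)
  nae <- adjacency_confusion(0:3, 0:3)
  expect_equal(nae$fraction, 0)
  expect_true(nae$no_errors)
  mixed <- adjacency_confusion(c(1L, 3L, 2L, 2L), c(0L, 0L, 2L, 1L))
  expect_equal(mixed$fraction, 2 / 3)
})

test_that("evaluation reports are deterministic and internally consistent", {
  recs <- micro_training_set()
  cfg <- micro_config()
  m <- build_model(cfg, "full", seed = 2)
  r1 <- evaluate_model(m, recs)
  r2 <- evaluate_model(m, recs)
  expect_identical(r1[names(r1) != "predictions"], r2[names(r2) != "predictions"])
  expect_equal(r1$recall_w, r1$accuracy, tolerance = 1e-12)
  expect_equal(sum(r1$confusion), length(recs))
  path <- withr::local_tempfile(fileext = ".json")
  write_report(r1, path)
  expect_true(jsonlite::validate(paste(readLines(path), collapse = "")))
})

test_that("ablation table covers requested variants with zero self-deltas", {
  recs <- micro_training_set()
  cfg <- micro_config()
  tc <- train_config(lr = 1e-3, batch_size = 4, max_epochs = 2, patience = 5)
  abl <- ablation_suite(cfg, tc, recs, recs, recs, variants = "full", seeds = 0L)
  expect_equal(unique(abl$per_run$variant), "full")
  expect_true(all(abs(as.numeric(abl$deltas[1, -1])) < 1e-12))
  expect_error(ablation_suite(cfg, tc, recs, recs, recs, variants = "swin"),
               "unknown variant")
})
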