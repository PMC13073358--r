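test_that("token sequence geometry and positional additivity hold", {
  cfg <- micro_config()
  m <- build_model(cfg, "full", seed = 1)
  img <- rand_image(16, seed = 1)
  patches <- patchify(img, 8)
  tok <- embed_patches(patches, m)
  expect_equal(dim(tok), c(cfg$grid$n_patches + 1L, cfg$embed_dim))

  # changing only pos_i changes only token i
  m2 <- m
  m2$params$pos[3, ] <- m2$params$pos[3, ] + 1
  tok2 <- embed_patches(patches, m2)
  expect_equal(tok2[-3, ], tok[-3, ])
  expect_equal(tok2[3, ], tok[3, ] + 1)

  expect_error(embed_patches(patches[, 1:10], m), "length")
})

test_that("single-head attention matches the nested-loop oracle", {
  cfg <- micro_config()
  m <- build_model(cfg, "full", seed = 2)
  pars <- m$params$blocks[[1]]$attn
  D <- cfg$embed_dim
  Xn <- matrix(stagevit:::with_seed(9, rnorm(3 * D)), 3, D)
  out <- stagevit:::mhsa_fwd(Xn, pars, n_heads = 1, n_img = 1, t_len = 3)

  # brute force: explicit loops over queries and keys
  Q <- Xn %*% pars$Wq + matrix(pars$bq, 3, D, byrow = TRUE)
  K <- Xn %*% pars$Wk + matrix(pars$bk, 3, D, byrow = TRUE)
  V <- Xn %*% pars$Wv + matrix(pars$bv, 3, D, byrow = TRUE)
  O <- matrix(0, 3, D)
  for (i in 1:3) {
    s <- numeric(3)
    for (j in 1:3) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(D)
    a <- exp(s) / sum(exp(s))
    for (j in 1:3) O[i, ] <- O[i, ] + a[j] * V[j, ]
  }
  expected <- O %*% pars$Wo + matrix(pars$bo, 3, D, byrow = TRUE)
  expect_equal(out$y, expected, tolerance = 1e-5)

  # attention rows sum to 1 for every head and query (multi-head case)
  out4 <- stagevit:::mhsa_fwd(Xn, pars, n_heads = 2, n_img = 1, t_len = 3)
  for (A in out4$A) expect_equal(rowSums(A), rep(1, 3), tolerance = 1e-12)
})

test_that("eval-mode forward pass is deterministic and satisfies head contracts", {
  cfg <- micro_config(dropout = 0.1)  # dropout present but inactive in eval
  m <- build_model(cfg, "full", seed = 3)
  img <- rand_image(16, seed = 2)
  p1 <- predict_stage(m, img)
  p2 <- predict_stage(m, img)
  expect_identical(p1, p2)
  expect_equal(sum(p1$class_probs), 1, tolerance = 1e-6)
  expect_true(all(p1$class_probs >= 0))
  expect_gt(p1$risk_score, 0); expect_lt(p1$risk_score, 1)

  # zero classifier head -> uniform probabilities
  m0 <- m
  m0$params$head_class$W[] <- 0
  m0$params$head_class$b[] <- 0
  expect_equal(predict_stage(m0, img)$class_probs, rep(0.25, 4), tolerance = 1e-12)
})

test_that("SFL uses the stage positions: tied embeddings collapse, permutation matters", {
  cfg <- micro_config()
  m <- build_model(cfg, "full", seed = 4)
  cls <- stagevit:::with_seed(5, rnorm(cfg$embed_dim))

  tied <- m
  tied$params$sfl$stage_emb <- matrix(rep(tied$params$sfl$stage_emb[1, ], each = 4),
                                      4, cfg$embed_dim)
  sf <- stagevit:::sfl_batch(tied$params, cfg, "full", matrix(cls, 1),
                             train = FALSE, keep_cache = TRUE)
  stage_outputs <- stagevit:::gelu(sf$cache$H2)
  for (k in 2:4) expect_equal(stage_outputs[k, ], stage_outputs[1, ], tolerance = 1e-6)
  # pooling over identical stage outputs is a no-op relative to any single stage
  expect_equal(as.vector(sf$Z), stage_outputs[1, ], tolerance = 1e-6)

  # the stage embeddings are used: altering one changes the pooled output ...
  bump <- m
  bump$params$sfl$stage_emb[2, ] <- bump$params$sfl$stage_emb[2, ] + 0.5
  expect_false(isTRUE(all.equal(sfl_forward(cls, m), sfl_forward(cls, bump))))

  # ... but with additive combination, permutation-equivariant attention and
  # mean pooling, the pooled output is exactly invariant to permuting them
  perm <- m
  perm$params$sfl$stage_emb <- perm$params$sfl$stage_emb[c(3, 1, 4, 2), ]
  expect_equal(sfl_forward(cls, m), sfl_forward(cls, perm), tolerance = 1e-12)
})

test_that("variants have the advertised structure", {
  cfg <- micro_config()
  full <- build_model(cfg, "full", seed = 5)
  nop <- build_model(cfg, "no_progression", seed = 5)
  nsa <- build_model(cfg, "no_self_attention", seed = 5)
  expect_null(nop$params$sfl)
  expect_gt(count_parameters(full), count_parameters(nop))
  expect_equal(length(sfl_forward(rnorm(cfg$embed_dim), full)),
               length(sfl_forward(rnorm(cfg$embed_dim), nsa)))
  expect_error(sfl_forward(rnorm(cfg$embed_dim), nop), "no_progression")
  expect_error(build_model(cfg, "bogus"), "arg")
  # sfl output length matches configured head width
  expect_length(sfl_forward(rnorm(cfg$embed_dim), full), cfg$sfl_ffn_dims[3])
})

test_that("analytic gradients match finite differences", {
  cfg <- micro_config()
  for (variant in c("full", "no_self_attention")) {
    m <- build_model(cfg, variant, seed = 6)
    plist <- lapply(1:2, function(i) {
      matrix(stagevit:::with_seed(i, runif(4 * 192)), 4, 192)
    })
    labels <- c(1L, 3L)
    lossfn <- function(mm) {
      fw <- stagevit:::forward_batch(mm, plist, train = FALSE)
      stagevit:::batch_loss_grads(fw$logits, fw$risk, labels, 0.5, rep(1, 4))$loss
    }
    fw <- stagevit:::forward_batch(m, plist, train = FALSE, keep_cache = TRUE)
    lg <- stagevit:::batch_loss_grads(fw$logits, fw$risk, labels, 0.5, rep(1, 4))
    grads <- stagevit:::backward_batch(m, fw, lg$dlogits, lg$du)
    gvec <- unlist(grads)
    pvec <- unlist(m$params)
    idx <- stagevit:::with_seed(7, sort(sample(length(pvec), 25)))
    eps <- 1e-5
    num <- vapply(idx, function(k) {
      up <- pvec; dn <- pvec
      up[k] <- up[k] + eps; dn[k] <- dn[k] - eps
      m1 <- m; m1$params <- utils::relist(up, m$params)
      m2 <- m; m2$params <- utils::relist(dn, m$params)
      (lossfn(m1) - lossfn(m2)) / (2 * eps)
    }, numeric(1))
    rel <- abs(num - gvec[idx]) / pmax(1e-4, abs(num) + abs(gvec[idx]))
    expect_lt(max(rel), 1e-4)
  }
})

test_that("checkpoints round-trip through serialization", {
  cfg <- micro_config()
  m <- build_model(cfg, "full", seed = 8)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path, extra = list(note = "fixture"))
  back <- load_checkpoint(path)
  img <- rand_image(16, seed = 9)
  expect_identical(predict_stage(back$model, img), predict_stage(m, img))
  expect_equal(back$extra$note, "fixture")
  saveRDS(list(format = "other"), path)
  expect_error(load_checkpoint(path), "unrecognized")
})
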