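# Stage-aware vision transformer --------------------------------------------
#
# Architecture: patchify -> linear patch embedding + [CLS] + learnable
# positional encodings -> L pre-norm transformer blocks (multi-head
# self-attention, GELU feed-forward, residual around each sublayer, dropout
# on attention weights and feed-forward outputs) -> final layer norm. The
# [CLS] state then enters the Sequential Feature Learner (SFL): it is copied
# to four ordinal stage positions, combined additively with learned stage
# embeddings, passed through two pre-norm self-attention layers and a
# per-token GELU feed-forward, and mean-pooled over the four stages. The
# pooled vector feeds two parallel heads: a 4-class softmax classifier and
# a sigmoid regressor emitting a continuous malignancy risk score in [0,1].

#' Model configuration presets
#'
#' The `base` preset mirrors ViT-Base/16 at 224 px input (12 blocks, 12
#' heads, width 768, FFN 3072) with an SFL of 2 attention layers (12 heads)
#' and a 768 -> 1024 -> 512 feed-forward. The `tiny` preset is a from-scratch
#' desk-scale variant (64 px input, 8 px patches, width 64, 2 blocks, 4
#' heads) used throughout the tests and examples.
#'
#' @param preset `"tiny"` or `"base"`.
#' @param ... Named overrides of individual fields.
#' @return A validated `model_config` list.
#' @export
model_config <- function(preset = c("tiny", "base"), ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "base") {
    list(image_size = 224L, patch_size = 16L, embed_dim = 768L, depth = 12L,
         n_heads = 12L, ffn_dim = 3072L, dropout = 0.1, n_stages = 4L,
         sfl_layers = 2L, sfl_heads = 12L, sfl_ffn_dims = c(768L, 1024L, 512L),
         n_classes = 4L)
  } else {
    list(image_size = 64L, patch_size = 8L, embed_dim = 64L, depth = 2L,
         n_heads = 4L, ffn_dim = 128L, dropout = 0.1, n_stages = 4L,
         sfl_layers = 2L, sfl_heads = 4L, sfl_ffn_dims = c(64L, 96L, 48L),
         n_classes = 4L)
  }
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stopf("unknown model_config field '%s'", nm)
    cfg[[nm]] <- over[[nm]]
  }
  if (cfg$embed_dim %% cfg$n_heads != 0) {
    stopf("embed_dim must be divisible by n_heads")
  }
  if (cfg$image_size %% cfg$patch_size != 0) {
    stopf("patch_size must divide image_size")
  }
  if (cfg$sfl_ffn_dims[1] != cfg$embed_dim) {
    stopf("sfl_ffn_dims[1] must equal embed_dim")
  }
  if (cfg$embed_dim %% cfg$sfl_heads != 0) {
    stopf("embed_dim must be divisible by sfl_heads")
  }
  if (cfg$n_stages != 4L) stopf("n_stages is fixed at 4")
  cfg$grid <- patch_grid(cfg$image_size, cfg$patch_size)
  class(cfg) <- "model_config"
  cfg
}

trunc_normal <- function(n, sd = 0.02) {
  pmin(pmax(stats::rnorm(n, 0, sd), -2 * sd), 2 * sd)
}

# Glorot-scaled truncated normal for linear maps: keeps activation scale
# roughly width-independent, so tiny presets train as the base geometry does
# (a flat sd of 0.02 is calibrated to width 768 and starves narrow models).
tn_mat <- function(nr, nc) {
  sd <- sqrt(2 / (nr + nc))
  matrix(pmin(pmax(stats::rnorm(nr * nc, 0, sd), -2 * sd), 2 * sd), nr, nc)
}

emb_mat <- function(nr, nc) matrix(trunc_normal(nr * nc), nr, nc)

ln_params <- function(d) list(g = rep(1, d), b = rep(0, d))

attn_params <- function(d) {
  list(Wq = tn_mat(d, d), bq = rep(0, d), Wk = tn_mat(d, d), bk = rep(0, d),
       Wv = tn_mat(d, d), bv = rep(0, d), Wo = tn_mat(d, d), bo = rep(0, d))
}

#' Build a model (full or ablated variant)
#'
#' Variants: `"full"` is the complete architecture; `"no_progression"`
#' removes the SFL entirely and attaches both heads directly to the [CLS]
#' embedding (heads re-dimensioned to the encoder width); `"no_self_attention"`
#' keeps the SFL but replaces each of its attention sublayers with a
#' width-preserving fully connected layer with GELU (pre-norm and residual
#' unchanged). Linear maps are initialized from a Glorot-scaled truncated
#' normal (sd `sqrt(2/(fan_in+fan_out))`, clipped at 2 sd) so activation
#' scale is width-independent; embeddings use the conventional truncated
#' normal sd 0.02; biases and LayerNorm offsets start at zero. All draws are
#' deterministic given `seed`.
#'
#' @param config A [model_config()].
#' @param variant One of `"full"`, `"no_progression"`, `"no_self_attention"`.
#' @param seed Integer initialization seed.
#' @return A `stagevit_model` list with `config`, `variant`, `params`, `seed`.
#' @export
build_model <- function(config, variant = c("full", "no_progression", "no_self_attention"),
                        seed = 0L) {
  variant <- match.arg(variant)
  cfg <- config
  D <- cfg$embed_dim
  pd <- cfg$patch_size^2 * 3
  n_tok <- cfg$grid$n_patches + 1L
  params <- with_seed(derive_seed(seed, 7L), {
    p <- list(
      embed = list(W = tn_mat(pd, D), b = rep(0, D)),
      cls = trunc_normal(D),
      pos = emb_mat(n_tok, D),
      blocks = lapply(seq_len(cfg$depth), function(l) {
        list(ln1 = ln_params(D), attn = attn_params(D), ln2 = ln_params(D),
             ffn = list(W1 = tn_mat(D, cfg$ffn_dim), b1 = rep(0, cfg$ffn_dim),
                        W2 = tn_mat(cfg$ffn_dim, D), b2 = rep(0, D)))
      }),
      ln_f = ln_params(D)
    )
    z_dim <- D
    if (variant != "no_progression") {
      d2 <- cfg$sfl_ffn_dims[2]; d3 <- cfg$sfl_ffn_dims[3]
      p$sfl <- list(
        stage_emb = emb_mat(cfg$n_stages, D),
        layers = lapply(seq_len(cfg$sfl_layers), function(l) {
          if (variant == "no_self_attention") {
            list(ln = ln_params(D), fc = list(W = tn_mat(D, D), b = rep(0, D)))
          } else {
            list(ln = ln_params(D), attn = attn_params(D))
          }
        }),
        ffn = list(W1 = tn_mat(D, d2), b1 = rep(0, d2),
                   W2 = tn_mat(d2, d3), b2 = rep(0, d3))
      )
      z_dim <- d3
    }
    p$head_class <- list(W = tn_mat(z_dim, cfg$n_classes), b = rep(0, cfg$n_classes))
    p$head_risk <- list(W = tn_mat(z_dim, 1L), b = 0)
    p
  })
  structure(list(config = cfg, variant = variant, params = params, seed = seed),
            class = "stagevit_model")
}

#' Number of trainable parameters
#' @param model A `stagevit_model`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) tree_n_params(model$params)

# ---- batched forward pass ---------------------------------------------------

# tok: stacked (n_img * n_tok) x D; token 1 of each block is [CLS].
embed_batch <- function(params, cfg, patch_stack, n_img) {
  n_tok <- cfg$grid$n_patches + 1L
  D <- cfg$embed_dim
  Pe <- linear_fwd(patch_stack, params$embed$W, params$embed$b)
  tok <- matrix(0, n_img * n_tok, D)
  cls_rows <- seq(1L, n_img * n_tok, by = n_tok)
  tok[cls_rows, ] <- matrix(params$cls, n_img, D, byrow = TRUE)
  tok[-cls_rows, ] <- Pe
  tok + params$pos[rep(seq_len(n_tok), n_img), , drop = FALSE]
}

encode_batch <- function(params, cfg, tok, n_img, train = FALSE, keep_cache = FALSE) {
  n_tok <- nrow(tok) %/% n_img
  caches <- if (keep_cache) vector("list", cfg$depth) else NULL
  for (l in seq_len(cfg$depth)) {
    bp <- params$blocks[[l]]
    ln1 <- layernorm_fwd(tok, bp$ln1$g, bp$ln1$b)
    mh <- mhsa_fwd(ln1$y, bp$attn, cfg$n_heads, n_img, n_tok, cfg$dropout, train)
    tok <- tok + mh$y
    ln2 <- layernorm_fwd(tok, bp$ln2$g, bp$ln2$b)
    H1 <- linear_fwd(ln2$y, bp$ffn$W1, bp$ffn$b1)
    G <- gelu(H1)
    Ff <- linear_fwd(G, bp$ffn$W2, bp$ffn$b2)
    dr <- dropout_fwd(Ff, cfg$dropout, train)
    tok <- tok + dr$y
    if (!all(is.finite(tok))) stopf("non-finite activations in encoder block %d", l)
    if (keep_cache) {
      caches[[l]] <- list(ln1 = ln1, mh = mh, ln2 = ln2, H1 = H1, G = G,
                          drop_mask = dr$mask)
    }
  }
  lnf <- layernorm_fwd(tok, params$ln_f$g, params$ln_f$b)
  list(tokF = lnf$y, block_caches = caches, lnf = if (keep_cache) lnf else NULL)
}

sfl_batch <- function(params, cfg, variant, cls_vecs, train = FALSE, keep_cache = FALSE) {
  B <- nrow(cls_vecs)
  S4 <- cfg$n_stages
  Sm <- cls_vecs[rep(seq_len(B), each = S4), , drop = FALSE] +
    params$sfl$stage_emb[rep(seq_len(S4), B), , drop = FALSE]
  layer_caches <- if (keep_cache) vector("list", cfg$sfl_layers) else NULL
  for (l in seq_len(cfg$sfl_layers)) {
    lp <- params$sfl$layers[[l]]
    ln <- layernorm_fwd(Sm, lp$ln$g, lp$ln$b)
    if (variant == "no_self_attention") {
      H <- linear_fwd(ln$y, lp$fc$W, lp$fc$b)
      out <- gelu(H)
      if (keep_cache) layer_caches[[l]] <- list(ln = ln, H = H)
    } else {
      mh <- mhsa_fwd(ln$y, lp$attn, cfg$sfl_heads, B, S4, cfg$dropout, train)
      out <- mh$y
      if (keep_cache) layer_caches[[l]] <- list(ln = ln, mh = mh)
    }
    Sm <- Sm + out
  }
  H1 <- linear_fwd(Sm, params$sfl$ffn$W1, params$sfl$ffn$b1)
  G1 <- gelu(H1)
  H2 <- linear_fwd(G1, params$sfl$ffn$W2, params$sfl$ffn$b2)
  G2 <- gelu(H2)
  Z <- rowsum(G2, rep(seq_len(B), each = S4), reorder = FALSE) / S4
  list(Z = Z,
       cache = if (keep_cache) {
         list(layers = layer_caches, Sf = Sm, H1 = H1, G1 = G1, H2 = H2)
       } else NULL)
}

heads_batch <- function(params, Z) {
  logits <- linear_fwd(Z, params$head_class$W, params$head_class$b)
  probs <- softmax_rows(logits)
  u <- as.vector(Z %*% params$head_risk$W) + params$head_risk$b
  list(logits = logits, probs = probs, risk = 1 / (1 + exp(-u)))
}

# Forward pass over a list of patch matrices (one per image). Returns
# predictions plus [CLS] vectors and final-block patch tokens; with
# keep_cache = TRUE everything backward_batch() needs is retained.
forward_batch <- function(model, patches_list, train = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  params <- model$params
  n_img <- length(patches_list)
  n_tok <- cfg$grid$n_patches + 1L
  patch_stack <- do.call(rbind, patches_list)
  tok <- embed_batch(params, cfg, patch_stack, n_img)
  enc <- encode_batch(params, cfg, tok, n_img, train, keep_cache)
  cls_rows <- seq(1L, n_img * n_tok, by = n_tok)
  cls_vecs <- enc$tokF[cls_rows, , drop = FALSE]
  patch_tokens <- enc$tokF[-cls_rows, , drop = FALSE]
  if (model$variant == "no_progression") {
    Z <- cls_vecs
    sf <- NULL
  } else {
    sf <- sfl_batch(params, cfg, model$variant, cls_vecs, train, keep_cache)
    Z <- sf$Z
  }
  hd <- heads_batch(params, Z)
  res <- list(logits = hd$logits, probs = hd$probs, risk = hd$risk,
              cls_vecs = cls_vecs, patch_tokens = patch_tokens, n_img = n_img)
  if (keep_cache) {
    res$cache <- list(patch_stack = patch_stack, enc = enc, cls_rows = cls_rows,
                      sfl = if (is.null(sf)) NULL else sf$cache, Z = Z,
                      n_tok = n_tok)
  }
  res
}

# ---- exported single-image operations ---------------------------------------

#' Embed a patch sequence into the token sequence
#'
#' Projects each flattened patch through the learnable linear embedding,
#' prepends the [CLS] token, and adds the learnable positional encodings.
#'
#' @param patches `n_patches` x `(P*P*3)` matrix from [patchify()].
#' @param model A `stagevit_model`.
#' @return `(n_patches + 1)` x D token matrix; row 1 is the [CLS] token.
#' @export
embed_patches <- function(patches, model) {
  cfg <- model$config
  if (ncol(patches) != cfg$patch_size^2 * 3) {
    stopf("patch vectors have length %d; model expects %d",
          ncol(patches), cfg$patch_size^2 * 3)
  }
  if (nrow(patches) != cfg$grid$n_patches) {
    stopf("expected %d patches, got %d", cfg$grid$n_patches, nrow(patches))
  }
  embed_batch(model$params, cfg, patches, 1L)
}

#' Run the transformer encoder
#'
#' Applies the pre-norm transformer blocks and the final layer norm, and
#' returns the [CLS] embedding (the high-level lesion descriptor) together
#' with the final-block patch token outputs consumed by [score_cam()].
#'
#' @param tokens Token matrix from [embed_patches()].
#' @param model A `stagevit_model`.
#' @param train_mode Activate dropout (training only).
#' @return List with `cls` (length-D vector) and `patch_tokens`
#'   (`n_patches` x D matrix).
#' @export
vit_encode <- function(tokens, model, train_mode = FALSE) {
  enc <- encode_batch(model$params, model$config, tokens, 1L, train_mode, FALSE)
  list(cls = enc$tokF[1, ], patch_tokens = enc$tokF[-1, , drop = FALSE])
}

#' Run the Sequential Feature Learner
#'
#' Builds the four stage tokens (CLS embedding plus each learned stage
#' embedding), applies the SFL layers and per-token feed-forward, and
#' returns the mean over the four ordinal stage outputs.
#'
#' @param cls_embedding Length-D [CLS] vector from [vit_encode()].
#' @param model A `stagevit_model` with an SFL (not `no_progression`).
#' @param train_mode Activate dropout (training only).
#' @return Pooled representation (length `sfl_ffn_dims[3]`).
#' @export
sfl_forward <- function(cls_embedding, model, train_mode = FALSE) {
  if (model$variant == "no_progression") {
    stopf("the no_progression variant has no Sequential Feature Learner")
  }
  sf <- sfl_batch(model$params, model$config, model$variant,
                  matrix(cls_embedding, 1), train_mode, FALSE)
  as.vector(sf$Z)
}

#' Predict the ordinal stage and continuous risk score of one image
#'
#' Composes [patchify()], [embed_patches()], [vit_encode()], [sfl_forward()]
#' and the two prediction heads in evaluation mode (deterministic).
#'
#' @param model A `stagevit_model`.
#' @param image Preprocessed `image_size` x `image_size` x 3 array (see
#'   [preprocess()]).
#' @return A `stage_prediction`: `class_probs` (4-vector summing to 1),
#'   `risk_score` in (0,1), `logits`, and `pred_class` in 0..3.
#' @export
predict_stage <- function(model, image) {
  patches <- patchify(image, model$config$patch_size)
  fw <- forward_batch(model, list(patches), train = FALSE)
  structure(
    list(class_probs = as.vector(fw$probs[1, ]), risk_score = fw$risk[1],
         logits = as.vector(fw$logits[1, ]),
         pred_class = which.max(fw$probs[1, ]) - 1L),
    class = "stage_prediction"
  )
}

# Batched eval-mode prediction over a list of image_records (preprocessed
# on the fly). Returns probs matrix, risk vector, predicted labels.
predict_records <- function(model, records, batch_size = 64L) {
  cfg <- model$config
  n <- length(records)
  probs <- matrix(NA_real_, n, cfg$n_classes)
  risk <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    plist <- lapply(records[i:j], function(r) {
      patchify(preprocess(r$pixels, cfg$image_size), cfg$patch_size)
    })
    fw <- forward_batch(model, plist, train = FALSE)
    probs[i:j, ] <- fw$probs
    risk[i:j] <- fw$risk
    i <- j + 1L
  }
  list(probs = probs, risk = risk, pred = max.col(probs) - 1L,
       labels = vapply(records, function(r) r$label, integer(1)))
}

# ---- checkpoints -------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Single-file serialized bundle holding the weights, the embedded
#' [model_config()], the variant, and the training seed. The format is
#' versioned; loading refuses unknown versions.
#'
#' @param model A `stagevit_model`.
#' @param path File path.
#' @param extra Optional named list stored alongside (e.g. training history).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a list with `model` and `extra`.
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  saveRDS(list(format = "stagevit-checkpoint-1", config = model$config,
               variant = model$variant, params = model$params,
               seed = model$seed, extra = extra), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "stagevit-checkpoint-1")) {
    stopf("unrecognized checkpoint format in '%s'", path)
  }
  model <- structure(list(config = x$config, variant = x$variant,
                          params = x$params, seed = x$seed),
                     class = "stagevit_model")
  list(model = model, extra = x$extra)
}
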