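# Analytic backpropagation through the batched forward pass ------------------
#
# backward_batch() consumes the cache of forward_batch(..., keep_cache = TRUE)
# together with the loss gradients at the two heads (d loss / d logits and
# d loss / d pre-sigmoid risk unit, both summed-over-batch scale) and returns
# a gradient tree with exactly the structure of model$params. Correctness is
# pinned down by the finite-difference test in the test suite.

backward_batch <- function(model, fw, dlogits, du) {
  cfg <- model$config
  params <- model$params
  cache <- fw$cache
  B <- fw$n_img
  S4 <- cfg$n_stages
  grads <- tree_zeros_like(params)

  # heads
  Z <- cache$Z
  grads$head_class$W <- t(Z) %*% dlogits
  grads$head_class$b <- colSums(dlogits)
  grads$head_risk$W <- t(Z) %*% matrix(du, B, 1)
  grads$head_risk$b <- sum(du)
  dZ <- dlogits %*% t(params$head_class$W) + matrix(du, B, 1) %*% t(params$head_risk$W)

  # SFL (absent in the no_progression variant, where Z is the CLS embedding)
  if (model$variant == "no_progression") {
    dcls <- dZ
  } else {
    sc <- cache$sfl
    fp <- params$sfl$ffn
    dG2 <- dZ[rep(seq_len(B), each = S4), , drop = FALSE] / S4
    dH2 <- gelu_bwd(dG2, sc$H2)
    grads$sfl$ffn$W2 <- t(sc$G1) %*% dH2
    grads$sfl$ffn$b2 <- colSums(dH2)
    dG1 <- dH2 %*% t(fp$W2)
    dH1 <- gelu_bwd(dG1, sc$H1)
    grads$sfl$ffn$W1 <- t(sc$Sf) %*% dH1
    grads$sfl$ffn$b1 <- colSums(dH1)
    dSm <- dH1 %*% t(fp$W1)
    for (l in rev(seq_len(cfg$sfl_layers))) {
      lp <- params$sfl$layers[[l]]
      lc <- sc$layers[[l]]
      if (model$variant == "no_self_attention") {
        dH <- gelu_bwd(dSm, lc$H)
        grads$sfl$layers[[l]]$fc$W <- t(lc$ln$y) %*% dH
        grads$sfl$layers[[l]]$fc$b <- colSums(dH)
        dln <- dH %*% t(lp$fc$W)
      } else {
        mb <- mhsa_bwd(dSm, lc$mh, lp$attn)
        grads$sfl$layers[[l]]$attn <- mb$grads
        dln <- mb$dXn
      }
      lb <- layernorm_bwd(dln, lc$ln, lp$ln$g)
      grads$sfl$layers[[l]]$ln <- list(g = lb$dg, b = lb$db)
      dSm <- dSm + lb$dX
    }
    grads$sfl$stage_emb <- rowsum(dSm, rep(seq_len(S4), B), reorder = FALSE)
    dcls <- rowsum(dSm, rep(seq_len(B), each = S4), reorder = FALSE)
  }

  # encoder: only the [CLS] rows receive gradient from the heads
  n_tok <- cache$n_tok
  dtokF <- matrix(0, B * n_tok, cfg$embed_dim)
  dtokF[cache$cls_rows, ] <- dcls
  lb <- layernorm_bwd(dtokF, cache$enc$lnf, params$ln_f$g)
  grads$ln_f <- list(g = lb$dg, b = lb$db)
  dtok <- lb$dX
  for (l in rev(seq_len(cfg$depth))) {
    bp <- params$blocks[[l]]
    bc <- cache$enc$block_caches[[l]]
    # feed-forward sublayer
    dF <- dropout_bwd(dtok, bc$drop_mask)
    grads$blocks[[l]]$ffn$W2 <- t(bc$G) %*% dF
    grads$blocks[[l]]$ffn$b2 <- colSums(dF)
    dG <- dF %*% t(bp$ffn$W2)
    dH1 <- gelu_bwd(dG, bc$H1)
    grads$blocks[[l]]$ffn$W1 <- t(bc$ln2$y) %*% dH1
    grads$blocks[[l]]$ffn$b1 <- colSums(dH1)
    dln2 <- dH1 %*% t(bp$ffn$W1)
    lb2 <- layernorm_bwd(dln2, bc$ln2, bp$ln2$g)
    grads$blocks[[l]]$ln2 <- list(g = lb2$dg, b = lb2$db)
    dtok <- dtok + lb2$dX
    # attention sublayer
    mb <- mhsa_bwd(dtok, bc$mh, bp$attn)
    grads$blocks[[l]]$attn <- mb$grads
    lb1 <- layernorm_bwd(mb$dXn, bc$ln1, bp$ln1$g)
    grads$blocks[[l]]$ln1 <- list(g = lb1$dg, b = lb1$db)
    dtok <- dtok + lb1$dX
  }

  # embedding, positional encodings, [CLS]
  grads$pos <- rowsum(dtok, rep(seq_len(n_tok), B), reorder = FALSE)
  grads$cls <- colSums(dtok[cache$cls_rows, , drop = FALSE])
  dPe <- dtok[-cache$cls_rows, , drop = FALSE]
  grads$embed$W <- t(cache$patch_stack) %*% dPe
  grads$embed$b <- colSums(dPe)
  grads
}
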