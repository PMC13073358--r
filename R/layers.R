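# Network primitives ---------------------------------------------------------
#
# All token-wise operations act on stacked token matrices (rows = tokens of
# all images in a batch, columns = embedding dimensions); self-attention
# loops over per-image row blocks. Each *_fwd returns the output plus the
# cache its *_bwd needs; backward passes are analytic.

addrow <- function(X, b) t(t(X) + b)

gelu <- function(x) x * stats::pnorm(x)

gelu_bwd <- function(dy, x) dy * (stats::pnorm(x) + x * stats::dnorm(x))

softmax_rows <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  s <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * s
  list(y = addrow(t(t(xhat) * g), b), xhat = xhat, s = s)
}

layernorm_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- t(t(dY) * g)
  dX <- cache$s * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

linear_fwd <- function(X, W, b) addrow(X %*% W, b)

# Inverted dropout; mask is NULL when inactive so eval costs nothing.
dropout_fwd <- function(X, p, train) {
  if (!train || p <= 0) return(list(y = X, mask = NULL))
  mask <- matrix((stats::runif(length(X)) >= p) / (1 - p), nrow(X), ncol(X))
  list(y = X * mask, mask = mask)
}

dropout_bwd <- function(dY, mask) if (is.null(mask)) dY else dY * mask

# Multi-head self-attention over n_img independent row blocks of t_len tokens.
# Dropout (rate p, train mode only) is applied to the attention weights.
mhsa_fwd <- function(Xn, pars, n_heads, n_img, t_len, p = 0, train = FALSE) {
  D <- ncol(Xn)
  dh <- D %/% n_heads
  scale <- 1 / sqrt(dh)
  Q <- linear_fwd(Xn, pars$Wq, pars$bq)
  K <- linear_fwd(Xn, pars$Wk, pars$bk)
  V <- linear_fwd(Xn, pars$Wv, pars$bv)
  O <- Q * 0
  A_list <- vector("list", n_img * n_heads)
  M_list <- vector("list", n_img * n_heads)
  for (b in seq_len(n_img)) {
    rb <- ((b - 1) * t_len + 1):(b * t_len)
    for (h in seq_len(n_heads)) {
      hc <- ((h - 1) * dh + 1):(h * dh)
      A <- softmax_rows(Q[rb, hc, drop = FALSE] %*%
                          t(K[rb, hc, drop = FALSE]) * scale)
      dr <- dropout_fwd(A, p, train)
      O[rb, hc] <- dr$y %*% V[rb, hc, drop = FALSE]
      idx <- (b - 1) * n_heads + h
      A_list[[idx]] <- A
      M_list[idx] <- list(dr$mask)
    }
  }
  out <- linear_fwd(O, pars$Wo, pars$bo)
  list(y = out, Q = Q, K = K, V = V, O = O, A = A_list, M = M_list,
       Xn = Xn, n_heads = n_heads, n_img = n_img, t_len = t_len, scale = scale)
}

mhsa_bwd <- function(dOut, cache, pars) {
  n_heads <- cache$n_heads; n_img <- cache$n_img; t_len <- cache$t_len
  D <- ncol(cache$Q); dh <- D %/% n_heads
  dWo <- t(cache$O) %*% dOut
  dbo <- colSums(dOut)
  dO <- dOut %*% t(pars$Wo)
  dQ <- dO * 0; dK <- dO * 0; dV <- dO * 0
  for (b in seq_len(n_img)) {
    rb <- ((b - 1) * t_len + 1):(b * t_len)
    for (h in seq_len(n_heads)) {
      hc <- ((h - 1) * dh + 1):(h * dh)
      idx <- (b - 1) * n_heads + h
      A <- cache$A[[idx]]; M <- cache$M[[idx]]
      Ad <- if (is.null(M)) A else A * M
      dAd <- dO[rb, hc, drop = FALSE] %*% t(cache$V[rb, hc, drop = FALSE])
      dV[rb, hc] <- t(Ad) %*% dO[rb, hc, drop = FALSE]
      dA <- if (is.null(M)) dAd else dAd * M
      dS <- A * (dA - rowSums(dA * A))
      dQ[rb, hc] <- (dS %*% cache$K[rb, hc, drop = FALSE]) * cache$scale
      dK[rb, hc] <- (t(dS) %*% cache$Q[rb, hc, drop = FALSE]) * cache$scale
    }
  }
  Xn <- cache$Xn
  list(
    dXn = dQ %*% t(pars$Wq) + dK %*% t(pars$Wk) + dV %*% t(pars$Wv),
    grads = list(Wq = t(Xn) %*% dQ, bq = colSums(dQ),
                 Wk = t(Xn) %*% dK, bk = colSums(dK),
                 Wv = t(Xn) %*% dV, bv = colSums(dV),
                 Wo = dWo, bo = dbo)
  )
}
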