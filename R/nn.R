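# Matrix-algebra neural primitives with hand-written backward passes.
# Conventions: token sequences are N x D matrices; fast-pathway feature
# maps are arrays of dim c(C, H, W, T) (channels first, frames last).
# Convolutions are 3 x 3 x 3, zero-padded by 1 in every dimension, with a
# configurable spatial stride and temporal stride 1, realised as im2col
# gathers followed by one BLAS matmul.

.satsn_cache <- new.env(parent = emptyenv())

sigmoid <- function(x) 1 / (1 + exp(-x))
gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

# ---- im2col for 3x3x3 convolution ------------------------------------------

im2col_plan <- function(C, H, W, T, stride) {
  key <- paste("conv", C, H, W, T, stride, sep = "_")
  plan <- .satsn_cache[[key]]
  if (!is.null(plan)) return(plan)
  Hp <- H + 2L; Wp <- W + 2L; Tp <- T + 2L
  Ho <- (H - 1L) %/% stride + 1L
  Wo <- (W - 1L) %/% stride + 1L
  grid <- expand.grid(c = seq_len(C), dh = 0:2, dw = 0:2, dt = 0:2)
  offsets <- (grid$c - 1L) + C * (grid$dh + Hp * (grid$dw + Wp * grid$dt))
  pos <- expand.grid(ho = seq_len(Ho), wo = seq_len(Wo), to = seq_len(T))
  h0 <- (pos$ho - 1L) * stride + 1L
  w0 <- (pos$wo - 1L) * stride + 1L
  bases <- 1L + C * ((h0 - 1L) + Hp * ((w0 - 1L) + Wp * (pos$to - 1L)))
  idx <- outer(as.integer(offsets), as.integer(bases), `+`)
  # col2im scatter-add as a cached sparse matrix: dxp = S %*% vec(dcols)
  scatter <- Matrix::sparseMatrix(i = as.vector(idx), j = seq_along(idx),
                                  x = 1, dims = c(C * Hp * Wp * Tp,
                                                  length(idx)))
  plan <- list(idx = idx, scatter = scatter, Ho = Ho, Wo = Wo,
               Hp = Hp, Wp = Wp, Tp = Tp,
               rows = nrow(idx), npos = ncol(idx))
  .satsn_cache[[key]] <- plan
  plan
}

pad3 <- function(x) {
  d <- dim(x)
  xp <- array(0, dim = c(d[1L], d[2L] + 2L, d[3L] + 2L, d[4L] + 2L))
  xp[, 2L:(d[2L] + 1L), 2L:(d[3L] + 1L), 2L:(d[4L] + 1L)] <- x
  xp
}

conv3d_fwd <- function(x, W, b, stride = 2L) {
  d <- dim(x)
  plan <- im2col_plan(d[1L], d[2L], d[3L], d[4L], stride)
  xp <- pad3(x)
  cols <- xp[plan$idx]
  dim(cols) <- c(plan$rows, plan$npos)
  y <- W %*% cols + b
  list(y = array(y, dim = c(nrow(W), plan$Ho, plan$Wo, d[4L])),
       cache = list(cols = cols, plan = plan, dims = d, stride = stride))
}

conv3d_bwd <- function(dy, W, cache, need_dx = TRUE) {
  plan <- cache$plan
  dym <- matrix(dy, nrow(W), plan$npos)
  dW <- tcrossprod(dym, cache$cols)
  db <- rowSums(dym)
  dx <- NULL
  if (need_dx) {
    dcols <- crossprod(W, dym)
    d <- cache$dims
    dxp <- array(as.numeric(plan$scatter %*% as.vector(dcols)),
                 dim = c(d[1L], plan$Hp, plan$Wp, plan$Tp))
    dx <- dxp[, 2L:(d[2L] + 1L), 2L:(d[3L] + 1L), 2L:(d[4L] + 1L), drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

# ---- layer norm -------------------------------------------------------------

ln_fwd <- function(x, g, b, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2L, g, `*`) + matrix(b, nrow(x), ncol(x), byrow = TRUE),
       cache = list(xhat = xhat, inv = inv, g = g))
}

ln_bwd <- function(dy, cache) {
  xhat <- cache$xhat; inv <- cache$inv
  dxhat <- sweep(dy, 2L, cache$g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * inv
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

# ---- multi-head self-attention ---------------------------------------------

mha_fwd <- function(x, p, n_heads) {
  N <- nrow(x); D <- ncol(x); dk <- D %/% n_heads
  qkv <- x %*% p$Wqkv + matrix(p$bqkv, N, 3L * D, byrow = TRUE)
  Q <- qkv[, 1:D, drop = FALSE]
  K <- qkv[, D + (1:D), drop = FALSE]
  V <- qkv[, 2L * D + (1:D), drop = FALSE]
  A <- vector("list", n_heads)
  O <- matrix(0, N, D)
  for (h in seq_len(n_heads)) {
    cols <- (h - 1L) * dk + seq_len(dk)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dk)
    A[[h]] <- softmax_rows(S)
    O[, cols] <- A[[h]] %*% V[, cols, drop = FALSE]
  }
  y <- O %*% p$Wo + matrix(p$bo, N, D, byrow = TRUE)
  list(y = y, cache = list(x = x, Q = Q, K = K, V = V, A = A, O = O,
                           n_heads = n_heads, dk = dk))
}

mha_bwd <- function(dy, p, cache) {
  x <- cache$x; N <- nrow(x); D <- ncol(x)
  dk <- cache$dk; n_heads <- cache$n_heads
  dWo <- crossprod(cache$O, dy)
  dbo <- colSums(dy)
  dO <- tcrossprod(dy, p$Wo)
  dQ <- matrix(0, N, D); dK <- matrix(0, N, D); dV <- matrix(0, N, D)
  for (h in seq_len(n_heads)) {
    cols <- (h - 1L) * dk + seq_len(dk)
    A <- cache$A[[h]]
    dOh <- dO[, cols, drop = FALSE]
    dA <- tcrossprod(dOh, cache$V[, cols, drop = FALSE])
    dV[, cols] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(A * dA))
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE] / sqrt(dk)
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE]) / sqrt(dk)
  }
  dqkv <- cbind(dQ, dK, dV)
  list(dx = tcrossprod(dqkv, p$Wqkv),
       dWqkv = crossprod(x, dqkv), dbqkv = colSums(dqkv),
       dWo = dWo, dbo = dbo)
}

# ---- transformer block (pre-norm) ------------------------------------------

block_fwd <- function(z, p, n_heads) {
  l1 <- ln_fwd(z, p$ln1_g, p$ln1_b)
  at <- mha_fwd(l1$y, p, n_heads)
  z1 <- z + at$y
  l2 <- ln_fwd(z1, p$ln2_g, p$ln2_b)
  h <- l2$y %*% p$W1 + matrix(p$b1, nrow(z), length(p$b1), byrow = TRUE)
  a <- gelu(h)
  f <- a %*% p$W2 + matrix(p$b2, nrow(z), length(p$b2), byrow = TRUE)
  list(y = z1 + f,
       cache = list(l1 = l1, at = at, l2 = l2, l2y = l2$y, h = h, a = a))
}

block_bwd <- function(dy, p, cache) {
  g <- list()
  da <- tcrossprod(dy, p$W2)
  g$W2 <- crossprod(cache$a, dy); g$b2 <- colSums(dy)
  dh <- da * gelu_grad(cache$h)
  g$W1 <- crossprod(cache$l2y, dh)
  g$b1 <- colSums(dh)
  dl2 <- tcrossprod(dh, p$W1)
  l2b <- ln_bwd(dl2, cache$l2$cache)
  g$ln2_g <- l2b$dg; g$ln2_b <- l2b$db
  dz1 <- dy + l2b$dx
  ab <- mha_bwd(dz1, p, cache$at$cache)
  g$Wqkv <- ab$dWqkv; g$bqkv <- ab$dbqkv; g$Wo <- ab$dWo; g$bo <- ab$dbo
  l1b <- ln_bwd(ab$dx, cache$l1$cache)
  g$ln1_g <- l1b$dg; g$ln1_b <- l1b$db
  list(dz = dz1 + l1b$dx, grads = g)
}
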