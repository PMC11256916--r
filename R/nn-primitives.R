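# Neural-network primitives: forward passes return a cache carrying every
# intermediate the matching backward pass needs. All parameters live in a
# flat named list; gradients come back in a list with the same names.

relu <- function(x) pmax(x, 0)
lrelu <- function(x, slope = 0.2) x * (slope + (1 - slope) * (x > 0))
lrelu_grad <- function(x, slope = 0.2) slope + (1 - slope) * (x > 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

## ---- row-wise layer normalization -------------------------------------

layernorm_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- sweep(xhat, 2, g, `*`)
  Y <- sweep(Y, 2, b, `+`)
  list(Y = Y, cache = list(xhat = xhat, inv = inv, g = g))
}

layernorm_backward <- function(dY, cache) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2, cache$g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

## ---- dropout ----------------------------------------------------------

dropout_forward <- function(X, rate, train) {
  if (!train || rate <= 0) {
    return(list(Y = X, mask = NULL))
  }
  mask <- matrix(stats::rbinom(length(X), 1L, 1 - rate), nrow(X)) / (1 - rate)
  list(Y = X * mask, mask = mask)
}

dropout_backward <- function(dY, mask) {
  if (is.null(mask)) dY else dY * mask
}

## ---- multi-head self-attention ----------------------------------------

mha_forward <- function(X, Wq, Wk, Wv, Wo, n_heads) {
  d <- ncol(Wq)
  dh <- d %/% n_heads
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  heads <- vector("list", n_heads)
  O <- matrix(0, nrow(X), d)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    S <- (Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE])) / sqrt(dh)
    A <- softmax_rows(S)
    O[, idx] <- A %*% V[, idx, drop = FALSE]
    heads[[h]] <- list(A = A, idx = idx)
  }
  Y <- O %*% Wo
  list(Y = Y,
       cache = list(X = X, Q = Q, K = K, V = V, O = O, heads = heads,
                    Wq = Wq, Wk = Wk, Wv = Wv, Wo = Wo, dh = dh))
}

mha_backward <- function(dY, cache) {
  X <- cache$X
  dWo <- t(cache$O) %*% dY
  dO <- dY %*% t(cache$Wo)
  dQ <- matrix(0, nrow(X), ncol(cache$Q))
  dK <- dQ; dV <- dQ
  for (hd in cache$heads) {
    idx <- hd$idx; A <- hd$A
    dOh <- dO[, idx, drop = FALSE]
    Vh <- cache$V[, idx, drop = FALSE]
    dA <- dOh %*% t(Vh)
    dV[, idx] <- t(A) %*% dOh
    dS <- A * (dA - rowSums(A * dA))
    dS <- dS / sqrt(cache$dh)
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE]
    dK[, idx] <- t(dS) %*% cache$Q[, idx, drop = FALSE]
  }
  dX <- dQ %*% t(cache$Wq) + dK %*% t(cache$Wk) + dV %*% t(cache$Wv)
  list(dX = dX,
       dWq = t(X) %*% dQ, dWk = t(X) %*% dK, dWv = t(X) %*% dV, dWo = dWo)
}

## ---- position-wise feed-forward ----------------------------------------

ffn_forward <- function(X, W1, b1, W2, b2) {
  H0 <- sweep(X %*% W1, 2, b1, `+`)
  H <- relu(H0)
  Y <- sweep(H %*% W2, 2, b2, `+`)
  list(Y = Y, cache = list(X = X, H0 = H0, H = H, W1 = W1, W2 = W2))
}

ffn_backward <- function(dY, cache) {
  dH <- dY %*% t(cache$W2)
  dH0 <- dH * (cache$H0 > 0)
  list(dX = dH0 %*% t(cache$W1),
       dW1 = t(cache$X) %*% dH0, db1 = colSums(dH0),
       dW2 = t(cache$H) %*% dY, db2 = colSums(dY))
}

## ---- transformer encoder block (pre-LN) ---------------------------------
## x1 = x + Drop(MHA(LN1(x))); y = x1 + Drop(FFN(LN2(x1)))
## Pre-LN keeps an unnormalized residual stream: gradients reach early
## layers undamped and the block's output norm is free to vary per node.

transformer_block_forward <- function(X, p, prefix, n_heads, dropout, train) {
  g <- function(s) p[[paste0(prefix, s)]]
  ln1 <- layernorm_forward(X, g("ln1_g"), g("ln1_b"))
  att <- mha_forward(ln1$Y, g("Wq"), g("Wk"), g("Wv"), g("Wo"), n_heads)
  d1 <- dropout_forward(att$Y, dropout, train)
  X1 <- X + d1$Y
  ln2 <- layernorm_forward(X1, g("ln2_g"), g("ln2_b"))
  ff <- ffn_forward(ln2$Y, g("W1"), g("b1"), g("W2"), g("b2"))
  d2 <- dropout_forward(ff$Y, dropout, train)
  list(Y = X1 + d2$Y,
       cache = list(ln1 = ln1$cache, att = att$cache, m1 = d1$mask,
                    ln2 = ln2$cache, ff = ff$cache, m2 = d2$mask))
}

transformer_block_backward <- function(dY, cache, prefix) {
  gr <- list()
  dff <- dropout_backward(dY, cache$m2)
  fb <- ffn_backward(dff, cache$ff)
  gr[[paste0(prefix, "W1")]] <- fb$dW1; gr[[paste0(prefix, "b1")]] <- fb$db1
  gr[[paste0(prefix, "W2")]] <- fb$dW2; gr[[paste0(prefix, "b2")]] <- fb$db2
  l2 <- layernorm_backward(fb$dX, cache$ln2)
  gr[[paste0(prefix, "ln2_g")]] <- l2$dg
  gr[[paste0(prefix, "ln2_b")]] <- l2$db
  dX1 <- dY + l2$dX
  datt <- dropout_backward(dX1, cache$m1)
  ab <- mha_backward(datt, cache$att)
  gr[[paste0(prefix, "Wq")]] <- ab$dWq; gr[[paste0(prefix, "Wk")]] <- ab$dWk
  gr[[paste0(prefix, "Wv")]] <- ab$dWv; gr[[paste0(prefix, "Wo")]] <- ab$dWo
  l1 <- layernorm_backward(ab$dX, cache$ln1)
  gr[[paste0(prefix, "ln1_g")]] <- l1$dg
  gr[[paste0(prefix, "ln1_b")]] <- l1$db
  list(dX = dX1 + l1$dX, grads = gr)
}

## ---- 1-D convolution over the bin axis ----------------------------------
## W: win x Cin x Cout (Cout filters sliding along the bins, same padding)

conv1d_forward <- function(X, W, b) {
  n <- nrow(X); win <- dim(W)[1]; cout <- dim(W)[3]
  left <- (win - 1L) %/% 2L
  right <- win - 1L - left
  Xp <- rbind(matrix(0, left, ncol(X)), X, matrix(0, right, ncol(X)))
  Y <- matrix(rep(b, each = n), n, cout)
  for (t in seq_len(win)) {
    Y <- Y + Xp[t:(t + n - 1L), , drop = FALSE] %*%
      matrix(W[t, , ], dim(W)[2], cout)
  }
  list(Y = Y, cache = list(Xp = Xp, W = W, n = n, left = left))
}

conv1d_backward <- function(dY, cache) {
  n <- cache$n; W <- cache$W; Xp <- cache$Xp
  win <- dim(W)[1]; cout <- dim(W)[3]
  dW <- W * 0
  dXp <- Xp * 0
  for (t in seq_len(win)) {
    rows <- t:(t + n - 1L)
    dW[t, , ] <- t(Xp[rows, , drop = FALSE]) %*% dY
    dXp[rows, ] <- dXp[rows, ] +
      dY %*% t(matrix(W[t, , ], dim(W)[2], cout))
  }
  list(dX = dXp[(cache$left + 1L):(cache$left + n), , drop = FALSE],
       dW = dW, db = colSums(dY))
}

## ---- 2-D convolution (3x3, same padding) via im2col ---------------------

conv2d_forward <- function(X, K, b) {
  # X: n x n x Cin ; K: 3 x 3 x Cin x Cout ; b: length Cout
  n <- dim(X)[1]; cin <- dim(K)[3]; cout <- dim(K)[4]
  Kmat <- matrix(K, nrow = 9L * cin, ncol = cout)
  Y <- conv3x3_fwd(X, Kmat, as.numeric(b))
  list(Y = Y, cache = list(X = X, Kmat = Kmat, n = n, cin = cin,
                           cout = cout))
}

conv2d_backward <- function(dY, cache) {
  if (is.null(dim(dY)) || length(dim(dY)) == 2L) {
    dY <- array(dY, c(cache$n, cache$n, cache$cout))
  }
  bk <- conv3x3_bwd(dY, cache$X, cache$Kmat)
  list(dX = bk$dX,
       dK = array(bk$dK, c(3L, 3L, cache$cin, cache$cout)),
       db = as.numeric(bk$db))
}

## ---- graph attention layer (additive logits with edge term) -------------

gat_forward <- function(Z, E, W1, W2, w3, a, slope = 0.2) {
  n <- nrow(Z); d <- ncol(Z)
  S1 <- Z %*% W1
  S2 <- Z %*% W2
  mask <- E != 0
  diag(mask) <- FALSE
  # logits l_ij = a . LeakyReLU(W1 z_i + W2 z_j + w3 * e_ij)
  logits <- gat_logits_fwd(S1, S2, E, w3, a, slope)
  logits[!mask] <- -Inf
  rowmax <- apply(logits, 1, max)
  rowmax[!is.finite(rowmax)] <- 0  # isolated nodes
  Ew <- exp(logits - rowmax)
  Ew[!mask] <- 0
  rs <- rowSums(Ew)
  rs[rs == 0] <- 1
  A <- Ew / rs
  Y <- S1 + A %*% S2
  list(Y = Y, alpha = A,
       cache = list(Z = Z, E = E, S1 = S1, S2 = S2, A = A, mask = mask,
                    W1 = W1, W2 = W2, w3 = w3, a = a, slope = slope))
}

gat_backward <- function(dY, cache, dA_extra = NULL) {
  Z <- cache$Z; A <- cache$A
  dS1 <- dY
  dS2 <- t(A) %*% dY
  dA <- dY %*% t(cache$S2)
  if (!is.null(dA_extra)) dA <- dA + dA_extra
  # softmax rows (masked); rows with no neighbors have A = 0 -> dl = 0
  dl <- A * (dA - rowSums(A * dA))
  dl[!cache$mask] <- 0
  pg <- gat_logits_bwd(dl, cache$S1, cache$S2, cache$E, cache$w3, cache$a,
                       cache$slope)
  dS1 <- dS1 + pg$dS1
  dS2 <- dS2 + pg$dS2
  dZ <- dS1 %*% t(cache$W1) + dS2 %*% t(cache$W2)
  list(dX = dZ,
       dW1 = t(Z) %*% dS1, dW2 = t(Z) %*% dS2, dw3 = as.numeric(pg$dw3),
       da = as.numeric(pg$da))
}
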