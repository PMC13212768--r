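# Minimal neural-network primitives with manual backpropagation.
# Feature maps on the structured lattice are stored as (H*W) x C matrices,
# H = axial stations (reflective padding), W = circumferential sectors
# (cyclic padding); row index = (i - 1) * W + k.

relu <- function(x) (x + abs(x)) * 0.5
drelu <- function(z) (z > 0) * 1

glorot <- function(nin, nout, shape = c(nin, nout)) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(prod(shape), -lim, lim), shape[1], shape[2])
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1c <- 1 - beta1^state$t; b2c <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / b1c) / (sqrt(state$v[[nm]] / b2c) + eps)
  }
  list(params = params, state = state)
}

# accumulate gradient lists (same structure)
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}
grad_scale <- function(g, s) lapply(g, function(x) x * s)

# ---- 3x3 convolution contexts -----------------------------------------------

.conv_cache <- new.env(parent = emptyenv())

# neighbour index map and scatter matrices for a 3x3 stencil on an H x W
# lattice: rows reflective, columns cyclic
conv_ctx <- function(H, W) {
  key <- paste0(H, "x", W)
  if (!is.null(.conv_cache[[key]])) return(.conv_cache[[key]])
  refl <- function(i, n) { i[i < 1L] <- 2L - i[i < 1L]
                           i[i > n] <- 2L * n - i[i > n]; i }
  cyc <- function(k, n) ((k - 1L) %% n) + 1L
  i <- rep(seq_len(H), each = W)
  k <- rep(seq_len(W), H)
  idx <- matrix(0L, H * W, 9L)
  m <- 0L
  for (di in -1:1) for (dk in -1:1) {
    m <- m + 1L
    idx[, m] <- (refl(i + di, H) - 1L) * W + cyc(k + dk, W)
  }
  scat <- lapply(seq_len(9L), function(m)
    Matrix::sparseMatrix(i = idx[, m], j = seq_len(H * W), x = 1,
                         dims = c(H * W, H * W)))
  ctx <- list(idx = idx, scat = scat, H = H, W = W)
  .conv_cache[[key]] <- ctx
  ctx
}

# X: (HW x Cin); K: (9*Cin x Cout); returns list(Y, P)
conv3_forward <- function(X, K, b, ctx) {
  Cin <- ncol(X)
  P <- matrix(0, nrow(X), 9L * Cin)
  for (m in seq_len(9L))
    P[, ((m - 1L) * Cin + 1L):(m * Cin)] <- X[ctx$idx[, m], , drop = FALSE]
  Y <- P %*% K
  Y <- sweep(Y, 2L, b, "+")
  list(Y = Y, P = P)
}

conv3_backward <- function(dY, K, cache, ctx, Cin) {
  dK <- crossprod(cache$P, dY)
  db <- colSums(dY)
  dP <- dY %*% t(K)
  dX <- matrix(0, nrow(dY), Cin)
  for (m in seq_len(9L)) {
    dPm <- dP[, ((m - 1L) * Cin + 1L):(m * Cin), drop = FALSE]
    dX <- dX + as.matrix(ctx$scat[[m]] %*% dPm)
  }
  list(dX = dX, dK = dK, db = db)
}

# ---- per-channel spatial normalization (instance variant of batch norm) -----

inorm_forward <- function(X, gamma, beta, eps = 1e-5) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  v <- colMeans(Xc^2)
  inv <- 1 / sqrt(v + eps)
  Xh <- sweep(Xc, 2L, inv, "*")
  Y <- sweep(sweep(Xh, 2L, gamma, "*"), 2L, beta, "+")
  list(Y = Y, Xh = Xh, inv = inv)
}

inorm_backward <- function(dY, gamma, cache) {
  N <- nrow(dY)
  dgamma <- colSums(dY * cache$Xh)
  dbeta <- colSums(dY)
  dXh <- sweep(dY, 2L, gamma, "*")
  # d/dX of (X - mu) / sqrt(var + eps) per channel
  t1 <- dXh
  t2 <- matrix(colMeans(dXh), nrow(dY), ncol(dY), byrow = TRUE)
  t3 <- sweep(cache$Xh, 2L, colMeans(dXh * cache$Xh), "*")
  dX <- sweep(t1 - t2 - t3, 2L, cache$inv, "*")
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- 2x2 max pooling --------------------------------------------------------

pool_ctx <- function(H, W) {
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  Ho <- H %/% 2L; Wo <- W %/% 2L
  io <- rep(seq_len(Ho), each = Wo); ko <- rep(seq_len(Wo), Ho)
  members <- cbind((2L * io - 2L) * W + (2L * ko - 1L),
                   (2L * io - 2L) * W + 2L * ko,
                   (2L * io - 1L) * W + (2L * ko - 1L),
                   (2L * io - 1L) * W + 2L * ko)
  list(members = members, Ho = Ho, Wo = Wo)
}

maxpool_forward <- function(X, pctx) {
  C <- ncol(X)
  Y <- matrix(0, nrow(pctx$members), C)
  arg <- matrix(0L, nrow(pctx$members), C)
  for (c_ in seq_len(C)) {
    vals <- matrix(X[pctx$members, c_], nrow(pctx$members), 4L)
    arg[, c_] <- max.col(vals, ties.method = "first")
    Y[, c_] <- vals[cbind(seq_len(nrow(vals)), arg[, c_])]
  }
  list(Y = Y, arg = arg)
}

maxpool_backward <- function(dY, cache, pctx, H, W) {
  C <- ncol(dY)
  dX <- matrix(0, H * W, C)
  for (c_ in seq_len(C)) {
    src <- pctx$members[cbind(seq_len(nrow(pctx$members)), cache$arg[, c_])]
    dX[src, c_] <- dX[src, c_] + dY[, c_]
  }
  dX
}

# ---- 2x2 stride-2 transpose convolution -------------------------------------

# X: (HW x Cin), K: (Cin x 4*Cout); output (2H*2W x Cout)
tconv_ctx <- function(H, W) {
  Ho <- 2L * H; Wo <- 2L * W
  i <- rep(seq_len(H), each = W); k <- rep(seq_len(W), H)
  dest <- cbind((2L * i - 2L) * Wo + (2L * k - 1L),
                (2L * i - 2L) * Wo + 2L * k,
                (2L * i - 1L) * Wo + (2L * k - 1L),
                (2L * i - 1L) * Wo + 2L * k)
  list(dest = dest, Ho = Ho, Wo = Wo)
}

tconv_forward <- function(X, K, b, tctx) {
  Cout <- ncol(K) %/% 4L
  Z <- X %*% K                                 # HW x 4Cout
  Y <- matrix(0, tctx$Ho * tctx$Wo, Cout)
  for (q in seq_len(4L))
    Y[tctx$dest[, q], ] <- Z[, ((q - 1L) * Cout + 1L):(q * Cout), drop = FALSE]
  sweep(Y, 2L, b, "+")
}

tconv_backward <- function(dY, X, K, tctx) {
  Cout <- ncol(K) %/% 4L
  dZ <- matrix(0, nrow(X), 4L * Cout)
  for (q in seq_len(4L))
    dZ[, ((q - 1L) * Cout + 1L):(q * Cout)] <- dY[tctx$dest[, q], , drop = FALSE]
  list(dX = dZ %*% t(K), dK = crossprod(X, dZ), db = colSums(dY))
}

# ---- dense layer ------------------------------------------------------------

dense_forward <- function(X, W, b) sweep(X %*% W, 2L, b, "+")

dense_backward <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

# ---- dropout ----------------------------------------------------------------

dropout_mask <- function(n, p) {
  if (p <= 0) return(NULL)
  matrix((runif(n) >= p) / (1 - p), nrow = 1L)[1, ]
}
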