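# ---- U-Net ------------------------------------------------------------------

#' Initialize a U-Net surrogate
#'
#' Symmetric encoder-decoder over the structured (axial x circumferential)
#' grid. Each level applies two 3x3 convolutions (reflective axial / cyclic
#' circumferential padding), each followed by per-channel normalization and
#' ReLU, then 2x2 max pooling; the bottleneck doubles the deepest width; the
#' decoder mirrors the encoder with 2x2 transpose-convolution upsampling and
#' skip concatenation; a final 1x1 linear convolution emits one value per
#' node. Dropout rates increase linearly from `dropout[1]` to `dropout[2]`
#' with depth (training only). Both grid dimensions must be divisible by
#' `2^depth`.
#'
#' @param input_shape `c(n_axial, n_theta)` of the (cropped) grid.
#' @param in_channels input feature channels (default 8).
#' @param channels encoder widths per level (default `c(64, 128, 256)`; the
#'   desk preset trains a narrower, shallower net).
#' @param bottleneck bottleneck width (default `2 * tail(channels, 1)`).
#' @param dropout `c(shallow, deep)` dropout rates (default `c(0.1, 0.3)`).
#' @param seed RNG seed for initialization.
#' @return An object of class `unet_model`.
#' @export
unet_init <- function(input_shape, in_channels = 8L,
                      channels = c(64L, 128L, 256L),
                      bottleneck = 2L * channels[length(channels)],
                      dropout = c(0.1, 0.3), seed = 1L) {
  d <- length(channels)
  if (any(input_shape %% 2L^d != 0L))
    stop(sprintf("shape: grid %d x %d not divisible by 2^%d",
                 input_shape[1], input_shape[2], d))
  with_seed(seed, {
    p <- list()
    cin <- in_channels
    for (l in seq_len(d)) {
      cl <- channels[l]
      p[[paste0("e", l, "K1")]] <- glorot(9 * cin, cl)
      p[[paste0("e", l, "c1b")]] <- rep(0, cl)
      p[[paste0("e", l, "g1")]] <- rep(1, cl); p[[paste0("e", l, "n1b")]] <- rep(0, cl)
      p[[paste0("e", l, "K2")]] <- glorot(9 * cl, cl)
      p[[paste0("e", l, "c2b")]] <- rep(0, cl)
      p[[paste0("e", l, "g2")]] <- rep(1, cl); p[[paste0("e", l, "n2b")]] <- rep(0, cl)
      cin <- cl
    }
    p$bK1 <- glorot(9 * cin, bottleneck); p$bc1b <- rep(0, bottleneck)
    p$bg1 <- rep(1, bottleneck); p$bn1b <- rep(0, bottleneck)
    p$bK2 <- glorot(9 * bottleneck, bottleneck); p$bc2b <- rep(0, bottleneck)
    p$bg2 <- rep(1, bottleneck); p$bn2b <- rep(0, bottleneck)
    cprev <- bottleneck
    for (l in rev(seq_len(d))) {
      cl <- channels[l]
      p[[paste0("u", l, "K")]] <- glorot(cprev, 4 * cl) # transpose conv
      p[[paste0("u", l, "b")]] <- rep(0, cl)
      p[[paste0("d", l, "K1")]] <- glorot(9 * 2 * cl, cl)
      p[[paste0("d", l, "c1b")]] <- rep(0, cl)
      p[[paste0("d", l, "g1")]] <- rep(1, cl); p[[paste0("d", l, "n1b")]] <- rep(0, cl)
      p[[paste0("d", l, "K2")]] <- glorot(9 * cl, cl)
      p[[paste0("d", l, "c2b")]] <- rep(0, cl)
      p[[paste0("d", l, "g2")]] <- rep(1, cl); p[[paste0("d", l, "n2b")]] <- rep(0, cl)
      cprev <- cl
    }
    p$outW <- glorot(channels[1], 1L); p$outb <- 0
    structure(list(params = p, channels = channels, bottleneck = bottleneck,
                   in_channels = in_channels, input_shape = input_shape,
                   dropout = dropout, depth = d, input_stats = NULL),
              class = "unet_model")
  })
}

# one conv->norm->relu unit; returns activation and cache
.cnr_fwd <- function(X, K, cb, g, nb, ctx) {
  cv <- conv3_forward(X, K, cb, ctx)
  nm <- inorm_forward(cv$Y, g, nb)
  list(A = relu(nm$Y), P = cv$P, nm = nm, Zn = nm$Y)
}

.cnr_bwd <- function(dA, cache, K, g, ctx, Cin) {
  dZ <- dA * drelu(cache$Zn)
  nb <- inorm_backward(dZ, g, cache$nm)
  cb <- conv3_backward(nb$dX, K, cache, ctx, Cin)
  list(dX = cb$dX, dK = cb$dK, dcb = cb$db, dg = nb$dgamma, dnb = nb$dbeta)
}

#' U-Net forward pass
#'
#' @param tensor an `input_tensor` (n x m x C).
#' @param model a `unet_model`.
#' @param train apply dropout (default FALSE).
#' @param return_cache keep intermediates for backprop.
#' @return Predicted (n x m) matrix (normalized scale), or
#'   `list(pred, cache)`.
#' @export
unet_forward <- function(tensor, model, train = FALSE, return_cache = FALSE) {
  d0 <- dim(tensor)
  if (length(d0) != 3L || d0[3] != model$in_channels ||
      any(d0[1:2] != model$input_shape))
    stop(sprintf("shape: input %s does not conform to %d x %d x %d",
                 paste(d0, collapse = " x "),
                 model$input_shape[1], model$input_shape[2],
                 model$in_channels))
  p <- model$params; d <- model$depth
  H <- model$input_shape[1]; W <- model$input_shape[2]
  drate <- if (d > 1)
    seq(model$dropout[1], model$dropout[2], length.out = d + 1L)
  else c(model$dropout[1], model$dropout[2])
  X <- standardize_features(tensor_to_node_matrix(tensor), model$input_stats)
  cache <- list(enc = vector("list", d), dec = vector("list", d), dims = d0)
  skips <- vector("list", d)
  h <- H; w <- W
  for (l in seq_len(d)) {
    ctx <- conv_ctx(h, w)
    u1 <- .cnr_fwd(X, p[[paste0("e", l, "K1")]], p[[paste0("e", l, "c1b")]],
                   p[[paste0("e", l, "g1")]], p[[paste0("e", l, "n1b")]], ctx)
    u2 <- .cnr_fwd(u1$A, p[[paste0("e", l, "K2")]], p[[paste0("e", l, "c2b")]],
                   p[[paste0("e", l, "g2")]], p[[paste0("e", l, "n2b")]], ctx)
    A <- u2$A
    mk <- if (train && drate[l] > 0) dropout_mask(length(A), drate[l]) else NULL
    if (!is.null(mk)) A <- A * mk
    skips[[l]] <- A
    pc <- pool_ctx(h, w)
    pl <- maxpool_forward(A, pc)
    cache$enc[[l]] <- list(u1 = u1, u2 = u2, mask = mk, pool = pl,
                           h = h, w = w, Xin = X)
    X <- pl$Y; h <- h %/% 2L; w <- w %/% 2L
  }
  ctx <- conv_ctx(h, w)
  b1 <- .cnr_fwd(X, p$bK1, p$bc1b, p$bg1, p$bn1b, ctx)
  b2 <- .cnr_fwd(b1$A, p$bK2, p$bc2b, p$bg2, p$bn2b, ctx)
  A <- b2$A
  mkb <- if (train && drate[d + 1L] > 0) dropout_mask(length(A), drate[d + 1L]) else NULL
  if (!is.null(mkb)) A <- A * mkb
  cache$bott <- list(b1 = b1, b2 = b2, mask = mkb, h = h, w = w, Xin = X)
  X <- A
  for (l in rev(seq_len(d))) {
    tc <- tconv_ctx(h, w)
    up <- tconv_forward(X, p[[paste0("u", l, "K")]], p[[paste0("u", l, "b")]], tc)
    h <- 2L * h; w <- 2L * w
    cat_in <- cbind(skips[[l]], up)
    ctx <- conv_ctx(h, w)
    u1 <- .cnr_fwd(cat_in, p[[paste0("d", l, "K1")]], p[[paste0("d", l, "c1b")]],
                   p[[paste0("d", l, "g1")]], p[[paste0("d", l, "n1b")]], ctx)
    u2 <- .cnr_fwd(u1$A, p[[paste0("d", l, "K2")]], p[[paste0("d", l, "c2b")]],
                   p[[paste0("d", l, "g2")]], p[[paste0("d", l, "n2b")]], ctx)
    cache$dec[[l]] <- list(up_in = X, u1 = u1, u2 = u2, cat_in = cat_in,
                           h = h, w = w)
    X <- u2$A
  }
  out <- as.vector(X %*% p$outW + p$outb)
  pred <- matrix(out, H, W, byrow = TRUE)
  if (!return_cache) return(pred)
  cache$final_in <- X
  list(pred = pred, cache = cache)
}

# gradients of all parameters given dL/dpred
unet_backward <- function(dpred, model, cache) {
  p <- model$params; d <- model$depth
  g <- list()
  dX <- matrix(as.vector(t(dpred)), ncol = 1L)
  g$outW <- crossprod(cache$final_in, dX); g$outb <- sum(dX)
  dX <- dX %*% t(p$outW)
  for (l in seq_len(d)) {           # decoder, shallow -> deep
    dc <- cache$dec[[l]]
    ctx <- conv_ctx(dc$h, dc$w)
    cl <- model$channels[l]
    b2 <- .cnr_bwd(dX, dc$u2, p[[paste0("d", l, "K2")]],
                   p[[paste0("d", l, "g2")]], ctx, cl)
    g[[paste0("d", l, "K2")]] <- b2$dK; g[[paste0("d", l, "c2b")]] <- b2$dcb
    g[[paste0("d", l, "g2")]] <- b2$dg; g[[paste0("d", l, "n2b")]] <- b2$dnb
    b1 <- .cnr_bwd(b2$dX, dc$u1, p[[paste0("d", l, "K1")]],
                   p[[paste0("d", l, "g1")]], ctx, 2L * cl)
    g[[paste0("d", l, "K1")]] <- b1$dK; g[[paste0("d", l, "c1b")]] <- b1$dcb
    g[[paste0("d", l, "g1")]] <- b1$dg; g[[paste0("d", l, "n1b")]] <- b1$dnb
    dskip <- b1$dX[, seq_len(cl), drop = FALSE]
    dup <- b1$dX[, cl + seq_len(cl), drop = FALSE]
    tc <- tconv_ctx(dc$h %/% 2L, dc$w %/% 2L)
    tb <- tconv_backward(dup, dc$up_in, p[[paste0("u", l, "K")]], tc)
    g[[paste0("u", l, "K")]] <- tb$dK; g[[paste0("u", l, "b")]] <- tb$db
    # stash: gradient flowing into the encoder skip at this level
    cache$enc[[l]]$dskip <- dskip
    dX <- tb$dX
  }
  bt <- cache$bott
  if (!is.null(bt$mask)) dX <- dX * bt$mask
  ctx <- conv_ctx(bt$h, bt$w)
  cb <- model$bottleneck
  b2 <- .cnr_bwd(dX, bt$b2, p$bK2, p$bg2, ctx, cb)
  g$bK2 <- b2$dK; g$bc2b <- b2$dcb; g$bg2 <- b2$dg; g$bn2b <- b2$dnb
  b1 <- .cnr_bwd(b2$dX, bt$b1, p$bK1, p$bg1, ctx,
                 model$channels[d])
  g$bK1 <- b1$dK; g$bc1b <- b1$dcb; g$bg1 <- b1$dg; g$bn1b <- b1$dnb
  dX <- b1$dX
  for (l in rev(seq_len(d))) {      # encoder, deep -> shallow
    ec <- cache$enc[[l]]
    pc <- pool_ctx(ec$h, ec$w)
    dA <- maxpool_backward(dX, ec$pool, pc, ec$h, ec$w) + ec$dskip
    if (!is.null(ec$mask)) dA <- dA * ec$mask
    ctx <- conv_ctx(ec$h, ec$w)
    cl <- model$channels[l]
    cin <- if (l == 1L) model$in_channels else model$channels[l - 1L]
    b2 <- .cnr_bwd(dA, ec$u2, p[[paste0("e", l, "K2")]],
                   p[[paste0("e", l, "g2")]], ctx, cl)
    g[[paste0("e", l, "K2")]] <- b2$dK; g[[paste0("e", l, "c2b")]] <- b2$dcb
    g[[paste0("e", l, "g2")]] <- b2$dg; g[[paste0("e", l, "n2b")]] <- b2$dnb
    b1 <- .cnr_bwd(b2$dX, ec$u1, p[[paste0("e", l, "K1")]],
                   p[[paste0("e", l, "g1")]], ctx, cin)
    g[[paste0("e", l, "K1")]] <- b1$dK; g[[paste0("e", l, "c1b")]] <- b1$dcb
    g[[paste0("e", l, "g1")]] <- b1$dg; g[[paste0("e", l, "n1b")]] <- b1$dnb
    dX <- b1$dX
  }
  g
}

# ---- composite U-Net loss ---------------------------------------------------

#' U-Net loss configuration
#'
#' Weights of `L = L_MSE + lambda1 L_relative + lambda2 L_smoothness`.
#'
#' @param lambda1 relative-error weight (default 0.1).
#' @param lambda2 smoothness weight (default 0.05).
#' @param eps_rel stabilizer of the relative term denominator (default 0.1).
#' @return A list of class `unet_loss_config`.
#' @export
unet_loss_config <- function(lambda1 = 0.1, lambda2 = 0.05, eps_rel = 0.1) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, eps_rel > 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, eps_rel = eps_rel),
            class = "unet_loss_config")
}

#' Composite U-Net loss
#'
#' `L_MSE` mean squared node error; `L_relative` mean of
#' `|y - yhat| / (|y| + eps)`; `L_smoothness` mean of squared
#' forward-difference gradients of the prediction in both grid directions
#' (circumferential differences wrap, axial do not).
#'
#' @param pred,target (n x m) matrices (or `wss_field`s) on the same grid.
#' @param config a [unet_loss_config()].
#' @param return_grad also return the gradient w.r.t. `pred`.
#' @return list with `total`, `mse`, `relative`, `smoothness`
#'   (and `grad`).
#' @export
unet_loss <- function(pred, target, config = unet_loss_config(),
                      return_grad = FALSE) {
  P <- if (inherits(pred, "wss_field")) pred$values else as.matrix(pred)
  Y <- if (inherits(target, "wss_field")) target$values else as.matrix(target)
  if (!all(dim(P) == dim(Y))) stop("shape: pred/target disagree")
  n <- nrow(P); m <- ncol(P); N <- n * m
  err <- P - Y
  mse <- mean(err^2)
  den <- abs(Y) + config$eps_rel
  rel <- mean(abs(err) / den)
  dax <- P[-1L, , drop = FALSE] - P[-n, , drop = FALSE]
  dci <- P[, c(2:m, 1L), drop = FALSE] - P
  smo <- (sum(dax^2) + sum(dci^2)) / N
  out <- list(total = mse + config$lambda1 * rel + config$lambda2 * smo,
              mse = mse, relative = rel, smoothness = smo)
  if (return_grad) {
    gsm <- matrix(0, n, m)
    gsm[-1L, ] <- gsm[-1L, ] + 2 * dax
    gsm[-n, ] <- gsm[-n, ] - 2 * dax
    gsm <- gsm - 2 * dci
    gsm[, c(2:m, 1L)] <- gsm[, c(2:m, 1L)] + 2 * dci
    out$grad <- 2 * err / N + config$lambda1 * sign(err) / den / N +
      config$lambda2 * gsm / N
  }
  out
}
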