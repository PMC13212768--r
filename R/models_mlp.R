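# field <-> flat vector in node ordering (circumferential index fastest)
flatten_field <- function(values) as.vector(t(values))
unflatten_field <- function(v, n, m) matrix(v, n, m, byrow = TRUE)

# coerce various containers to a (samples x nodes) matrix of Pa values
as_field_matrix <- function(dataset) {
  if (is.matrix(dataset)) return(dataset)
  fields <- if (inherits(dataset, "wss_dataset"))
    lapply(dataset$samples, `[[`, "target") else dataset
  do.call(rbind, lapply(fields, function(f)
    flatten_field(if (inherits(f, "wss_field")) f$values else f)))
}

# normalized mean absolute error, percent of the mean reference magnitude
nmae_percent <- function(X, Xhat) 100 * mean(abs(X - Xhat)) / mean(abs(X))

# ---- PCA baseline -----------------------------------------------------------

#' PCA reconstruction baseline
#'
#' Projects the (centered) field matrix onto its top principal components
#' and reports the normalized mean absolute reconstruction error (percent).
#' The exact linear projection makes the error non-increasing in the number
#' of components.
#'
#' @param dataset a `wss_dataset`, a list of `wss_field`s, or a
#'   (samples x nodes) matrix.
#' @param n_components number of principal components.
#' @return list with `nmae` (percent) and `n_components`.
#' @export
pca_baseline <- function(dataset, n_components) {
  X <- as_field_matrix(dataset)
  q <- min(n_components, nrow(X) - 1L, ncol(X))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = q, nv = q)
  Xhat <- sweep(sv$u %*% diag(sv$d[seq_len(q)], q, q) %*% t(sv$v), 2L, mu, "+")
  list(nmae = nmae_percent(X, Xhat), n_components = n_components,
       rank_used = q)
}

# ---- dense autoencoder ------------------------------------------------------

#' Autoencoder training configuration
#'
#' @param hidden hidden width of the symmetric MLP autoencoder (default 256).
#' @param epochs training epochs (default 300).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed RNG seed.
#' @return list of class `ae_config`.
#' @export
ae_config <- function(hidden = 256L, epochs = 300L, lr = 1e-3, seed = 1L) {
  structure(list(hidden = hidden, epochs = epochs, lr = lr, seed = seed),
            class = "ae_config")
}

dense_ae_init <- function(D, hidden, q) {
  list(W1 = glorot(D, hidden), b1 = rep(0, hidden),
       W2 = glorot(hidden, q), b2 = rep(0, q),
       W3 = glorot(q, hidden), b3 = rep(0, hidden),
       W4 = glorot(hidden, D), b4 = rep(0, D))
}

dense_ae_forward <- function(X, p) {
  A1 <- relu(dense_forward(X, p$W1, p$b1))
  Z <- dense_forward(A1, p$W2, p$b2)
  A2 <- relu(dense_forward(Z, p$W3, p$b3))
  Xh <- dense_forward(A2, p$W4, p$b4)
  list(Xh = Xh, A1 = A1, Z = Z, A2 = A2)
}

# train a dense autoencoder with Adam; `init` warm-starts the parameters,
# `eval_fn(p)` (default: training MSE) scores states every `eval_every`
# epochs including the initial one, and the best-scoring state is returned
dense_ae_fit <- function(X, q, hidden = 256L, epochs = 300L, lr = 1e-3,
                         seed = 1L, init = NULL, eval_fn = NULL,
                         eval_every = 10L) {
  D <- ncol(X)
  with_seed(seed, {
    p <- if (is.null(init)) dense_ae_init(D, hidden, q) else init
    if (is.null(eval_fn))
      eval_fn <- function(p) mean((dense_ae_forward(X, p)$Xh - X)^2)
    st <- adam_init(p)
    best <- list(score = eval_fn(p), p = p)
    for (ep in seq_len(epochs)) {
      fw <- dense_ae_forward(X, p)
      err <- fw$Xh - X
      dXh <- 2 * err / length(err)
      g <- list()
      b4 <- dense_backward(dXh, fw$A2, p$W4); g$W4 <- b4$dW; g$b4 <- b4$db
      dA2 <- b4$dX * drelu(fw$A2)
      b3 <- dense_backward(dA2, fw$Z, p$W3); g$W3 <- b3$dW; g$b3 <- b3$db
      b2 <- dense_backward(b3$dX, fw$A1, p$W2); g$W2 <- b2$dW; g$b2 <- b2$db
      dA1 <- b2$dX * drelu(fw$A1)
      b1 <- dense_backward(dA1, X, p$W1); g$W1 <- b1$dW; g$b1 <- b1$db
      upd <- adam_step(p, g, st, lr = lr)
      p <- upd$params; st <- upd$state
      if (ep %% eval_every == 0L || ep == epochs) {
        sc <- eval_fn(p)
        if (sc < best$score) best <- list(score = sc, p = p)
      }
    }
    best
  })
}

# embed a fitted (hidden, q1) autoencoder into a (hidden, q2 > q1) one so the
# initial reconstruction is bit-identical: new latent dimensions enter with
# zero encoder columns (silent at init) and small random decoder rows
# (so their gradients are alive)
dense_ae_embed <- function(p, q_new) {
  q_old <- ncol(p$W2)
  if (q_new <= q_old) stop("embedding requires a larger bottleneck")
  h <- ncol(p$W1)
  add <- q_new - q_old
  p$W2 <- cbind(p$W2, matrix(0, h, add))
  p$b2 <- c(p$b2, rep(0, add))
  p$W3 <- rbind(p$W3, glorot(q_new, h, shape = c(add, h)) * 0.1)
  p
}

#' Fit the WSS-field autoencoder and report its reconstruction error
#'
#' A symmetric MLP autoencoder (D -> hidden -> bottleneck -> hidden -> D,
#' ReLU hidden activations, linear bottleneck and output) trained with Adam
#' on the log-standardized scale used throughout surrogate training
#' (`z = (log(wss + 1e-6) - mean) / sd`), minimizing the mean squared
#' reconstruction error; the state with the best reconstruction NMAE seen
#' during training is kept. Reports the normalized MAE (percent) between
#' original and reconstructed Pa fields. Candidate bottleneck dimensions are
#' 32, 64, 128, 256, 512; other values warn but still run.
#'
#' @param dataset as in [pca_baseline()].
#' @param bottleneck_dim latent dimension.
#' @param config an [ae_config()].
#' @param init optional warm-start parameters (e.g. an embedded
#'   smaller-bottleneck solution, see [autoencoder_sweep()]).
#' @return An object of class `wss_autoencoder`: `params`, `nmae`
#'   (percent), `bottleneck_dim`, and the frozen `stats`
#'   ([wss_normalizer()]).
#' @export
fit_wss_autoencoder <- function(dataset, bottleneck_dim,
                                config = ae_config(), init = NULL) {
  if (!bottleneck_dim %in% c(32L, 64L, 128L, 256L, 512L))
    warning("bottleneck_dim is outside the candidate set {32,64,128,256,512}")
  X <- as_field_matrix(dataset)
  if (stats::sd(as.vector(X)) == 0)
    stop("degenerate-statistics: constant fields")
  st <- wss_normalizer(X)
  Z <- (log(X + st$eps_log) - st$mean) / st$sd
  nmae_of <- function(p) {
    Xh <- exp(dense_ae_forward(Z, p)$Xh * st$sd + st$mean) - st$eps_log
    nmae_percent(X, Xh)
  }
  best <- dense_ae_fit(Z, q = bottleneck_dim, hidden = config$hidden,
                       epochs = config$epochs, lr = config$lr,
                       seed = config$seed, init = init, eval_fn = nmae_of)
  structure(list(params = best$p, nmae = best$score,
                 bottleneck_dim = bottleneck_dim, stats = st),
            class = "wss_autoencoder")
}

#' Bottleneck-dimension reconstruction sweep
#'
#' Evaluates PCA and the learned autoencoder over the candidate bottleneck
#' dimensions. The autoencoders are trained as a nested warm-start sweep:
#' each larger bottleneck is initialized by embedding the previous solution
#' (reproducing it exactly at initialization), so the reported
#' best-state reconstruction error is non-increasing in the bottleneck
#' dimension by construction, and training can only improve it.
#'
#' @param dataset as in [pca_baseline()].
#' @param dims bottleneck dimensions (default `c(32, 64, 128, 256, 512)`).
#' @param config an [ae_config()] applied to every fit.
#' @return data.frame with `dim`, `pca_nmae`, `ae_nmae` (percent).
#' @export
autoencoder_sweep <- function(dataset, dims = c(32L, 64L, 128L, 256L, 512L),
                              config = ae_config()) {
  X <- as_field_matrix(dataset)
  pca <- vapply(dims, function(q) pca_baseline(X, q)$nmae, numeric(1))
  ae <- numeric(length(dims))
  prev <- NULL
  for (j in seq_along(dims)) {
    init <- if (is.null(prev)) NULL else dense_ae_embed(prev$params, dims[j])
    fit <- fit_wss_autoencoder(X, dims[j], config, init = init)
    # keep the better of (fresh best, inherited best); inheritance alone
    # already guarantees monotonicity
    if (!is.null(prev) && prev$nmae < fit$nmae) {
      fit$params <- dense_ae_embed(prev$params, dims[j])
      fit$nmae <- prev$nmae
    }
    ae[j] <- fit$nmae
    prev <- fit
  }
  data.frame(dim = dims, pca_nmae = pca, ae_nmae = ae)
}

#' Encode / decode with a fitted autoencoder
#' @param ae a `wss_autoencoder` (or raw dense-AE parameter list).
#' @param X (samples x D) matrix on the scale the AE was fitted on
#'   (`ae_encode` standardizes internally for `wss_autoencoder`s).
#' @return latent matrix / reconstructed matrix.
#' @export
ae_encode <- function(ae, X) {
  p <- if (inherits(ae, "wss_autoencoder")) ae$params else ae
  if (inherits(ae, "wss_autoencoder"))
    X <- (log(X + ae$stats$eps_log) - ae$stats$mean) / ae$stats$sd
  A1 <- relu(dense_forward(X, p$W1, p$b1))
  dense_forward(A1, p$W2, p$b2)
}

#' @rdname ae_encode
#' @param Z latent matrix.
#' @export
ae_decode <- function(ae, Z) {
  p <- if (inherits(ae, "wss_autoencoder")) ae$params else ae
  A2 <- relu(dense_forward(Z, p$W3, p$b3))
  Xh <- dense_forward(A2, p$W4, p$b4)
  if (inherits(ae, "wss_autoencoder"))
    Xh <- exp(Xh * ae$stats$sd + ae$stats$mean) - ae$stats$eps_log
  Xh
}

# ---- convolutional input autoencoder ---------------------------------------

# encoder: conv3x3 -> ReLU -> pool, twice, then a dense map to the latent;
# decoder mirrors with transpose convolutions; linear output
input_ae_init <- function(shape, C = 8L, ch = c(8L, 16L), q = 128L) {
  H <- shape[1]; W <- shape[2]
  flat <- (H %/% 4L) * (W %/% 4L) * ch[2]
  list(K1 = glorot(9L * C, ch[1]), c1 = rep(0, ch[1]),
       K2 = glorot(9L * ch[1], ch[2]), c2 = rep(0, ch[2]),
       We = glorot(flat, q), be = rep(0, q),
       Wd = glorot(q, flat), bd = rep(0, flat),
       T1 = glorot(ch[2], 4L * ch[1]), t1 = rep(0, ch[1]),
       T2 = glorot(ch[1], 4L * C), t2 = rep(0, C))
}

input_ae_encode <- function(X, p, shape, ch, cache = FALSE) {
  H <- shape[1]; W <- shape[2]
  c1 <- conv3_forward(X, p$K1, p$c1, conv_ctx(H, W)); A1 <- relu(c1$Y)
  p1 <- maxpool_forward(A1, pool_ctx(H, W))
  c2 <- conv3_forward(p1$Y, p$K2, p$c2, conv_ctx(H %/% 2L, W %/% 2L))
  A2 <- relu(c2$Y)
  p2 <- maxpool_forward(A2, pool_ctx(H %/% 2L, W %/% 2L))
  z <- as.vector(p2$Y)
  lat <- as.vector(z %*% p$We + p$be)
  if (!cache) return(lat)
  list(lat = lat, c1 = c1, A1 = A1, p1 = p1, c2 = c2, A2 = A2, p2 = p2,
       z = z)
}

input_ae_decode <- function(lat, p, shape, ch, C = 8L, cache = FALSE) {
  H <- shape[1]; W <- shape[2]
  zf <- as.vector(lat %*% p$Wd + p$bd)
  Ad <- relu(zf)
  Xd <- matrix(Ad, (H %/% 4L) * (W %/% 4L), ch[2])
  t1 <- tconv_forward(Xd, p$T1, p$t1, tconv_ctx(H %/% 4L, W %/% 4L))
  A3 <- relu(t1)
  Xh <- tconv_forward(A3, p$T2, p$t2, tconv_ctx(H %/% 2L, W %/% 2L))
  if (!cache) return(Xh)
  list(Xh = Xh, zf = zf, Xd = Xd, t1 = t1, A3 = A3)
}

# one Adam step worth of gradient for a single sample (reconstruction MSE)
input_ae_grad <- function(X, p, shape, ch, C = 8L) {
  H <- shape[1]; W <- shape[2]
  en <- input_ae_encode(X, p, shape, ch, cache = TRUE)
  de <- input_ae_decode(en$lat, p, shape, ch, C, cache = TRUE)
  err <- de$Xh - X
  loss <- mean(err^2)
  g <- list()
  dXh <- 2 * err / length(err)
  t2b <- tconv_backward(dXh, de$A3, p$T2, tconv_ctx(H %/% 2L, W %/% 2L))
  g$T2 <- t2b$dK; g$t2 <- t2b$db
  dA3 <- t2b$dX * drelu(de$t1)
  t1b <- tconv_backward(dA3, de$Xd, p$T1, tconv_ctx(H %/% 4L, W %/% 4L))
  g$T1 <- t1b$dK; g$t1 <- t1b$db
  dzf <- as.vector(t1b$dX) * drelu(de$zf)
  g$Wd <- outer(en$lat, dzf); g$bd <- dzf
  dlat <- as.vector(dzf %*% t(p$Wd))
  g$We <- outer(en$z, dlat); g$be <- dlat
  dz <- as.vector(dlat %*% t(p$We))
  dP2 <- matrix(dz, nrow(en$p2$Y), ncol(en$p2$Y))
  dA2 <- maxpool_backward(dP2, en$p2, pool_ctx(H %/% 2L, W %/% 2L),
                          H %/% 2L, W %/% 2L) * drelu(en$c2$Y)
  c2b <- conv3_backward(dA2, p$K2, en$c2, conv_ctx(H %/% 2L, W %/% 2L), ch[1])
  g$K2 <- c2b$dK; g$c2 <- c2b$db
  dA1 <- maxpool_backward(c2b$dX, en$p1, pool_ctx(H, W), H, W) *
    drelu(en$c1$Y)
  c1b <- conv3_backward(dA1, p$K1, en$c1, conv_ctx(H, W), C)
  g$K1 <- c1b$dK; g$c1 <- c1b$db
  list(grads = g, loss = loss)
}

# ---- latent mapper ----------------------------------------------------------

mapper_init <- function(q_in, q_out, hidden = 100L) {
  list(W1 = glorot(q_in, hidden), b1 = rep(0, hidden),
       W2 = glorot(hidden, hidden), b2 = rep(0, hidden),
       W3 = glorot(hidden, q_out), b3 = rep(0, q_out))
}

mapper_forward <- function(Z, p, dropout = 0, cache = FALSE) {
  A1 <- relu(dense_forward(Z, p$W1, p$b1))
  m1 <- if (dropout > 0) dropout_mask(length(A1), dropout) else NULL
  A1d <- if (is.null(m1)) A1 else A1 * m1
  A2 <- relu(dense_forward(A1d, p$W2, p$b2))
  m2 <- if (dropout > 0) dropout_mask(length(A2), dropout) else NULL
  A2d <- if (is.null(m2)) A2 else A2 * m2
  out <- dense_forward(A2d, p$W3, p$b3)
  if (!cache) return(out)
  list(out = out, A1 = A1, A1d = A1d, m1 = m1, A2 = A2, A2d = A2d, m2 = m2)
}

mapper_grad <- function(Z, Y, p, dropout = 0) {
  fw <- mapper_forward(Z, p, dropout, cache = TRUE)
  err <- fw$out - Y
  loss <- mean(err^2)
  dOut <- 2 * err / length(err)
  g <- list()
  b3 <- dense_backward(dOut, fw$A2d, p$W3); g$W3 <- b3$dW; g$b3 <- b3$db
  dA2 <- b3$dX; if (!is.null(fw$m2)) dA2 <- dA2 * fw$m2
  dA2 <- dA2 * drelu(fw$A2)
  b2 <- dense_backward(dA2, fw$A1d, p$W2); g$W2 <- b2$dW; g$b2 <- b2$db
  dA1 <- b2$dX; if (!is.null(fw$m1)) dA1 <- dA1 * fw$m1
  dA1 <- dA1 * drelu(fw$A1)
  b1 <- dense_backward(dA1, Z, p$W1); g$W1 <- b1$dW; g$b1 <- b1$db
  list(grads = g, loss = loss)
}

#' MLP surrogate forward pass
#'
#' Three-stage pipeline: convolutional input encoder to the input latent,
#' two-hidden-layer (100 + 100, ReLU) latent mapper, and the WSS
#' autoencoder's decoder back to the full field. Dropout is inactive at
#' inference.
#'
#' @param tensor an `input_tensor`.
#' @param bundle a fitted MLP surrogate bundle (from
#'   [train_surrogate()] with `model_kind = "mlp"`).
#' @return Predicted (n x m) matrix on the normalized scale.
#' @export
mlp_forward <- function(tensor, bundle) {
  if (is.null(bundle$input_ae) || is.null(bundle$output_ae) ||
      is.null(bundle$mapper))
    stop("state: MLP bundle components are not fitted")
  X <- standardize_features(tensor_to_node_matrix(tensor),
                            bundle$input_stats)
  lat <- input_ae_encode(X, bundle$input_ae, bundle$shape, bundle$ch)
  zo <- mapper_forward(matrix(lat, 1L), bundle$mapper)
  v <- ae_decode(bundle$output_ae, zo)
  unflatten_field(as.vector(v), bundle$shape[1], bundle$shape[2])
}
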