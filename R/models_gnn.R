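# ---- graph operators --------------------------------------------------------

#' Normalized graph operators for message passing
#'
#' `gcn_operator` returns the symmetric-normalized adjacency with self-loops,
#' `D^(-1/2) (A + I) D^(-1/2)`, where `A` carries the edge weights and the
#' degrees include a unit self-loop. `sage_operator` returns the
#' row-normalized (mean-aggregation) adjacency without self-loops; isolated
#' nodes aggregate a zero mean.
#'
#' @param graph a `vessel_graph`.
#' @return A sparse `Matrix`.
#' @export
gcn_operator <- function(graph) {
  A <- graph_adjacency(graph, self_loops = FALSE)
  N <- graph$n_nodes
  dhat <- Matrix::rowSums(A) + 1
  Dm <- Matrix::Diagonal(N, 1 / sqrt(dhat))
  Dm %*% (A + Matrix::Diagonal(N, 1)) %*% Dm
}

#' @rdname gcn_operator
#' @export
sage_operator <- function(graph) {
  A <- graph_adjacency(graph, self_loops = FALSE)
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  Matrix::Diagonal(graph$n_nodes, 1 / deg) %*% A
}

# ---- single layers (spec-level operations) ----------------------------------

#' One graph-convolution (GCN) layer
#'
#' Symmetric-normalized aggregation with self-loops followed by a linear map
#' and (optionally) ReLU: `H' = sigma(A_hat H W + b)`. The activation is
#' applied after the linear map (standard order).
#'
#' @param H node-feature matrix (n_nodes x F).
#' @param graph a `vessel_graph`.
#' @param params list with `W` (F x F') and optional `b`.
#' @param activate apply ReLU (default TRUE; FALSE gives the pre-activation
#'   output).
#' @param op optional precomputed [gcn_operator()].
#' @return Node-feature matrix (n_nodes x F').
#' @export
gcn_layer <- function(H, graph, params, activate = TRUE, op = NULL) {
  if (nrow(H) != graph$n_nodes) stop("shape: H rows must equal node count")
  if (nrow(params$W) != ncol(H)) stop("shape: W rows must equal feature dim")
  if (is.null(op)) op <- gcn_operator(graph)
  Z <- as.matrix(op %*% H) %*% params$W
  if (!is.null(params$b)) Z <- sweep(Z, 2L, params$b, "+")
  if (activate) relu(Z) else Z
}

#' One GraphSAGE layer (mean aggregation)
#'
#' `H' = sigma(H W1 + mean_{j in N(i)} H_j W2 + b)`; the self node is
#' excluded from the mean, and empty neighbourhoods contribute zero.
#'
#' @inheritParams gcn_layer
#' @param params list with `W1`, `W2` (F x F') and optional `b`.
#' @param op optional precomputed [sage_operator()].
#' @return Node-feature matrix (n_nodes x F').
#' @export
sage_layer <- function(H, graph, params, activate = TRUE, op = NULL) {
  if (nrow(H) != graph$n_nodes) stop("shape: H rows must equal node count")
  if (nrow(params$W1) != ncol(H) || nrow(params$W2) != ncol(H))
    stop("shape: weight rows must equal feature dim")
  if (is.null(op)) op <- sage_operator(graph)
  Z <- H %*% params$W1 + as.matrix(op %*% H) %*% params$W2
  if (!is.null(params$b)) Z <- sweep(Z, 2L, params$b, "+")
  if (activate) relu(Z) else Z
}

# ---- PI-GNN model -----------------------------------------------------------

#' Initialize a PI-GNN surrogate
#'
#' Architecture: a linear+ReLU input transformation projecting the
#' 8-dimensional node features to `hidden` dimensions, `n_layers`
#' alternating GCN (odd positions) and GraphSAGE (even positions) layers at
#' constant width, each followed by an identity residual addition, and a
#' linear output head to one value per node.
#'
#' @param n_features input feature count (default 8).
#' @param hidden hidden width (default 256; the desk preset trains narrower).
#' @param n_layers number of alternating message-passing layers (default 4:
#'   gcn, sage, gcn, sage).
#' @param seed RNG seed for the Glorot initialization.
#' @return An object of class `pignn_model`.
#' @export
pignn_init <- function(n_features = 8L, hidden = 256L, n_layers = 4L,
                       seed = 1L) {
  with_seed(seed, {
    kinds <- rep(c("gcn", "sage"), length.out = n_layers)
    params <- list(Win = glorot(n_features, hidden), bin = rep(0, hidden))
    for (l in seq_len(n_layers)) {
      if (kinds[l] == "gcn") {
        params[[paste0("W", l)]] <- glorot(hidden, hidden)
      } else {
        params[[paste0("W1_", l)]] <- glorot(hidden, hidden)
        params[[paste0("W2_", l)]] <- glorot(hidden, hidden)
      }
      params[[paste0("b", l)]] <- rep(0, hidden)
    }
    params$Wout <- glorot(hidden, 1L)
    params$bout <- 0
    structure(list(params = params, kinds = kinds, hidden = hidden,
                   n_features = n_features, n_layers = n_layers,
                   input_stats = NULL),
              class = "pignn_model")
  })
}

# flatten an input tensor to the graph's node ordering (sector index fastest)
tensor_to_node_matrix <- function(tensor) {
  d <- dim(tensor)
  matrix(aperm(unclass(tensor), c(2L, 1L, 3L)), d[1] * d[2], d[3])
}

standardize_features <- function(X, stats) {
  if (is.null(stats)) return(X)
  sweep(sweep(X, 2L, stats$mean), 2L, stats$sd, "/")
}

#' PI-GNN forward pass
#'
#' @param tensor an `input_tensor` (n x m x 8).
#' @param graph the matching `vessel_graph`.
#' @param model a `pignn_model`.
#' @param ops optional list with precomputed `gcn`/`sage` operators; may
#'   also carry `X`, the pre-standardized node-feature matrix.
#' @param return_cache keep intermediate activations for backprop.
#' @return Predicted field as an (n x m) matrix (normalized scale), or a
#'   list `(pred, cache)` when `return_cache`.
#' @export
pignn_forward <- function(tensor, graph, model, ops = NULL,
                          return_cache = FALSE) {
  d <- dim(tensor)
  if (d[1] * d[2] != graph$n_nodes) stop("state: graph/tensor mismatch")
  if (is.null(ops)) ops <- list(gcn = gcn_operator(graph),
                                sage = sage_operator(graph))
  X <- if (!is.null(ops$X)) ops$X else
    standardize_features(tensor_to_node_matrix(tensor), model$input_stats)
  p <- model$params
  Zin <- sweep(X %*% p$Win, 2L, p$bin, "+")
  H <- relu(Zin)
  cache <- list(X = X, Zin = Zin, H = list(H))
  Zs <- vector("list", model$n_layers)
  AH <- vector("list", model$n_layers)
  for (l in seq_len(model$n_layers)) {
    if (model$kinds[l] == "gcn") {
      AHl <- as.matrix(ops$gcn %*% H)
      Z <- sweep(AHl %*% p[[paste0("W", l)]], 2L, p[[paste0("b", l)]], "+")
    } else {
      AHl <- as.matrix(ops$sage %*% H)
      Z <- sweep(H %*% p[[paste0("W1_", l)]] + AHl %*% p[[paste0("W2_", l)]],
                 2L, p[[paste0("b", l)]], "+")
    }
    H <- H + relu(Z)                       # residual addition
    Zs[[l]] <- Z; AH[[l]] <- AHl
    cache$H[[l + 1L]] <- H
  }
  out <- as.vector(H %*% p$Wout + p$bout)
  pred <- matrix(out, d[1], d[2], byrow = TRUE)
  if (!return_cache) return(pred)
  cache$Zs <- Zs; cache$AH <- AH; cache$ops <- ops; cache$dims <- d
  list(pred = pred, cache = cache)
}

# gradient of all parameters given dL/dpred (n x m matrix)
pignn_backward <- function(dpred, model, cache) {
  p <- model$params
  dOut <- matrix(as.vector(t(dpred)), ncol = 1L)     # node ordering
  HL <- cache$H[[model$n_layers + 1L]]
  grads <- list(Wout = crossprod(HL, dOut), bout = sum(dOut))
  dH <- dOut %*% t(p$Wout)
  for (l in rev(seq_len(model$n_layers))) {
    Z <- cache$Zs[[l]]
    dZ <- dH * drelu(Z)
    Hprev <- cache$H[[l]]
    if (model$kinds[l] == "gcn") {
      W <- p[[paste0("W", l)]]
      grads[[paste0("W", l)]] <- crossprod(cache$AH[[l]], dZ)
      grads[[paste0("b", l)]] <- colSums(dZ)
      dH <- dH + as.matrix(Matrix::t(cache$ops$gcn) %*% (dZ %*% t(W)))
    } else {
      W1 <- p[[paste0("W1_", l)]]; W2 <- p[[paste0("W2_", l)]]
      grads[[paste0("W1_", l)]] <- crossprod(Hprev, dZ)
      grads[[paste0("W2_", l)]] <- crossprod(cache$AH[[l]], dZ)
      grads[[paste0("b", l)]] <- colSums(dZ)
      dH <- dH + dZ %*% t(W1) +
        as.matrix(Matrix::t(cache$ops$sage) %*% (dZ %*% t(W2)))
    }
  }
  dZin <- dH * drelu(cache$Zin)
  grads$Win <- crossprod(cache$X, dZin)
  grads$bin <- colSums(dZin)
  grads
}

# ---- physics-informed loss --------------------------------------------------

#' Physics-loss configuration
#'
#' Weights of the composite loss `L = L_MSE + alpha L_gradient +
#' beta L_continuity + gamma(epoch) L_boundary`, with `gamma` increasing
#' linearly from `gamma_start` to `gamma_end` over `gamma_epochs` epochs.
#' The inlet target stress is the Poiseuille value at the inlet radius and
#' `mean_velocity`, multiplied by the curvature factor
#' `1 + curvature_factor * kappa * R` (factor defaults to 0).
#'
#' @param alpha gradient-term weight (default 0.1).
#' @param beta continuity-term weight (default 0.05).
#' @param gamma_start,gamma_end,gamma_epochs boundary-term schedule
#'   (defaults 0.01, 0.1, 500).
#' @param mean_velocity inlet mean velocity, m/s.
#' @param viscosity viscosity for the inlet Poiseuille stress, Pa s.
#' @param curvature_factor inlet curvature adjustment gain (default 0).
#' @param blood_density kg/m^3 (used to report the Reynolds number).
#' @return A list of class `physics_loss_config`.
#' @export
physics_loss_config <- function(alpha = 0.1, beta = 0.05,
                                gamma_start = 0.01, gamma_end = 0.1,
                                gamma_epochs = 500L,
                                mean_velocity = 0.2, viscosity = 0.0035,
                                curvature_factor = 0,
                                blood_density = 1060) {
  stopifnot(alpha >= 0, beta >= 0, gamma_start >= 0,
            gamma_end >= gamma_start)
  structure(list(alpha = alpha, beta = beta, gamma_start = gamma_start,
                 gamma_end = gamma_end, gamma_epochs = gamma_epochs,
                 mean_velocity = mean_velocity, viscosity = viscosity,
                 curvature_factor = curvature_factor,
                 blood_density = blood_density),
            class = "physics_loss_config")
}

#' Boundary-weight schedule
#' @param epoch epoch index (>= 0).
#' @param config a [physics_loss_config()].
#' @return `gamma(epoch)`, linear between the endpoints and clamped after
#'   `gamma_epochs`.
#' @export
gamma_schedule <- function(epoch, config = physics_loss_config()) {
  if (any(epoch < 0)) stop("parameter: epoch must be non-negative")
  f <- pmin(epoch, config$gamma_epochs) / config$gamma_epochs
  config$gamma_start + (config$gamma_end - config$gamma_start) * f
}

# sparse central-difference operator on the axial coordinate (one-sided ends)
fd_operator <- function(n, h) {
  i <- c(seq(2L, n - 1L), seq(2L, n - 1L), 1L, 1L, n, n)
  j <- c(seq(1L, n - 2L), seq(3L, n), 1L, 2L, n - 1L, n)
  x <- c(rep(-1 / (2 * h), n - 2L), rep(1 / (2 * h), n - 2L),
         -1 / h, 1 / h, -1 / h, 1 / h)
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}

# per-graph quantities reused by every physics-loss evaluation
physics_prep <- function(graph, config = physics_loss_config()) {
  n <- graph$dims[1]; m <- graph$dims[2]
  geo <- graph$geometry
  R_st <- geo$R[seq(1L, graph$n_nodes, by = m)]       # per-station radius
  s_st <- geo$s[seq(1L, graph$n_nodes, by = m)]
  h <- s_st[2] - s_st[1]
  D <- fd_operator(n, h)
  g1 <- as.vector(D %*% log(R_st))                    # d(ln R)/ds
  kcos <- matrix(geo$kappa * cos(geo$theta), n, m, byrow = TRUE)
  Gmat <- matrix(g1, n, m) + kcos
  E <- nrow(graph$edges)
  d_e <- pmax(graph$edge_dist, 1e-9)
  Ginc <- Matrix::sparseMatrix(
    i = c(seq_len(E), seq_len(E)),
    j = c(graph$edges[, 1], graph$edges[, 2]),
    x = c(-1 / d_e, 1 / d_e), dims = c(E, graph$n_nodes))
  R_in <- geo$R[1L]; k_in <- geo$kappa[1L]
  tau_inlet <- poiseuille_wss(config$mean_velocity, R_in, config$viscosity) *
    (1 + config$curvature_factor * k_in * R_in)
  Re <- config$blood_density * config$mean_velocity *
    (2 * R_in * 1e-3) / config$viscosity
  list(D = D, Dt = Matrix::t(D), Gmat = Gmat, Ginc = Ginc,
       Ginct = Matrix::t(Ginc), tau_inlet = tau_inlet, reynolds = Re,
       n = n, m = m, E = E)
}

#' Composite physics-informed loss
#'
#' `L = L_MSE + alpha L_gradient + beta L_continuity + gamma(epoch)
#' L_boundary` on Pa-scale fields:
#' mean squared node error; mean over all graph edges of the squared
#' difference between predicted and reference edge-wise finite-difference
#' gradients; mean squared residual of the quasi-1D continuity relation
#' `dy/ds + y (d(ln R)/ds + kappa cos(theta))` (axial central differences
#' along each circumferential strip); and the mean squared deviation of the
#' inlet-ring prediction from the curvature-adjusted Poiseuille inlet
#' stress.
#'
#' @param pred,target predicted and reference fields: `wss_field` objects or
#'   (n x m) matrices on the graph's grid.
#' @param graph the `vessel_graph`.
#' @param config a [physics_loss_config()].
#' @param epoch training epoch (>= 0), sets `gamma`.
#' @param prep optional cached output of the internal preparation step.
#' @param return_grad also return `grad`, the (n x m) derivative of the
#'   total loss with respect to the prediction.
#' @return A list with `total`, `mse`, `gradient`, `continuity`, `boundary`,
#'   `gamma` (and `grad` if requested).
#' @export
physics_loss <- function(pred, target, graph, config = physics_loss_config(),
                         epoch = 0, prep = NULL, return_grad = FALSE) {
  P <- if (inherits(pred, "wss_field")) pred$values else as.matrix(pred)
  Y <- if (inherits(target, "wss_field")) target$values else as.matrix(target)
  if (!all(dim(P) == dim(Y))) stop("shape: pred/target disagree")
  if (nrow(P) * ncol(P) != graph$n_nodes) stop("shape: field/graph disagree")
  if (is.null(prep)) prep <- physics_prep(graph, config)
  N <- graph$n_nodes
  gam <- gamma_schedule(epoch, config)

  err <- P - Y
  mse <- mean(err^2)

  pv <- as.vector(t(P)); yv <- as.vector(t(Y))     # node ordering
  r_edge <- as.vector(prep$Ginc %*% (pv - yv))
  l_grad <- mean(r_edge^2)

  resid <- as.matrix(prep$D %*% P) + P * prep$Gmat
  l_cont <- mean(resid^2)

  b_res <- P[1L, ] - prep$tau_inlet
  l_bound <- mean(b_res^2)

  out <- list(total = mse + config$alpha * l_grad + config$beta * l_cont +
                gam * l_bound,
              mse = mse, gradient = l_grad, continuity = l_cont,
              boundary = l_bound, gamma = gam)
  if (return_grad) {
    g <- 2 * err / N
    gv <- config$alpha * 2 / prep$E * as.vector(prep$Ginct %*% r_edge)
    g <- g + matrix(gv, nrow(P), ncol(P), byrow = TRUE)
    g <- g + config$beta * 2 / N *
      (as.matrix(prep$Dt %*% resid) + resid * prep$Gmat)
    g[1L, ] <- g[1L, ] + gam * 2 / ncol(P) * b_res
    out$grad <- g
  }
  out
}
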