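# Shared fixtures, built in code and memoized for the session.

.fix_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fix_env[[name]])) .fix_env[[name]] <- build()
  .fix_env[[name]]
}

straight_points <- function(n = 50, L = 80) cbind(0, 0, seq(0, L, length.out = n))

fix_straight_cl <- function() fixture("straight_cl", function()
  resample_centerline(straight_points(), n = 640L, target_length = 80))

fix_bend_cl <- function() fixture("bend_cl", function()
  resample_centerline(make_template_centerline("single_bend")$xyz,
                      n = 640L, target_length = 80))

# straight vessel, concentric round AR = 0.16 lesion at 40 mm, full-resolution grid
fix_throat_lattice <- function() fixture("throat_lattice", function() {
  cl <- fix_straight_cl()
  sp <- make_stenosis_spec("concentric_round", area_ratio = 0.16,
                           position = 40, seed = 1)
  build_surface(cl, apply_stenosis(cl, sp), 40L)
})

# small straight lattice for cheap graph/oracle checks (40 x 8)
fix_small_lattice <- function() fixture("small_lattice", function() {
  cl <- resample_centerline(straight_points(60), n = 40L, target_length = 80)
  build_surface(cl, apply_stenosis(cl, NULL), 8L)
})

fix_small_graph <- function() fixture("small_graph", function() {
  lat <- fix_small_lattice()
  tx <- build_feature_tensor(lat, margin = 5)
  list(lattice = lat, tensor = tx, graph = build_graph(lat, tx))
})

# a hand-rolled toy graph in the vessel_graph layout
toy_graph <- function(n, edges, weights = rep(1, nrow(edges)),
                      xyz = NULL, seed = 1) {
  if (is.null(xyz)) xyz <- with_seed(seed, matrix(rnorm(n * 3), n, 3))
  structure(list(
    n_nodes = n, edges = edges, weights = weights,
    is_grid = rep(TRUE, nrow(edges)), node_xyz = xyz, dims = c(n, 1L),
    geometry = data.frame(R = rep(1.5, n), kappa = 0, s = seq_len(n),
                          theta = 0),
    edge_dist = sqrt(rowSums((xyz[edges[, 1], , drop = FALSE] -
                                xyz[edges[, 2], , drop = FALSE])^2))),
    class = "vessel_graph")
}

# dense GCN reference: D^-1/2 (A + I) D^-1/2 H W, unit weights
dense_gcn <- function(H, edges, n, W) {
  A <- matrix(0, n, n)
  for (r in seq_len(nrow(edges))) {
    A[edges[r, 1], edges[r, 2]] <- 1
    A[edges[r, 2], edges[r, 1]] <- 1
  }
  dh <- rowSums(A) + 1
  Ah <- diag(1 / sqrt(dh)) %*% (A + diag(n)) %*% diag(1 / sqrt(dh))
  (Ah %*% H) %*% W
}

# looped GraphSAGE reference
loop_sage <- function(H, edges, n, W1, W2) {
  A <- matrix(0, n, n)
  for (r in seq_len(nrow(edges))) {
    A[edges[r, 1], edges[r, 2]] <- 1
    A[edges[r, 2], edges[r, 1]] <- 1
  }
  t(vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    mn <- if (length(nb)) colMeans(H[nb, , drop = FALSE]) else
      rep(0, ncol(H))
    as.vector(H[i, ] %*% W1 + mn %*% W2)
  }, numeric(ncol(W1))))
}

# tiny desk cohort for training smoke tests
fix_tiny_cohort <- function() fixture("tiny_cohort", function()
  generate_wss_cohort(12, "desk", seed = 401))
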