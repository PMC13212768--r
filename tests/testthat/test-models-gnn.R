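test_that("GCN layers equal the dense normalized-adjacency oracle", {
  # single node with only its self-loop: identity at W = I, pre-activation
  g1 <- toy_graph(1L, matrix(integer(0), 0, 2))
  H1 <- matrix(c(2, -3), 1)
  expect_equal(gcn_layer(H1, g1, list(W = diag(2)), activate = FALSE), H1)

  # constant rows on a ring (every d-hat = 3) are preserved pre-activation
  ring <- cbind(1:6, c(2:6, 1))
  gr <- toy_graph(6L, cbind(pmin(ring[, 1], ring[, 2]),
                            pmax(ring[, 1], ring[, 2])))
  Hc <- matrix(2, 6, 3)
  expect_equal(gcn_layer(Hc, gr, list(W = diag(3)), activate = FALSE), Hc,
               tolerance = 1e-12)

  # random graphs against the explicit dense product
  for (seed in 1:5) {
    n <- 6L
    e <- with_seed(seed, {
      pairs <- t(combn(n, 2))
      pairs[sample(nrow(pairs), 7), , drop = FALSE]
    })
    g <- toy_graph(n, e, seed = seed)
    H <- with_seed(seed + 50, matrix(rnorm(n * 4), n, 4))
    W <- with_seed(seed + 60, matrix(rnorm(16), 4, 4))
    expect_equal(gcn_layer(H, g, list(W = W), activate = FALSE),
                 dense_gcn(H, e, n, W), tolerance = 1e-6)
    expect_equal(gcn_layer(H, g, list(W = W)),
                 pmax(dense_gcn(H, e, n, W), 0), tolerance = 1e-6)
  }
})

test_that("GraphSAGE layers equal the per-node loop oracle", {
  for (seed in 1:5) {
    n <- 6L
    e <- with_seed(seed, {
      pairs <- t(combn(n, 2))
      pairs[sample(nrow(pairs), 6), , drop = FALSE]
    })
    g <- toy_graph(n, e, seed = seed)
    H <- with_seed(seed + 10, matrix(rnorm(n * 3), n, 3))
    W1 <- with_seed(seed + 20, matrix(rnorm(9), 3, 3))
    W2 <- with_seed(seed + 30, matrix(rnorm(9), 3, 3))
    expect_equal(sage_layer(H, g, list(W1 = W1, W2 = W2), activate = FALSE),
                 loop_sage(H, e, n, W1, W2), tolerance = 1e-6)
  }
  # W2 = 0 reduces to the per-node linear map
  g <- toy_graph(4L, cbind(1:3, 2:4))
  H <- matrix(rnorm(8), 4)
  W1 <- matrix(rnorm(4), 2)
  expect_equal(sage_layer(H, g, list(W1 = W1, W2 = matrix(0, 2, 2))),
               pmax(H %*% W1, 0))
  # constant features stay constant (mean of constants)
  Hc <- matrix(1, 4, 2)
  out <- sage_layer(Hc, g, list(W1 = diag(2), W2 = diag(2)),
                    activate = FALSE)
  expect_equal(out, 2 * Hc)
})

test_that("the PI-GNN forward pass meets its shape and determinism contracts", {
  fx <- fix_small_graph()
  mod <- pignn_init(8L, hidden = 12L, n_layers = 4L, seed = 5)
  p1 <- pignn_forward(fx$tensor, fx$graph, mod)
  expect_equal(dim(p1), fx$graph$dims)
  expect_identical(p1, pignn_forward(fx$tensor, fx$graph, mod))
  # zeroed output head -> constant zero prediction
  mod0 <- mod; mod0$params$Wout[] <- 0; mod0$params$bout <- 0
  expect_true(all(pignn_forward(fx$tensor, fx$graph, mod0) == 0))
  expect_error(pignn_forward(fx$tensor, toy_graph(3L, cbind(1L, 2L)), mod),
               "state")
})

test_that("the physics loss vanishes for a perfect Poiseuille prediction", {
  fx <- fix_small_graph()
  tau <- poiseuille_wss(0.2, 1.5, 0.0035)
  U <- matrix(tau, fx$graph$dims[1], fx$graph$dims[2])
  pl <- physics_loss(U, U, fx$graph)
  expect_equal(pl$mse, 0)
  expect_equal(pl$gradient, 0)
  expect_equal(pl$continuity, 0, tolerance = 1e-12)
  expect_equal(pl$boundary, 0, tolerance = 1e-12)
  expect_equal(pl$total, 0, tolerance = 1e-12)
})

test_that("y = c / R on a straight taper annihilates the continuity term", {
  # straight vessel with a smoothly tapering radius via a wide mild lesion
  cl <- resample_centerline(straight_points(60), n = 160L,
                            target_length = 80)
  sp <- make_stenosis_spec("concentric_round", area_ratio = 0.5,
                           position = 40, axial_extent = 40, seed = 1)
  lat <- build_surface(cl, apply_stenosis(cl, sp), 8L)
  tx <- build_feature_tensor(lat)
  g <- build_graph(lat, tx)
  R <- matrix(g$geometry$R, g$dims[1], g$dims[2], byrow = TRUE)
  pred <- 3 / R
  pl <- physics_loss(pred, pred, g)
  # residual is pure discretization error of the central differences
  expect_equal(pl$continuity, 0, tolerance = 1e-6)
})

test_that("the composite loss decomposes exactly and gamma follows schedule", {
  fx <- fix_small_graph()
  Y <- oracle_wss_field(fx$lattice, flow_params(), seed = 3,
                        noise_sd = 0.2)$values
  P <- Y + with_seed(9, matrix(rnorm(length(Y), 0, 0.4), nrow(Y)))
  cfg <- physics_loss_config()
  for (epoch in c(0, 250, 500)) {
    pl <- physics_loss(P, Y, fx$graph, cfg, epoch = epoch)
    expect_equal(pl$total,
                 pl$mse + cfg$alpha * pl$gradient + cfg$beta * pl$continuity +
                   pl$gamma * pl$boundary, tolerance = 1e-10)
  }
  expect_equal(gamma_schedule(0), 0.01)
  expect_equal(gamma_schedule(250), 0.055)
  expect_equal(gamma_schedule(500), 0.1)
  expect_equal(gamma_schedule(800), 0.1)       # clamped past the ramp
  expect_error(gamma_schedule(-1), "parameter")
})

test_that("analytic physics-loss gradients match finite differences", {
  fx <- fix_small_graph()
  Y <- oracle_wss_field(fx$lattice, flow_params(), seed = 3,
                        noise_sd = 0.2)$values
  P <- Y + with_seed(4, matrix(rnorm(length(Y), 0, 0.3), nrow(Y)))
  pl <- physics_loss(P, Y, fx$graph, epoch = 100, return_grad = TRUE)
  eps <- 1e-5
  for (cell in list(c(1, 2), c(17, 5), c(35, 8))) {
    Pp <- P; Pp[cell[1], cell[2]] <- Pp[cell[1], cell[2]] + eps
    Pm <- P; Pm[cell[1], cell[2]] <- Pm[cell[1], cell[2]] - eps
    fd <- (physics_loss(Pp, Y, fx$graph, epoch = 100)$total -
             physics_loss(Pm, Y, fx$graph, epoch = 100)$total) / (2 * eps)
    expect_equal(pl$grad[cell[1], cell[2]], fd, tolerance = 1e-6)
  }
})

test_that("PI-GNN parameter gradients are exact through the full chain", {
  fx <- fix_small_graph()
  fld <- oracle_wss_field(fx$lattice, flow_params(), seed = 3,
                          noise_sd = 0.2)
  st <- wss_normalizer(list(fld))
  mod <- pignn_init(8L, hidden = 8L, n_layers = 4L, seed = 2)
  mod$input_stats <- list(mean = rep(0, 8), sd = rep(1, 8))
  loss_of <- function(m) {
    z <- pignn_forward(fx$tensor, fx$graph, m)
    physics_loss(denormalize_wss(z, st), fld$values, fx$graph,
                 epoch = 10)$total
  }
  fw <- pignn_forward(fx$tensor, fx$graph, mod, return_cache = TRUE)
  y <- denormalize_wss(fw$pred, st)
  pl <- physics_loss(y, fld$values, fx$graph, epoch = 10, return_grad = TRUE)
  dz <- pl$grad * st$sd * (y + st$eps_log)
  grads <- stenowss:::pignn_backward(dz, mod, fw$cache)
  for (nm in c("Win", "W1", "W1_2", "W2_2", "Wout")) {
    m2 <- mod; m2$params[[nm]][1, 1] <- m2$params[[nm]][1, 1] + 1e-6
    m3 <- mod; m3$params[[nm]][1, 1] <- m3$params[[nm]][1, 1] - 1e-6
    fd <- (loss_of(m2) - loss_of(m3)) / 2e-6
    expect_equal(unname(grads[[nm]][1, 1]), fd, tolerance = 1e-4)
  }
})
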