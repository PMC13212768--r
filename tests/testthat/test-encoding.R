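test_that("the feature tensor has the standard cardinalities and channels", {
  tx <- build_feature_tensor(fix_throat_lattice())
  expect_equal(dim(tx), c(560L, 40L, 8L))
  expect_equal(length(tx), 179200L)
  # angle channel forced by A = 2 pi (k-1) / 40
  expect_equal(tx[1, 1, 5], 0)
  expect_equal(tx[1, 21, 5], pi)
  expect_equal(tx[5, , 5], 2 * pi * (0:39) / 40)
  # station-level channels constant per ring
  expect_true(all(apply(tx[, , 6], 1, function(r) length(unique(r))) == 1))
  # crop covers [5, 75] mm at the endpoint-inclusive spacing
  s <- attr(tx, "station_s")
  expect_equal(length(s), 560L)
  expect_equal(diff(range(s)), 80 * 559 / 639, tolerance = 1e-12)
  expect_equal(s[1], 80 / 639 * 40, tolerance = 1e-12)
  expect_error(build_feature_tensor(fix_small_lattice(),
                                    dims = c(640L, 40L)), "shape")
})

test_that("a straight unstenosed tube has null curvature and offset channels", {
  tx <- build_feature_tensor(fix_small_lattice())
  expect_equal(max(abs(tx[, , 4])), 0, tolerance = 1e-9)
  expect_true(all(tx[, , 6] == 0))
  expect_true(all(tx[, , 7] == 1.5 & tx[, , 8] == 1.5))
})

test_that("nearest-neighbour WSS mapping is exact, sized, and tie-stable", {
  lat <- fix_small_lattice()
  f <- oracle_wss_field(lat, flow_params(), seed = 2, noise_sd = 0.2)
  keep <- f$station_index
  pts <- matrix(aperm(lat$node_xyz[keep, , , drop = FALSE], c(2, 1, 3)),
                length(keep) * 8L, 3L)
  mapped <- map_wss_to_grid(pts, as.vector(t(f$values)), lat)
  expect_identical(mapped$values, f$values)       # samples on grid nodes
  expect_equal(length(mapped$values), length(keep) * 8L)

  # ties broken by the lowest sample index, against a brute-force scan
  two <- rbind(pts[1, ] + c(0, 0, 0.5), pts[1, ] - c(0, 0, 0.5))
  m2 <- map_wss_to_grid(two, c(7, 9), lat)
  brute <- apply(pts, 1L, function(g) {
    d <- sqrt(colSums((t(two) - g)^2))
    which(d == min(d))[1]
  })
  expect_equal(as.vector(t(m2$values)), c(7, 9)[brute])
  expect_error(map_wss_to_grid(matrix(0, 0, 3), numeric(0), lat), "input")
})

test_that("the log-z transform is exact, standardizing, and guarded", {
  f <- oracle_wss_field(fix_small_lattice(), flow_params(), seed = 1,
                        noise_sd = 0.3)
  st <- wss_normalizer(list(f))
  z <- normalize_wss(f, st)
  expect_equal(mean(z), 0, tolerance = 1e-6)
  expect_equal(mean((z - mean(z))^2), 1, tolerance = 1e-6)
  expect_equal(denormalize_wss(z, st), f$values, tolerance = 1e-9)
  # zero WSS maps to a finite value
  z0 <- normalize_wss(matrix(0, 2, 2), st)
  expect_true(all(is.finite(z0)))
  expect_error(wss_normalizer(list(new_wss_field(matrix(1, 4, 4), 1:4,
                                                 1:4, 4L))),
               "degenerate-statistics")
})

test_that("grid edges realize the wrapped 8-neighbourhood", {
  g <- fix_small_graph()$graph
  deg <- grid_degree(g)
  n <- g$dims[1]; m <- g$dims[2]
  interior <- rep(seq_len(n) > 1 & seq_len(n) < n, each = m)
  expect_true(all(deg[interior] == 8L))
  expect_true(all(deg[!interior] == 5L))
  # circumferential wrap: (i, m) adjacent to (i, 1)
  i <- 3L
  a <- (i - 1L) * m + m; b <- (i - 1L) * m + 1L
  key <- paste(pmin(g$edges[, 1], g$edges[, 2]),
               pmax(g$edges[, 1], g$edges[, 2]))
  expect_true(paste(min(a, b), max(a, b)) %in% key)
  # no axial wrap: node (1, k) never adjacent to (n, k)
  expect_false(paste(1L, (n - 1L) * m + 1L) %in% key)
})

test_that("edge weights follow exp(-d / 0.1) and decay monotonically", {
  g <- fix_small_graph()$graph
  expect_equal(g$weights, exp(-g$edge_dist / 0.1), tolerance = 1e-15)
  expect_equal(exp(-0.1 / 0.1), 1 / exp(1), tolerance = 1e-12)
  o <- order(g$edge_dist)
  expect_true(all(diff(g$weights[o]) <= 1e-15))
  # adjacency is symmetric with equal weights both ways
  A <- graph_adjacency(g)
  expect_equal(as.numeric(max(abs(A - Matrix::t(A)))), 0)
  expect_error(build_graph(fix_small_lattice(), fix_small_graph()$tensor,
                           spatial_radius = -1), "parameter")
})

test_that("windowed spatial search equals the brute-force scan", {
  cl <- resample_centerline(make_template_centerline("s_bend")$xyz,
                            40L, 80)
  sp <- make_stenosis_spec("concentric_round", 0.15, 40, seed = 2)
  lat <- build_surface(cl, apply_stenosis(cl, sp), 20L)
  tx <- build_feature_tensor(lat)
  keep <- attr(tx, "station_index")
  nx <- matrix(aperm(lat$node_xyz[keep, , , drop = FALSE], c(2, 1, 3)),
               length(keep) * 20L, 3L)
  for (radius in c(0.4, 0.9, 1.6)) {
    a <- stenowss:::spatial_candidate_pairs(nx, keep, lat, radius, "window")
    b <- stenowss:::spatial_candidate_pairs(nx, keep, lat, radius,
                                            "bruteforce")
    ka <- sort(a$pairs[, 1] * 1e6 + a$pairs[, 2])
    kb <- sort(b$pairs[, 1] * 1e6 + b$pairs[, 2])
    expect_identical(ka, kb)
  }
})

test_that("spatial edges respect the degree cap and avoid grid duplicates", {
  lat <- fix_small_lattice()
  tx <- build_feature_tensor(lat)
  g <- build_graph(lat, tx, spatial_radius = 2.0, max_spatial_degree = 3L)
  sp_deg <- tabulate(c(g$edges[!g$is_grid, ]), nbins = g$n_nodes)
  expect_lte(max(sp_deg), 3L)
  key <- paste(g$edges[, 1], g$edges[, 2])
  expect_false(any(duplicated(key)))
})
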