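test_that("the inlet waveform meets its mean, peak and periodicity contracts", {
  p <- flow_params()
  tt <- seq(0, p$cycle_period, length.out = 20001L)[-20001L]
  v <- inlet_waveform(tt, p)
  expect_equal(mean(v), 0.20, tolerance = 1e-4)     # cycle average
  expect_equal(max(v), 0.55, tolerance = 1e-3)      # peak
  expect_true(all(v >= 0))
  expect_equal(inlet_waveform(0.17, p),
               inlet_waveform(0.17 + p$cycle_period, p), tolerance = 1e-12)
  expect_error(flow_params(peak_inlet_velocity = 0.1), "parameter")
})

test_that("Carreau viscosity matches its closed form and limits", {
  p <- flow_params()
  expect_equal(carreau_viscosity(0, p), p$mu0)
  expect_equal(carreau_viscosity(1e6, p), p$mu_inf, tolerance = 0.01)
  # independent evaluation of the formula at gamma = 100 / s
  g <- 100
  ref <- 0.00345 + (0.056 - 0.00345) * (1 + (3.313 * g)^2)^((0.3568 - 1) / 2)
  expect_equal(carreau_viscosity(g, p), ref, tolerance = 1e-12)
  expect_error(flow_params(mu0 = 0.001, mu_inf = 0.01), "mu_inf")
})

test_that("Poiseuille WSS follows tau = 4 mu U / R with mm radii", {
  expect_equal(poiseuille_wss(0.2, 1.5, 0.0035), 4 * 0.0035 * 0.2 / 0.0015)
  expect_equal(poiseuille_wss(0, 1.5, 0.0035), 0)
  expect_equal(poiseuille_wss(0.3, 3, 0.004),
               poiseuille_wss(0.3, 1.5, 0.004) / 2)  # tau ~ 1/R
  expect_error(poiseuille_wss(0.2, -1), "domain")
})

test_that("a straight unstenosed tube yields the uniform Poiseuille field", {
  f <- oracle_wss_field(fix_small_lattice(), flow_params(),
                        rheology = "newtonian")
  expect_equal(as.vector(f$values),
               rep(poiseuille_wss(0.2, 1.5, 0.0035), length(f$values)),
               tolerance = 1e-6)
})

test_that("station-mean WSS follows the cubic radius law through a throat", {
  f <- oracle_wss_field(fix_throat_lattice(), flow_params(),
                        rheology = "newtonian", wake_depth = 0)
  sm <- rowMeans(f$values)
  expect_equal(max(sm) / sm[10], (1.5 / 0.6)^3, tolerance = 0.02)
  # conservation on the unstenosed straight proximal segment
  expect_equal(stats::sd(sm[1:50]) / mean(sm[1:50]), 0, tolerance = 1e-6)
})

test_that("concentric round throats are circumferentially uniform", {
  f <- oracle_wss_field(fix_throat_lattice(), flow_params())
  ring <- f$values[which.max(rowMeans(f$values)), ]
  expect_lt(max(ring) / min(ring), 1.01)
})

test_that("eccentric throats peak on the offset side", {
  cl <- fix_straight_cl()
  for (orient in c(0.7, 2.5, 4.4)) {
    sp <- make_stenosis_spec("eccentric_round", area_ratio = 0.16,
                             position = 40, eccentric_distance = 0.6,
                             orientation = orient)
    lat <- build_surface(cl, apply_stenosis(cl, sp), 40L)
    f <- oracle_wss_field(lat, flow_params())
    ring <- f$values[which.max(rowMeans(f$values)), ]
    k_hat <- which.max(ring)
    k_exp <- (round(orient / (2 * pi) * 40) %% 40) + 1L
    dk <- min(abs(k_hat - k_exp), 40 - abs(k_hat - k_exp))
    expect_lte(dk, 2L)
  }
})

test_that("peak WSS increases strictly with stenosis severity", {
  cl <- fix_straight_cl()
  peaks <- vapply(c(0.5, 0.3, 0.1), function(ar) {
    sp <- make_stenosis_spec("concentric_round", area_ratio = ar,
                             position = 40, seed = 1)
    max(oracle_wss_field(build_surface(cl, apply_stenosis(cl, sp), 40L),
                         flow_params())$values)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))   # mild < moderate < severe
})

test_that("post-stenotic wakes depress WSS downstream, not upstream", {
  lat <- fix_throat_lattice()
  f_wake <- oracle_wss_field(lat, flow_params(), rheology = "newtonian")
  f_none <- oracle_wss_field(lat, flow_params(), rheology = "newtonian",
                             wake_depth = 0)
  it <- which.max(rowMeans(f_none$values))
  down <- it + 30L; up <- it - 30L
  expect_lt(mean(f_wake$values[down, ]), mean(f_none$values[down, ]))
  expect_equal(f_wake$values[up, ], f_none$values[up, ], tolerance = 1e-9)
})

test_that("seeded oracle noise is reproducible and non-negative", {
  lat <- fix_throat_lattice()
  f1 <- oracle_wss_field(lat, flow_params(), seed = 11, noise_sd = 0.1)
  f2 <- oracle_wss_field(lat, flow_params(), seed = 11, noise_sd = 0.1)
  f3 <- oracle_wss_field(lat, flow_params(), seed = 12, noise_sd = 0.1)
  expect_identical(f1$values, f2$values)
  expect_false(identical(f1$values, f3$values))
  expect_true(all(f1$values >= 0))
})

test_that("WSS CSV round-trips exactly", {
  f <- oracle_wss_field(fix_throat_lattice(), flow_params(), seed = 5,
                        noise_sd = 0.05)
  path <- tempfile(fileext = ".csv")
  write_wss_csv(f, path)
  back <- read_wss_csv(path)
  expect_identical(back$values, f$values)
  expect_identical(back$station_index, f$station_index)
})
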