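test_that("metrics match hand-evaluated formulas", {
  m <- compute_metrics(c(2, 4, 6), c(1, 2, 3))
  expect_equal(m$MAE, 2)
  expect_equal(m$MdnAE, 2)
  expect_equal(m$RMSE, sqrt(14 / 3))
  expect_equal(m$PearsonR, 1)
  expect_equal(m$R2, 1)

  # uniform +1 Pa offset on a varying reference
  ref <- c(1, 2, 3, 5)
  mo <- compute_metrics(ref + 1, ref)
  expect_equal(mo$MAE, 1); expect_equal(mo$RMSE, 1)
  expect_equal(mo$StdError, 0)
  expect_equal(mo$PearsonR, 1)

  expect_error(compute_metrics(c(1, 2, 3), c(1, 1, 1)),
               "correlation-undefined")
  expect_error(compute_metrics(1:4, 1:5), "shape")
})

test_that("MAE never exceeds RMSE, with equality only for equal errors", {
  for (seed in 1:10) {
    x <- with_seed(seed, runif(50, 0, 10))
    y <- x + with_seed(seed + 99, rnorm(50))
    m <- compute_metrics(y, x)
    expect_lte(m$MAE, m$RMSE + 1e-12)
  }
  meq <- compute_metrics(c(1, 2, 3) + 2, c(1, 2, 3))
  expect_equal(meq$MAE, meq$RMSE)
})

test_that("metrics are layout-invariant and R is affine-invariant", {
  Y <- matrix(with_seed(3, runif(40, 0, 20)), 8, 5)
  P <- Y + matrix(with_seed(4, rnorm(40)), 8, 5)
  m2d <- compute_metrics(P, Y)
  m1d <- compute_metrics(as.vector(P), as.vector(Y))
  expect_identical(m2d[names(m2d) != "n_nodes"],
                   m1d[names(m1d) != "n_nodes"])
  maf <- compute_metrics(2.5 * P + 1, Y)
  expect_equal(maf$PearsonR, m2d$PearsonR, tolerance = 1e-12)
})

test_that("Bland-Altman agreement matches hand computations", {
  x <- c(1, 2, 3)
  b0 <- bland_altman(x, x)
  expect_equal(b0$bias, 0); expect_equal(b0$loa_low, 0)
  expect_equal(b0$loa_high, 0)

  b2 <- bland_altman(x + 2, x)
  expect_equal(b2$bias, 2)
  expect_equal(b2$sd_diff, 0)
  expect_equal(c(b2$loa_low, b2$loa_high), c(2, 2))

  # differences {0, 1, 2}: bias 1, population sd sqrt(2/3)
  b <- bland_altman(c(1, 3, 5), c(1, 2, 3))
  expect_equal(b$bias, 1)
  expect_equal(b$sd_diff, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(b$loa_low, 1 - 1.96 * sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(b$loa_high, 1 + 1.96 * sqrt(2 / 3), tolerance = 1e-12)
  # limits re-derived from the returned bias/sd reproduce the fields
  expect_equal(b$loa_high - b$bias, 1.96 * b$sd_diff)
})

test_that("axial profiles locate uniform levels, rings, and throats", {
  U <- matrix(4.2, 20, 8)
  pu <- axial_profile(U)
  expect_equal(pu$wss_mean, rep(4.2, 20))
  expect_equal(range(pu$l_norm), c(0, 1))

  E <- U; E[7, ] <- 9
  expect_equal(which.max(axial_profile(E)$wss_mean), 7L)

  # severe concentric oracle: profile peak at the spec throat station
  cl <- resample_centerline(straight_points(), n = 160L, target_length = 80)
  sp <- make_stenosis_spec("concentric_round", area_ratio = 0.1,
                           position = 40, seed = 1)
  lat <- build_surface(cl, apply_stenosis(cl, sp), 20L)
  f <- oracle_wss_field(lat, flow_params())
  i_peak <- which.max(axial_profile(f)$wss_mean)
  i_spec <- which.min(abs(f$station_s - sp$position))
  expect_lte(abs(i_peak - i_spec), 2L)
})

test_that("the report bundle contains exactly the declared artifacts", {
  lat <- fix_small_lattice()
  ref <- oracle_wss_field(lat, flow_params(), seed = 2, noise_sd = 0.1)
  pred <- new_wss_field(ref$values * 0.9 + 0.1, ref$station_s,
                        ref$station_index, ref$n_theta)
  out <- withr::local_tempdir()
  paths <- render_report("toy case", pred, ref, out)
  expect_setequal(list.files(out),
                  c("heatmap_ref.png", "heatmap_pred.png",
                    "heatmap_error.png", "scatter.png", "bland_altman.png",
                    "axial_profile.png", "metrics.csv"))
  expect_true(all(file.exists(paths)))
  # the CSV re-read equals a fresh metrics computation
  tab <- read.csv(file.path(out, "metrics.csv"))
  m <- compute_metrics(pred, ref)
  expect_equal(tab$MAE, m$MAE, tolerance = 1e-12)
  expect_equal(tab$PearsonR, m$PearsonR, tolerance = 1e-12)
  expect_equal(tab$loa_high, bland_altman(pred, ref)$loa_high,
               tolerance = 1e-12)
})
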