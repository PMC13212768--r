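test_that("resampling produces the standard 640-point, 80 mm representation", {
  cl <- fix_straight_cl()
  expect_equal(cl$n_samples, 640L)
  expect_equal(centerline_length(cl), 80)
  expect_equal(diff(cl$s), rep(80 / 639, 639), tolerance = 1e-12)
  # measured polyline length matches the arc coordinate
  poly <- sum(sqrt(rowSums(diff(cl$xyz)^2)))
  expect_equal(poly, 80, tolerance = 1e-6)
  # input already conforming -> identity
  again <- resample_centerline(cl$xyz, n = 640L, target_length = 80)
  expect_equal(again$xyz, cl$xyz, tolerance = 1e-9)
})

test_that("resampling a quarter circle preserves shape while rescaling", {
  t <- seq(0, pi / 2, length.out = 200)
  cl <- resample_centerline(cbind(10 * cos(t), 10 * sin(t), 0),
                            n = 640L, target_length = 80)
  d <- compute_descriptors(cl)
  expect_equal(d$path_length, 80)
  # a circular arc rescaled from length 5*pi to 80 has radius 160/pi
  expect_equal(d$curvature[30:610], rep(pi / 160, 581), tolerance = 1e-3)
})

test_that("resampling rejects degenerate inputs", {
  expect_error(resample_centerline(cbind(0, 0, c(0, 1, 2)), 10, 10),
               "invalid-geometry")
  expect_error(resample_centerline(matrix(1, 5, 3), 10, 10),
               "invalid-geometry")
})

test_that("descriptors match closed forms for line, circle and helix", {
  ds <- compute_descriptors(fix_straight_cl())
  expect_equal(ds$sinuosity, 1)
  expect_equal(max(abs(ds$curvature)), 0, tolerance = 1e-9)
  expect_equal(max(abs(ds$torsion)), 0, tolerance = 1e-9)

  t <- seq(0, 2 * pi, length.out = 400)
  circ <- resample_centerline(cbind(10 * cos(t), 10 * sin(t), 0)[-400, ],
                              n = 640L, target_length = 2 * pi * 10 * 398 / 399)
  dc <- compute_descriptors(circ)
  expect_equal(dc$curvature[20:620], rep(0.1, 601), tolerance = 1e-3)
  expect_equal(dc$torsion[20:620], rep(0, 601), tolerance = 1e-3)

  t <- seq(0, 6 * pi, length.out = 500)
  helix <- resample_centerline(cbind(2 * cos(t), 2 * sin(t), t),
                               n = 640L, target_length = sqrt(5) * 6 * pi)
  dh <- compute_descriptors(helix)
  expect_equal(dh$curvature[20:620], rep(0.4, 601), tolerance = 1e-3)
  expect_equal(dh$torsion[20:620], rep(0.2, 601), tolerance = 1e-3)
})

test_that("descriptor guards reject short and closed curves", {
  cl <- new_centerline(cbind(0, 0, 0:3), 1, 0:3)
  expect_error(compute_descriptors(cl), "insufficient-samples")
  th <- seq(0, 2 * pi, length.out = 100)
  closed <- new_centerline(cbind(cos(th), sin(th), 0), 1,
                           seq(0, 1, length.out = 100))
  expect_error(compute_descriptors(closed), "degenerate-chord")
})

test_that("sinuosity is 1 only for collinear paths", {
  for (seed in 1:5) {
    pts <- with_seed(seed, {
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      outer(sort(runif(30, 0, 50)), dir)
    })
    d <- compute_descriptors(resample_centerline(pts, 100, 50))
    expect_equal(d$sinuosity, 1, tolerance = 1e-9)
    bent <- pts + with_seed(seed + 100, cbind(0, 3 * sin(seq(0, pi,
      length.out = 30)), 0))
    db <- compute_descriptors(resample_centerline(bent, 100, 50))
    expect_gt(db$sinuosity, 1)
  }
})

test_that("torsion vanishes on random planar splines", {
  for (seed in 1:5) {
    pts <- with_seed(seed, {
      x <- seq(0, 60, length.out = 40)
      cbind(x, 5 * sin(x / 10 + runif(1, 0, 2 * pi)) +
              3 * cos(x / 17 + runif(1, 0, 2 * pi)), 0)
    })
    d <- compute_descriptors(resample_centerline(pts, 400, 60))
    expect_lt(max(abs(d$torsion)), 1e-6)
  }
})

test_that("synthesis honours identity, standard, and constraint contracts", {
  tpl <- make_template_centerline("s_bend")
  base <- synthesize_centerline(tpl, amplitude = 0, seed = 1)
  expect_equal(base$n_samples, 640L)
  expect_equal(centerline_length(base), 80)
  # amplitude 0 equals the canonically aligned resampled template
  ref <- canonicalize_centerline(
    resample_centerline(tpl$xyz, 640L, 80, tpl$radius))
  expect_equal(base$xyz, ref$xyz, tolerance = 1e-12)

  s1 <- synthesize_centerline(tpl, amplitude = 1.5, seed = 42)
  s2 <- synthesize_centerline(tpl, amplitude = 1.5, seed = 42)
  expect_identical(s1$xyz, s2$xyz)   # bit-stable under a fixed seed
  expect_false(isTRUE(all.equal(s1$xyz, base$xyz)))
})

test_that("synthesized centerlines satisfy the descriptor bounds under audit", {
  bounds <- default_descriptor_bounds()
  tpl <- make_template_centerline("single_bend")
  for (seed in 1:20) {
    s <- synthesize_centerline(tpl, amplitude = 1.2, seed = seed,
                               bounds = bounds)
    d <- compute_descriptors(s)     # independent re-validation
    for (nm in names(bounds)) {
      expect_gte(d[[nm]], bounds[[nm]][1])
      expect_lte(d[[nm]], bounds[[nm]][2])
    }
  }
  # infeasible bounds report the violated descriptor
  expect_error(
    synthesize_centerline(tpl, amplitude = 1.2, seed = 1,
                          bounds = list(sinuosity = c(1, 1 + 1e-12)),
                          max_retry = 3),
    "constraint-infeasible.*sinuosity")
})

test_that("centerline CSV and VTP writers round-trip and validate", {
  cl <- fix_bend_cl()
  csv <- tempfile(fileext = ".csv")
  write_centerline_csv(cl, csv)
  back <- read_centerline_csv(csv)
  expect_equal(back$xyz, cl$xyz, tolerance = 1e-12)
  expect_equal(back$radius, cl$radius, tolerance = 1e-12)
  vtp <- tempfile(fileext = ".vtp")
  write_centerline_vtp(cl, vtp)
  doc <- readLines(vtp)
  expect_true(any(grepl("PolyData", doc)))
  expect_true(any(grepl(sprintf('NumberOfPoints="%d"', cl$n_samples), doc)))
})
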