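test_that("spec resolution matches the area-ratio arithmetic", {
  sp <- make_stenosis_spec("concentric_round", area_ratio = 0.16,
                           position = 40, seed = 1)
  expect_equal(2 * sp$semi_major, 1.2)     # 16% AR on D0 = 3 mm -> 1.2 mm
  expect_equal(sp$semi_major, sp$semi_minor)
  expect_equal(sp$eccentric_distance, 0)   # concentric forces d = 0

  spo <- make_stenosis_spec("eccentric_oval", area_ratio = 0.1,
                            position = 30, eccentric_distance = 0.4,
                            orientation = 1, aspect_ratio = 2)
  # throat area recomputed from the returned semi-axes
  expect_equal(pi * spo$semi_major * spo$semi_minor / (pi * 1.5^2), 0.1,
               tolerance = 1e-12)
  expect_equal(spo$semi_major / spo$semi_minor, 2)
})

test_that("severity presets map to the prescribed area ratios", {
  expect_equal(severity_area_ratio(c("mild", "moderate", "severe")),
               c(0.50, 0.30, 0.10))
  sp <- make_stenosis_spec("concentric_round", area_ratio = "severe",
                           position = 40, seed = 1)
  expect_equal(sp$area_ratio, 0.10)
  expect_error(severity_area_ratio("extreme"), "unknown severity")
})

test_that("spec validation names the violated bound", {
  expect_error(make_stenosis_spec("concentric_round", 0.95, 40),
               "area_ratio")
  expect_error(make_stenosis_spec("concentric_round", 0.5, 5), "position")
  expect_error(make_stenosis_spec("eccentric_round", 0.5, 40,
                                  eccentric_distance = 1.0),
               "eccentric_distance")
})

test_that("random draws are reproducible and within the invariant ranges", {
  for (seed in 1:10) {
    sp <- make_stenosis_spec(seed = seed)
    expect_true(sp$morphology %in% stenosis_morphologies())
    expect_gte(sp$area_ratio, 0.1); expect_lte(sp$area_ratio, 0.9)
    expect_gte(sp$position, 10); expect_lte(sp$position, 70)
    expect_lte(sp$eccentric_distance, 0.5 * 1.5 + 1e-12)
  }
  expect_identical(make_stenosis_spec(seed = 7),
                   make_stenosis_spec(seed = 7))
})

test_that("lesion profiles blend to the exact throat and back", {
  cl <- fix_straight_cl()
  # no lesion: all stations nominal
  p0 <- apply_stenosis(cl, NULL)
  expect_true(all(p0$a == 1.5 & p0$b == 1.5 & p0$off == 0))

  sp <- make_stenosis_spec("concentric_round", area_ratio = 0.16,
                           position = 40, seed = 1)
  p <- apply_stenosis(cl, sp)
  expect_equal(min(profile_area(p)) / (pi * 1.5^2), 0.16, tolerance = 1e-6)
  # nominal outside the taper
  far <- abs(p$s - 40) > sp$axial_extent / 2 + 1e-9
  expect_true(all(p$a[far] == 1.5))

  # area-ratio exactness across morphologies and severities (analytic)
  for (ar in c(0.1, 0.33, 0.9)) for (mo in stenosis_morphologies()) {
    spx <- make_stenosis_spec(mo, area_ratio = ar, position = 40, seed = 3)
    px <- apply_stenosis(cl, spx)
    expect_equal(min(profile_area(px)) / (pi * 1.5^2), ar,
                 tolerance = 1e-6)
  }
})

test_that("dual lesions must be separated by one axial extent", {
  cl <- fix_straight_cl()
  s1 <- make_stenosis_spec("concentric_round", 0.3, 30, seed = 1)
  s2 <- make_stenosis_spec("concentric_round", 0.5, 50, seed = 2)
  expect_s3_class(apply_stenosis(cl, list(s1, s2)), "section_profile")
  s3 <- make_stenosis_spec("concentric_round", 0.5, 33, seed = 2)
  expect_error(apply_stenosis(cl, list(s1, s3)), "overlap")
})

test_that("the wall lattice realizes the prescribed cross-sections", {
  lat <- fix_throat_lattice()
  expect_equal(c(lat$n_axial, lat$n_theta), c(640L, 40L))
  pa <- ring_polygon_area(lat)
  # unstenosed ring area = pi R0^2 within the 40-gon tolerance (0.5%)
  expect_equal(pa[1] / (pi * 1.5^2), 1, tolerance = 5e-3)
  # throat ring area = AR * A0 within 0.5%
  expect_equal(min(pa) / (0.16 * pi * 1.5^2), 1, tolerance = 5e-3)
  # ratio of polygon areas cancels the discretization factor
  expect_equal(min(pa) / pa[1], 0.16, tolerance = 1e-6)

  # straight unstenosed tube: every node at 1.5 mm from the axis
  lat0 <- fix_small_lattice()
  for (i in c(1L, 20L, 40L)) {
    d <- sqrt(rowSums(sweep(matrix(lat0$node_xyz[i, , ], 8, 3), 2,
                            lat0$centerline$xyz[i, ])^2))
    expect_equal(d, rep(1.5, 8), tolerance = 1e-9)
  }
})

test_that("eccentric throats offset the section centroid as prescribed", {
  cl <- fix_straight_cl()
  sp <- make_stenosis_spec("eccentric_round", area_ratio = 0.16,
                           position = 40, eccentric_distance = 0.6,
                           orientation = 1.2)
  lat <- build_surface(cl, apply_stenosis(cl, sp), 40L)
  it <- which.min(ring_polygon_area(lat))
  ctr <- colMeans(matrix(lat$node_xyz[it, , ], 40, 3))
  expect_equal(sqrt(sum((ctr - cl$xyz[it, ])^2)), 0.6, tolerance = 1e-9)
})

test_that("lattice generation is deterministic", {
  cl <- resample_centerline(make_template_centerline("helical")$xyz,
                            160L, 80)
  sp <- make_stenosis_spec("eccentric_oval", 0.3, 40, 0.5, 1, 2, seed = 9)
  l1 <- build_surface(cl, apply_stenosis(cl, sp), 20L)
  l2 <- build_surface(cl, apply_stenosis(cl, sp), 20L)
  expect_identical(l1$node_xyz, l2$node_xyz)
})

test_that("STL/CSV export is auditable and round-trips", {
  lat <- fix_throat_lattice()
  d <- withr::local_tempdir()
  out <- export_geometry(lat, stl_path = file.path(d, "w.stl"),
                         vtp_path = file.path(d, "c.vtp"),
                         csv_path = file.path(d, "n.csv"))
  stl <- read_stl_binary(out$stl)
  expect_equal(nrow(stl$v1), 2L * 639L * 40L)   # 51,120 wall triangles
  audit <- stl_edge_audit(stl)
  # every interior edge shared by exactly 2 triangles; the two open end
  # rings contribute exactly 2 * n_theta boundary edges
  expect_equal(unname(audit["1"]), 2L * 40L)
  expect_false(any(as.integer(names(audit)) > 2L))
  df <- read_lattice_csv(out$csv)
  flat <- matrix(aperm(lat$node_xyz, c(2, 1, 3)), 640L * 40L, 3L)
  expect_identical(cbind(df$x, df$y, df$z), flat)  # bitwise round trip
})
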