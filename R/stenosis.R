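# ---- stenosis specification -------------------------------------------------

#' Severity presets for the stenotic area ratio
#'
#' Maps clinical severity labels to area ratios: mild 50%, moderate 30%,
#' severe 10% (smaller area ratio = severer lesion).
#'
#' @param level `"mild"`, `"moderate"` or `"severe"` (vectorized).
#' @return Numeric area ratio(s).
#' @export
severity_area_ratio <- function(level) {
  map <- c(mild = 0.50, moderate = 0.30, severe = 0.10)
  bad <- setdiff(level, names(map))
  if (length(bad)) stop("unknown severity level: ", paste(bad, collapse = ", "))
  unname(map[level])
}

#' Morphology classes of a focal stenosis
#' @return Character vector of the four classes.
#' @export
stenosis_morphologies <- function() {
  c("concentric_round", "eccentric_round", "concentric_oval", "eccentric_oval")
}

#' Construct a fully resolved stenosis specification
#'
#' A lesion is described by its morphology class, stenotic area ratio
#' `AR = A_sten / A0` (throat cross-sectional area over nominal lumen area),
#' axial position of the throat, eccentric offset `d` of the throat centroid
#' from the centerline, throat semi-axes `a >= b` with `pi a b = AR * A0`,
#' in-plane orientation, and the axial extent of the tapered transition.
#' Arguments given as `"random"` are drawn uniformly within their valid
#' ranges (seeded).
#'
#' @param morphology one of [stenosis_morphologies()], or `"random"`.
#' @param area_ratio AR in `[0.1, 0.9]`, a severity label
#'   (`"mild"/"moderate"/"severe"`), or `"random"`.
#' @param position throat position in mm from the inlet, in `[10, 70]`, or
#'   `"random"`.
#' @param eccentric_distance offset d in mm (eccentric classes; concentric
#'   classes force 0). `"random"` draws up to `max_offset_frac` of the local
#'   radius.
#' @param orientation in-plane angle in rad, or `"random"` (uniform on
#'   `[0, 2*pi)`).
#' @param aspect_ratio a/b for oval classes (default `"random"` in
#'   `aspect_range`); round classes force 1.
#' @param aspect_range admissible oval aspect ratios (default `c(1.5, 3)`).
#' @param axial_extent taper length in mm (default 8).
#' @param nominal_diameter D0 in mm (default 3).
#' @param local_radius local lumen radius at `position` (defaults to D0/2);
#'   bounds the eccentric offset at 50% of it.
#' @param max_offset_frac cap on d as a fraction of the local radius
#'   (default 0.5).
#' @param seed integer seed used when any argument is `"random"`.
#' @return An object of class `stenosis_spec`.
#' @export
make_stenosis_spec <- function(morphology = "random", area_ratio = "random",
                               position = "random",
                               eccentric_distance = "random",
                               orientation = "random",
                               aspect_ratio = "random",
                               aspect_range = c(1.5, 3),
                               axial_extent = 8, nominal_diameter = 3,
                               local_radius = nominal_diameter / 2,
                               max_offset_frac = 0.5, seed = NULL) {
  with_seed(seed, {
    if (identical(morphology, "random"))
      morphology <- sample(stenosis_morphologies(), 1L)
    morphology <- match.arg(morphology, stenosis_morphologies())
    if (is.character(area_ratio) && area_ratio %in% c("mild", "moderate", "severe"))
      area_ratio <- severity_area_ratio(area_ratio)
    if (identical(area_ratio, "random")) area_ratio <- runif(1, 0.1, 0.9)
    if (identical(position, "random")) position <- runif(1, 10, 70)
    if (identical(orientation, "random")) orientation <- runif(1, 0, 2 * pi)
    concentric <- grepl("^concentric", morphology)
    oval <- grepl("oval$", morphology)
    if (concentric) {
      eccentric_distance <- 0
    } else if (identical(eccentric_distance, "random")) {
      eccentric_distance <- runif(1, 0.1, max_offset_frac) * local_radius
    }
    if (oval) {
      if (identical(aspect_ratio, "random"))
        aspect_ratio <- runif(1, aspect_range[1], aspect_range[2])
      if (aspect_ratio <= 1) stop("validation: oval aspect_ratio must exceed 1")
    } else aspect_ratio <- 1

    if (area_ratio < 0.1 || area_ratio > 0.9)
      stop("validation: area_ratio outside [0.1, 0.9]")
    if (position < 10 || position > 70)
      stop("validation: position outside [10, 70] mm")
    if (eccentric_distance > max_offset_frac * local_radius + 1e-12)
      stop(sprintf(
        "validation: eccentric_distance %.3f exceeds %.0f%% of local radius %.3f",
        eccentric_distance, 100 * max_offset_frac, local_radius))
    if (axial_extent <= 0) stop("validation: axial_extent must be positive")

    R0 <- nominal_diameter / 2
    A_throat <- area_ratio * pi * R0^2
    # pi a b = A_throat with a / b = aspect_ratio
    b <- sqrt(A_throat / (pi * aspect_ratio))
    a <- aspect_ratio * b
    structure(list(
      morphology = morphology, area_ratio = area_ratio, position = position,
      eccentric_distance = eccentric_distance, orientation = orientation,
      semi_major = a, semi_minor = b, aspect_ratio = aspect_ratio,
      axial_extent = axial_extent, nominal_diameter = nominal_diameter),
      class = "stenosis_spec")
  })
}

#' @export
print.stenosis_spec <- function(x, ...) {
  cat(sprintf(
    "<stenosis_spec> %s AR=%.3f at %.1f mm, d=%.3f mm, a=%.3f b=%.3f mm\n",
    x$morphology, x$area_ratio, x$position, x$eccentric_distance,
    x$semi_major, x$semi_minor))
  invisible(x)
}

# ---- per-station cross-section profile --------------------------------------

#' Sculpt lesions into a per-station cross-section profile
#'
#' Each axial station carries an elliptical cross-section boundary: centroid
#' offset `(off, orientation)` in the cross-section plane, semi-axes
#' `(a, b)` and in-plane angle. Away from lesions the section is the nominal
#' circle of radius D0/2. Within `axial_extent` of a throat the section
#' blends between nominal and throat shape with a cosine taper (weight 1 at
#' the throat, 0 at the taper edges). Throat positions are snapped to the
#' nearest station so the prescribed throat area is attained exactly at one
#' station.
#'
#' @param cl a `centerline` (typically 640 samples / 80 mm).
#' @param specs a single `stenosis_spec` or a list of 1-2 of them. `NULL` or
#'   an empty list yields the all-nominal profile.
#' @return A data.frame of class `section_profile` with one row per station:
#'   `station, s, off, off_angle, a, b, phi` (mm / rad).
#' @export
apply_stenosis <- function(cl, specs = NULL) {
  stopifnot(inherits(cl, "centerline"))
  if (inherits(specs, "stenosis_spec")) specs <- list(specs)
  if (is.null(specs)) specs <- list()
  n <- cl$n_samples
  R0 <- if (length(specs)) specs[[1L]]$nominal_diameter / 2 else cl$radius[1L]
  prof <- data.frame(station = seq_len(n), s = cl$s,
                     off = 0, off_angle = 0, a = R0, b = R0, phi = 0)

  if (length(specs) > 1L) {
    pos <- vapply(specs, `[[`, numeric(1), "position")
    ext <- vapply(specs, `[[`, numeric(1), "axial_extent")
    o <- order(pos)
    for (i in seq_len(length(specs) - 1L)) {
      gap <- pos[o[i + 1L]] - pos[o[i]]
      min_gap <- max(ext[o[i]], ext[o[i + 1L]])
      if (gap < min_gap)
        stop(sprintf(
          "overlap: throats %.1f and %.1f mm apart are closer than one axial extent (%.1f mm)",
          pos[o[i]], pos[o[i + 1L]], min_gap))
    }
  }

  L <- cl$s[n] - cl$s[1]
  for (sp in specs) {
    half <- sp$axial_extent / 2
    if (sp$position - half < cl$s[1] - 1e-9 ||
        sp$position + half > cl$s[n] + 1e-9)
      stop("validation: lesion axial extent lies outside the vessel")
    i_throat <- which.min(abs(cl$s - sp$position))
    s_throat <- cl$s[i_throat]
    u <- (cl$s - s_throat) / half                       # -1..1 inside taper
    w <- ifelse(abs(u) <= 1, 0.5 * (1 + cos(pi * u)), 0)
    idx <- which(w > 0)
    prof$a[idx] <- R0 + w[idx] * (sp$semi_major - R0)
    prof$b[idx] <- R0 + w[idx] * (sp$semi_minor - R0)
    prof$off[idx] <- w[idx] * sp$eccentric_distance
    prof$off_angle[idx] <- sp$orientation
    prof$phi[idx] <- sp$orientation
  }
  class(prof) <- c("section_profile", class(prof))
  attr(prof, "nominal_radius") <- R0
  prof
}

#' Analytic cross-sectional area per station of a profile
#' @param profile a `section_profile`.
#' @return Numeric vector `pi * a * b` per station (mm^2).
#' @export
profile_area <- function(profile) pi * profile$a * profile$b

# ---- rotation-minimizing frames and surface lattice -------------------------

# parallel-transport (double-reflection) frames along the centerline;
# returns list(tangent, normal, binormal) as n x 3 matrices
rmf_frames <- function(cl) {
  xyz <- cl$xyz; n <- nrow(xyz)
  tg <- .fd_mat(xyz, cl$s[2] - cl$s[1])
  nt <- sqrt(rowSums(tg^2))
  if (any(nt < 1e-12)) stop("invalid-geometry: zero tangent in frame computation")
  tg <- tg / nt
  # initial normal: any vector orthogonal to t1
  t1 <- tg[1L, ]
  ref <- if (abs(t1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  n1 <- ref - sum(ref * t1) * t1
  n1 <- n1 / sqrt(sum(n1^2))
  N <- matrix(0, n, 3L); N[1L, ] <- n1
  for (i in seq_len(n - 1L)) {
    v1 <- xyz[i + 1L, ] - xyz[i, ]
    c1 <- sum(v1 * v1)
    if (c1 < 1e-24) { N[i + 1L, ] <- N[i, ]; next }
    rL <- N[i, ] - (2 / c1) * sum(v1 * N[i, ]) * v1
    tL <- tg[i, ] - (2 / c1) * sum(v1 * tg[i, ]) * v1
    v2 <- tg[i + 1L, ] - tL
    c2 <- sum(v2 * v2)
    Nn <- if (c2 < 1e-24) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    # re-orthogonalize against the true tangent
    Nn <- Nn - sum(Nn * tg[i + 1L, ]) * tg[i + 1L, ]
    N[i + 1L, ] <- Nn / sqrt(sum(Nn^2))
  }
  B <- cbind(tg[, 2] * N[, 3] - tg[, 3] * N[, 2],
             tg[, 3] * N[, 1] - tg[, 1] * N[, 3],
             tg[, 1] * N[, 2] - tg[, 2] * N[, 1])
  list(tangent = tg, normal = N, binormal = B)
}

#' Build the structured wall lattice
#'
#' Places node `(i, k)` on the station-`i` cross-section boundary at
#' circumferential parameter `2*pi*(k-1)/n_theta`, measured in a
#' rotation-minimizing (parallel-transport) frame along the centerline. The
#' boundary is the profile ellipse, rotated by its in-plane angle and offset
#' by the eccentric displacement.
#'
#' @param cl a `centerline`.
#' @param profile a `section_profile` from [apply_stenosis()].
#' @param n_theta circumferential resolution (default 40).
#' @return An object of class `surface_lattice`: `node_xyz` array
#'   (n_axial x n_theta x 3), `station_s`, `station_radius` (effective
#'   radius `sqrt(a*b)`), `station_curvature`, `station_area`, `frames`,
#'   `centerline`, `profile`, `n_axial`, `n_theta`.
#' @export
build_surface <- function(cl, profile, n_theta = 40L) {
  stopifnot(inherits(cl, "centerline"))
  n <- cl$n_samples
  if (nrow(profile) != n) stop("shape: profile must cover every station")
  fr <- rmf_frames(cl)
  dsc <- compute_descriptors(cl)
  theta <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta

  node <- array(0, c(n, n_theta, 3L))
  for (i in seq_len(n)) {
    phi <- profile$phi[i]
    tloc <- theta - phi
    ex <- profile$a[i] * cos(tloc)
    ey <- profile$b[i] * sin(tloc)
    # rotate ellipse by phi, add centroid offset
    px <- ex * cos(phi) - ey * sin(phi) + profile$off[i] * cos(profile$off_angle[i])
    py <- ex * sin(phi) + ey * cos(phi) + profile$off[i] * sin(profile$off_angle[i])
    node[i, , ] <- rep(cl$xyz[i, ], each = n_theta) +
      outer(px, fr$normal[i, ]) + outer(py, fr$binormal[i, ])
  }
  structure(list(
    node_xyz = node, station_s = cl$s,
    station_radius = sqrt(profile$a * profile$b),
    station_curvature = dsc$curvature,
    station_area = pi * profile$a * profile$b,
    frames = fr, centerline = cl, profile = profile,
    n_axial = n, n_theta = as.integer(n_theta)),
    class = "surface_lattice")
}

#' @export
print.surface_lattice <- function(x, ...) {
  cat(sprintf("<surface_lattice> %d x %d nodes, length %.1f mm\n",
              x$n_axial, x$n_theta, x$station_s[x$n_axial] - x$station_s[1]))
  invisible(x)
}

#' Polygon (shoelace) area of each cross-sectional ring
#'
#' Areas are measured in the local cross-section plane; used to audit the
#' lattice against the prescribed analytic areas.
#'
#' @param lattice a `surface_lattice`.
#' @return Numeric vector of ring polygon areas (mm^2).
#' @export
ring_polygon_area <- function(lattice) {
  n <- lattice$n_axial; m <- lattice$n_theta
  fr <- lattice$frames
  areas <- numeric(n)
  cxyz <- lattice$centerline$xyz
  for (i in seq_len(n)) {
    rel <- sweep(matrix(lattice$node_xyz[i, , ], m, 3L), 2L, cxyz[i, ])
    u <- rel %*% fr$normal[i, ]
    v <- rel %*% fr$binormal[i, ]
    j <- c(2:m, 1L)
    areas[i] <- 0.5 * abs(sum(u * v[j] - u[j] * v))
  }
  areas
}

# ---- export -----------------------------------------------------------------

#' Export a lattice as STL surface, VTP centerline and CSV node table
#'
#' The wall is triangulated by splitting each quad consistently
#' (`2 * (n_axial - 1) * n_theta` triangles, circumferentially closed, open
#' at the two ends unless `cap_ends`). Binary STL; the node CSV has columns
#' `i, k, x, y, z, s_mm, angle_rad` and round-trips exactly.
#'
#' @param lattice a `surface_lattice`.
#' @param stl_path,vtp_path,csv_path output files (any may be `NULL` to skip).
#' @param cap_ends triangulate fans over the two end rings (default FALSE).
#' @return Invisibly, a named list of the written paths.
#' @export
export_geometry <- function(lattice, stl_path = NULL, vtp_path = NULL,
                            csv_path = NULL, cap_ends = FALSE) {
  out <- list()
  if (!is.null(stl_path)) {
    tri <- lattice_triangles(lattice, cap_ends = cap_ends)
    write_stl_binary(tri$v1, tri$v2, tri$v3, stl_path)
    out$stl <- stl_path
  }
  if (!is.null(vtp_path)) {
    write_centerline_vtp(lattice$centerline, vtp_path)
    out$vtp <- vtp_path
  }
  if (!is.null(csv_path)) {
    n <- lattice$n_axial; m <- lattice$n_theta
    idx <- expand.grid(k = seq_len(m), i = seq_len(n))
    flat <- matrix(aperm(lattice$node_xyz, c(2L, 1L, 3L)), n * m, 3L)
    df <- data.frame(i = idx$i, k = idx$k,
                     x = flat[, 1], y = flat[, 2], z = flat[, 3],
                     s_mm = rep(lattice$station_s, each = m),
                     angle_rad = rep(2 * pi * (seq_len(m) - 1L) / m, n))
    write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
              csv_path, row.names = FALSE, quote = FALSE)
    out$csv <- csv_path
  }
  invisible(out)
}

# triangle soup of the wall; consistent quad split
lattice_triangles <- function(lattice, cap_ends = FALSE) {
  n <- lattice$n_axial; m <- lattice$n_theta
  node <- lattice$node_xyz
  P <- function(i, k) matrix(node[cbind(i, k, rep(1:3, each = length(i)))],
                             length(i), 3L)
  i <- rep(seq_len(n - 1L), each = m)
  k <- rep(seq_len(m), n - 1L)
  k2 <- ifelse(k == m, 1L, k + 1L)
  a <- P(i, k); b <- P(i + 1L, k); c_ <- P(i + 1L, k2); d <- P(i, k2)
  v1 <- rbind(a, a); v2 <- rbind(b, c_); v3 <- rbind(c_, d)
  if (cap_ends) {
    ce <- lattice$centerline$xyz
    for (end in c(1L, n)) {
      kk <- seq_len(m); kk2 <- ifelse(kk == m, 1L, kk + 1L)
      ctr <- matrix(ce[end, ], m, 3L, byrow = TRUE)
      if (end == 1L) {
        v1 <- rbind(v1, ctr); v2 <- rbind(v2, P(rep(end, m), kk2))
        v3 <- rbind(v3, P(rep(end, m), kk))
      } else {
        v1 <- rbind(v1, ctr); v2 <- rbind(v2, P(rep(end, m), kk))
        v3 <- rbind(v3, P(rep(end, m), kk2))
      }
    }
  }
  list(v1 = v1, v2 = v2, v3 = v3)
}

#' Write / read binary STL
#'
#' @param v1,v2,v3 (n_tri x 3) matrices of triangle vertices.
#' @param path output `.stl` file.
#' @return `write_stl_binary` the path invisibly; `read_stl_binary` a list
#'   with `v1, v2, v3, normals` matrices.
#' @export
write_stl_binary <- function(v1, v2, v3, path) {
  ntri <- nrow(v1)
  e1 <- v2 - v1; e2 <- v3 - v1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  writeBin(as.integer(ntri), con, size = 4L, endian = "little")
  block <- t(cbind(nrm, v1, v2, v3))     # 12 floats per triangle
  for (start in seq(1L, ntri, by = 65536L)) {
    end <- min(start + 65535L, ntri)
    for (tr in start:end) {
      writeBin(as.numeric(block[, tr]), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  }
  invisible(path)
}

#' @rdname write_stl_binary
#' @export
read_stl_binary <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  rec <- matrix(0, 12L, ntri)
  for (tr in seq_len(ntri)) {
    rec[, tr] <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
    readBin(con, "raw", 2L)
  }
  list(normals = t(rec[1:3, , drop = FALSE]),
       v1 = t(rec[4:6, , drop = FALSE]),
       v2 = t(rec[7:9, , drop = FALSE]),
       v3 = t(rec[10:12, , drop = FALSE]))
}

#' Edge-manifold audit of a triangle soup
#'
#' Counts how many triangles share each undirected edge (vertices matched to
#' a tolerance by rounding). For a watertight surface every edge is shared by
#' exactly 2 triangles; an open tube additionally has boundary edges shared
#' by exactly 1 (the two end rings).
#'
#' @param stl a list with `v1, v2, v3` as read by [read_stl_binary()].
#' @param digits vertex rounding for identification (default 4).
#' @return A table of edge multiplicities.
#' @export
stl_edge_audit <- function(stl, digits = 4) {
  key <- function(v) apply(round(v, digits), 1L, paste, collapse = ",")
  k1 <- key(stl$v1); k2 <- key(stl$v2); k3 <- key(stl$v3)
  edge <- function(a, b) ifelse(a < b, paste(a, b, sep = "|"),
                                paste(b, a, sep = "|"))
  edges <- c(edge(k1, k2), edge(k2, k3), edge(k3, k1))
  table(table(edges))
}

#' Read back a lattice node CSV
#' @param path CSV written by [export_geometry()].
#' @return data.frame with columns `i, k, x, y, z, s_mm, angle_rad`.
#' @export
read_lattice_csv <- function(path) read.csv(path)
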