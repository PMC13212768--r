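#' @importFrom stats splinefun rnorm runif sd approx
#' @importFrom utils write.csv read.csv head tail
NULL

# ---- centerline container ---------------------------------------------------

#' Construct a centerline object
#'
#' A centerline is an arc-length-parameterized 3D path with a per-sample lumen
#' radius. `arc_coord` must be strictly increasing and all radii positive.
#'
#' @param xyz numeric matrix (n x 3), positions in mm.
#' @param radius numeric vector of per-sample lumen radii in mm (recycled if
#'   length 1).
#' @param arc_coord numeric vector of arc-length coordinates s in mm.
#' @return An object of class `centerline` with fields `xyz`, `radius`, `s`.
#' @export
new_centerline <- function(xyz, radius, arc_coord) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L) stop("invalid-geometry: xyz must be an n x 3 matrix")
  n <- nrow(xyz)
  if (length(radius) == 1L) radius <- rep(as.numeric(radius), n)
  if (length(radius) != n || length(arc_coord) != n)
    stop("invalid-geometry: field lengths disagree")
  if (any(!is.finite(xyz)) || any(!is.finite(radius)) || any(!is.finite(arc_coord)))
    stop("invalid-geometry: non-finite values")
  if (any(diff(arc_coord) <= 0))
    stop("invalid-geometry: arc_coord must be strictly increasing")
  if (any(radius <= 0)) stop("invalid-geometry: all radii must be positive")
  structure(
    list(xyz = xyz, radius = as.numeric(radius), s = as.numeric(arc_coord),
         n_samples = n),
    class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d samples, length %.3f mm, radius %.3f-%.3f mm\n",
              x$n_samples, x$s[x$n_samples] - x$s[1],
              min(x$radius), max(x$radius)))
  invisible(x)
}

#' Total path length of a centerline (mm)
#' @param cl a `centerline`.
#' @return numeric scalar, `s[last] - s[first]`.
#' @export
centerline_length <- function(cl) cl$s[cl$n_samples] - cl$s[1]

# ---- resampling -------------------------------------------------------------

#' Rescale and uniformly resample an ordered 3D path
#'
#' The input polyline is parameterized by cumulative chord length, smoothed
#' through natural cubic splines per coordinate, reparameterized by arc
#' length, rescaled so the output polyline length equals `target_length`
#' exactly, and sampled at `n` endpoint-inclusive stations spaced
#' `target_length / (n - 1)` apart.
#'
#' @param points numeric matrix (m x 3) of ordered positions, m >= 4.
#' @param n number of output samples (default 640).
#' @param target_length output path length in mm (default 80).
#' @param radius optional per-input-point radius (mm); interpolated onto the
#'   output stations. A scalar is propagated. Default 1.5 mm (half the 3 mm
#'   nominal diameter).
#' @return A [new_centerline()] object with `n` samples.
#' @export
resample_centerline <- function(points, n = 640L, target_length = 80,
                                radius = 1.5) {
  points <- as.matrix(points)
  if (nrow(points) < 4L) stop("invalid-geometry: need at least 4 input points")
  if (ncol(points) != 3L) stop("invalid-geometry: points must be m x 3")
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  if (sum(seg) <= 0) stop("invalid-geometry: zero-length input path")
  keep <- c(TRUE, seg > 0)          # drop exactly duplicated points
  points <- points[keep, , drop = FALSE]
  if (length(radius) > 1L) radius <- radius[keep]
  t0 <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))

  fx <- splinefun(t0, points[, 1L], method = "natural")
  fy <- splinefun(t0, points[, 2L], method = "natural")
  fz <- splinefun(t0, points[, 3L], method = "natural")

  # reparameterize by arc length on a dense grid
  m_dense <- max(10L * n, 2000L)
  td <- seq(0, t0[length(t0)], length.out = m_dense)
  pd <- cbind(fx(td), fy(td), fz(td))
  sd_ <- c(0, cumsum(sqrt(rowSums(diff(pd)^2))))
  s_new <- seq(0, sd_[length(sd_)], length.out = n)
  t_new <- approx(sd_, td, xout = s_new, ties = "ordered")$y
  out <- cbind(fx(t_new), fy(t_new), fz(t_new))

  # exact rescale: polyline length is linear in a global scale factor
  L_out <- sum(sqrt(rowSums(diff(out)^2)))
  out <- sweep(out, 2L, out[1L, ])
  out <- out * (target_length / L_out)
  out <- sweep(out, 2L, points[1L, ], FUN = "+")

  if (length(radius) == 1L) {
    rad_new <- rep(radius, n)
  } else {
    rad_new <- approx(t0, radius, xout = t_new, rule = 2, ties = "ordered")$y
  }
  new_centerline(out, rad_new, seq(0, target_length, length.out = n))
}

# ---- descriptors ------------------------------------------------------------

# successive central differences on a uniform grid, one-sided at endpoints
.fd <- function(v, h) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * h)
  d[1] <- (v[2] - v[1]) / h
  d[n] <- (v[n] - v[n - 1]) / h
  d
}

.fd_mat <- function(m, h) apply(m, 2L, .fd, h = h)

#' Geometric descriptors of a centerline
#'
#' Computes the path length `l = s_max - s_min`, the chord length
#' `c = ||r(s_end) - r(s_start)||`, the sinuosity `S = l / c`, and per-sample
#' Frenet-Serret curvature and torsion
#' \deqn{\kappa(s) = \frac{\|r' \times r''\|}{\|r'\|^3}, \qquad
#'       \tau(s) = \frac{\det(r', r'', r''')}{\|r' \times r''\|^2},}
#' with derivatives by central finite differences on the uniform arc grid
#' (one-sided at the endpoints). Where \eqn{\|r' \times r''\| < 10^{-9}}
#' (locally straight) the torsion is set to 0. Integral curvature measures
#' exposed: `total_curvature` (trapezoidal \eqn{\int \kappa\, ds}),
#' `max_curvature` and `mean_curvature`.
#'
#' @param cl a `centerline` with at least 5 samples.
#' @return A list of class `geometry_descriptors` with fields `path_length`,
#'   `chord_length`, `sinuosity`, `curvature`, `torsion`,
#'   `total_curvature`, `max_curvature`, `mean_curvature`.
#' @export
compute_descriptors <- function(cl) {
  stopifnot(inherits(cl, "centerline"))
  n <- cl$n_samples
  if (n < 5L) stop("insufficient-samples: need at least 5 samples")
  h <- cl$s[2] - cl$s[1]
  l <- cl$s[n] - cl$s[1]
  chord <- sqrt(sum((cl$xyz[n, ] - cl$xyz[1, ])^2))
  if (chord < 1e-12) stop("degenerate-chord: start and end coincide")

  r1 <- .fd_mat(cl$xyz, h)
  r2 <- .fd_mat(r1, h)
  r3 <- .fd_mat(r2, h)

  cr <- cbind(r1[, 2] * r2[, 3] - r1[, 3] * r2[, 2],
              r1[, 3] * r2[, 1] - r1[, 1] * r2[, 3],
              r1[, 1] * r2[, 2] - r1[, 2] * r2[, 1])
  cr_norm <- sqrt(rowSums(cr^2))
  speed <- sqrt(rowSums(r1^2))
  kappa <- cr_norm / pmax(speed^3, 1e-300)

  det3 <- rowSums(cr * r3)            # det(r', r'', r''') = (r' x r'') . r'''
  tors <- ifelse(cr_norm < 1e-9, 0, det3 / cr_norm^2)

  structure(list(
    path_length = l, chord_length = chord, sinuosity = l / chord,
    curvature = kappa, torsion = tors,
    total_curvature = sum((kappa[-1] + kappa[-n]) / 2) * h,
    max_curvature = max(kappa), mean_curvature = mean(kappa)),
    class = "geometry_descriptors")
}

#' @export
print.geometry_descriptors <- function(x, ...) {
  cat(sprintf(
    "<descriptors> l=%.3f mm  c=%.3f mm  S=%.4f  max kappa=%.4f 1/mm\n",
    x$path_length, x$chord_length, x$sinuosity, x$max_curvature))
  invisible(x)
}

# ---- templates and synthesis ------------------------------------------------

#' Parametric template centerlines
#'
#' Four canonical vessel path families used as deformation templates:
#' straight, single-bend, S-bend and helical. All are generated at unit
#' nominal radius scale (1.5 mm lumen radius) and should be passed through
#' [resample_centerline()] (done by [synthesize_centerline()]).
#'
#' @param kind one of `"straight"`, `"single_bend"`, `"s_bend"`, `"helical"`.
#' @param n number of raw parameter samples (default 400).
#' @param length nominal template length scale in mm (default 80).
#' @return A `centerline`.
#' @export
make_template_centerline <- function(kind = c("straight", "single_bend",
                                              "s_bend", "helical"),
                                     n = 400L, length = 80) {
  kind <- match.arg(kind)
  u <- seq(0, 1, length.out = n)
  L <- length
  pts <- switch(kind,
    straight    = cbind(0, 0, u * L),
    single_bend = cbind(6 * sin(pi * u), 0, u * L),
    s_bend      = cbind(5 * sin(2 * pi * u), 0, u * L),
    helical     = cbind(3 * cos(2.5 * pi * u) - 3, 3 * sin(2.5 * pi * u), u * L))
  resample_centerline(pts, n = n, target_length = L, radius = 1.5)
}

#' Default descriptor bounds for centerline synthesis
#'
#' Ranges of (sinuosity, total curvature, max curvature) measured over the
#' packaged template family, widened by a tolerance factor. These stand in
#' for clinical empirical descriptor distributions, which the package does
#' not reproduce.
#'
#' @param margin multiplicative widening of the measured upper bounds
#'   (default 1.5).
#' @return A list with elements `sinuosity`, `total_curvature`,
#'   `max_curvature`, each `c(lo, hi)`.
#' @export
default_descriptor_bounds <- function(margin = 1.5) {
  kinds <- c("straight", "single_bend", "s_bend", "helical")
  d <- lapply(kinds, function(k) {
    compute_descriptors(resample_centerline(
      make_template_centerline(k)$xyz, n = 640L, target_length = 80))
  })
  rng <- function(f) range(vapply(d, `[[`, numeric(1), f))
  list(
    sinuosity       = c(1, rng("sinuosity")[2] * margin),
    total_curvature = c(0, rng("total_curvature")[2] * margin),
    max_curvature   = c(0, rng("max_curvature")[2] * margin))
}

# run expr under a private RNG stream, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Canonically align a centerline
#'
#' Translates the inlet to the origin and rotates the inlet tangent onto the
#' positive z axis (the canonical coordinate system of the cohort).
#'
#' @param cl a `centerline`.
#' @return The aligned `centerline`.
#' @export
canonicalize_centerline <- function(cl) {
  xyz <- sweep(cl$xyz, 2L, cl$xyz[1L, ])
  t0 <- xyz[2L, ] - xyz[1L, ]
  t0 <- t0 / sqrt(sum(t0^2))
  z <- c(0, 0, 1)
  v <- c(t0[2] * z[3] - t0[3] * z[2],
         t0[3] * z[1] - t0[1] * z[3],
         t0[1] * z[2] - t0[2] * z[1])
  s2 <- sum(v^2); cth <- sum(t0 * z)
  if (s2 < 1e-20) {
    Rm <- if (cth > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    Rm <- diag(3) + vx + vx %*% vx * ((1 - cth) / s2)
  }
  new_centerline(xyz %*% t(Rm), cl$radius, cl$s)
}

#' Synthesize a descriptor-constrained random centerline
#'
#' Applies a smooth random deformation to a template path: a sum of
#' Gaussian-kernel displacement bumps (random centers, widths, directions and
#' amplitudes), followed by canonical alignment, rescaling to `target_length`
#' and uniform resampling to `n` points. Candidates are rejected and redrawn
#' until the [compute_descriptors()] vector falls inside `bounds`
#' (sinuosity, total curvature, max curvature), up to `max_retry` attempts.
#' Deterministic for a fixed `seed`; `amplitude = 0` returns the resampled
#' template unchanged.
#'
#' @param template a `centerline` template (see [make_template_centerline()]).
#' @param amplitude displacement amplitude scale in mm (sd of bump
#'   amplitudes); `>= 0`.
#' @param seed integer seed (required for reproducibility; may be `NULL`).
#' @param bounds descriptor ranges, see [default_descriptor_bounds()].
#' @param n,target_length resampling standard (default 640 points, 80 mm).
#' @param n_bumps number of Gaussian displacement bumps (default 6).
#' @param sigma_range range of bump widths in mm (default 8-20).
#' @param max_retry rejection-sampling cap (default 50).
#' @return A `centerline` satisfying the bounds.
#' @export
synthesize_centerline <- function(template, amplitude = 1.0, seed = NULL,
                                  bounds = default_descriptor_bounds(),
                                  n = 640L, target_length = 80,
                                  n_bumps = 6L, sigma_range = c(8, 20),
                                  max_retry = 50L) {
  stopifnot(inherits(template, "centerline"), amplitude >= 0,
            length(bounds) >= 1L)
  base <- resample_centerline(template$xyz, n = n,
                              target_length = target_length,
                              radius = template$radius)
  base <- canonicalize_centerline(base)
  if (amplitude == 0) return(base)

  with_seed(seed, {
    last_violation <- "none"
    for (try in seq_len(max_retry)) {
      disp <- matrix(0, n, 3L)
      for (j in seq_len(n_bumps)) {
        cj <- runif(1, 0.1, 0.9) * target_length
        sj <- runif(1, sigma_range[1], sigma_range[2])
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        aj <- rnorm(1, 0, amplitude)
        disp <- disp + outer(aj * exp(-(base$s - cj)^2 / (2 * sj^2)), dir)
      }
      cand <- resample_centerline(base$xyz + disp, n = n,
                                  target_length = target_length,
                                  radius = base$radius)
      cand <- canonicalize_centerline(cand)
      dsc <- compute_descriptors(cand)
      ok <- TRUE
      for (nm in names(bounds)) {
        val <- dsc[[nm]]
        if (val < bounds[[nm]][1] || val > bounds[[nm]][2]) {
          ok <- FALSE
          last_violation <- sprintf("%s = %.4g outside [%.4g, %.4g]",
                                    nm, val, bounds[[nm]][1], bounds[[nm]][2])
          break
        }
      }
      if (ok) return(cand)
    }
    stop("constraint-infeasible: retry cap exhausted; last violation: ",
         last_violation)
  })
}

# ---- I/O --------------------------------------------------------------------

#' Write / read a centerline as CSV
#'
#' Columns: `s_mm, x_mm, y_mm, z_mm, radius_mm`. The round trip is exact to
#' the printed precision (15 significant digits).
#'
#' @param cl a `centerline`.
#' @param path output file.
#' @return `write_centerline_csv` the path invisibly; `read_centerline_csv`
#'   a `centerline`.
#' @export
write_centerline_csv <- function(cl, path) {
  df <- data.frame(s_mm = cl$s, x_mm = cl$xyz[, 1], y_mm = cl$xyz[, 2],
                   z_mm = cl$xyz[, 3], radius_mm = cl$radius)
  old <- options(digits = 15); on.exit(options(old))
  write.csv(format(df, digits = 15, scientific = TRUE, trim = TRUE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_centerline_csv
#' @export
read_centerline_csv <- function(path) {
  df <- read.csv(path)
  new_centerline(cbind(df$x_mm, df$y_mm, df$z_mm), df$radius_mm, df$s_mm)
}

#' Write a centerline as VTK XML PolyData (VTP)
#'
#' ASCII VTP with the path as a single polyline and the radius as point data,
#' readable by standard mesh viewers.
#'
#' @param cl a `centerline`.
#' @param path output `.vtp` file.
#' @return The path, invisibly.
#' @export
write_centerline_vtp <- function(cl, path) {
  n <- cl$n_samples
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">')
  w('  <PolyData>')
  w('    <Piece NumberOfPoints="%d" NumberOfVerts="0" NumberOfLines="1" NumberOfStrips="0" NumberOfPolys="0">', n)
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(paste(apply(cl$xyz, 1L, function(p)
    sprintf("%.10g %.10g %.10g", p[1], p[2], p[3])), collapse = " "), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <PointData Scalars="radius_mm">')
  w('        <DataArray type="Float64" Name="radius_mm" format="ascii">')
  writeLines(paste(sprintf("%.10g", cl$radius), collapse = " "), con)
  w('        </DataArray>')
  w('      </PointData>')
  w('      <Lines>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(paste(0:(n - 1L), collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  w('          %d', n)
  w('        </DataArray>')
  w('      </Lines>')
  w('    </Piece>')
  w('  </PolyData>')
  w('</VTKFile>')
  invisible(path)
}
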