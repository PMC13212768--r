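# ---- flow parameters --------------------------------------------------------

#' Default hemodynamic flow parameters
#'
#' Defaults: cycle-averaged inlet velocity 0.20 m/s with a 0.55 m/s peak over
#' a 0.6 s cardiac cycle, blood density 1060 kg/m^3, Carreau shear-thinning
#' rheology with standard literature blood constants
#' (mu0 = 0.056 Pa s, mu_inf = 0.00345 Pa s, lambda = 3.313 s, n = 0.3568),
#' and a 13.3 kPa (100 mmHg) outlet pressure.
#'
#' @param mean_inlet_velocity cycle-averaged inlet velocity, m/s.
#' @param peak_inlet_velocity peak inlet velocity, m/s (must exceed the mean).
#' @param cycle_period cardiac cycle length, s.
#' @param blood_density kg/m^3.
#' @param mu0,mu_inf Carreau zero/infinite-shear viscosities, Pa s
#'   (`mu_inf < mu0`).
#' @param lambda_relax Carreau relaxation time, s.
#' @param n_index Carreau power index, in (0, 1).
#' @param outlet_pressure kPa.
#' @return A list of class `flow_params`.
#' @export
flow_params <- function(mean_inlet_velocity = 0.20,
                        peak_inlet_velocity = 0.55,
                        cycle_period = 0.6,
                        blood_density = 1060,
                        mu0 = 0.056, mu_inf = 0.00345,
                        lambda_relax = 3.313, n_index = 0.3568,
                        outlet_pressure = 13.3) {
  p <- list(mean_inlet_velocity = mean_inlet_velocity,
            peak_inlet_velocity = peak_inlet_velocity,
            cycle_period = cycle_period, blood_density = blood_density,
            mu0 = mu0, mu_inf = mu_inf, lambda_relax = lambda_relax,
            n_index = n_index, outlet_pressure = outlet_pressure)
  if (any(unlist(p) <= 0)) stop("parameter: all flow parameters must be positive")
  if (mu_inf >= mu0) stop("parameter: mu_inf must be below mu0")
  if (n_index >= 1) stop("parameter: Carreau n_index must be below 1")
  if (peak_inlet_velocity < mean_inlet_velocity)
    stop("parameter: peak velocity below mean velocity is infeasible")
  structure(p, class = "flow_params")
}

# ---- inlet waveform ---------------------------------------------------------

# raw two-bump shape on [0, 1): small systolic shoulder + dominant diastolic
# peak, wrapped to be smoothly periodic
.waveform_shape <- function(u) {
  g <- rep(0, length(u))
  for (shift in c(-1, 0, 1)) {
    g <- g + 0.45 * exp(-((u + shift - 0.18)^2) / (2 * 0.06^2)) +
             1.00 * exp(-((u + shift - 0.62)^2) / (2 * 0.11^2))
  }
  g
}

#' Diastole-dominant coronary inlet velocity waveform
#'
#' A periodic two-bump parametric waveform (small systolic shoulder plus a
#' dominant diastolic peak on a baseline), affinely renormalized so that the
#' cycle average equals `mean_inlet_velocity` and the maximum equals
#' `peak_inlet_velocity`; non-negative everywhere for the default parameters.
#'
#' @param t time(s) in seconds (vectorized); evaluated modulo the cycle.
#' @param params a [flow_params()] object.
#' @return Inlet velocity in m/s, same length as `t`.
#' @export
inlet_waveform <- function(t, params = flow_params()) {
  stopifnot(inherits(params, "flow_params"))
  T_ <- params$cycle_period
  u <- (t %% T_) / T_
  # renormalization constants of the fixed shape (cycle mean and max)
  uu <- seq(0, 1, length.out = 20001L)[-20001L]
  gg <- .waveform_shape(uu)
  g_mean <- mean(gg); g_max <- max(gg)
  m <- params$mean_inlet_velocity; p <- params$peak_inlet_velocity
  v <- m + (p - m) * (.waveform_shape(u) - g_mean) / (g_max - g_mean)
  if (min(m + (p - m) * (gg - g_mean) / (g_max - g_mean)) < 0)
    stop("parameter: waveform renormalization yields negative velocities")
  v
}

# ---- rheology and Poiseuille ------------------------------------------------

#' Carreau shear-thinning blood viscosity
#'
#' \deqn{\mu_{eff} = \mu_\infty + (\mu_0 - \mu_\infty)
#'   [1 + (\lambda \dot\gamma)^2]^{(n-1)/2}.}
#'
#' @param shear_rate shear rate in 1/s (vectorized, `>= 0`).
#' @param params a [flow_params()] object.
#' @return Effective viscosity in Pa s.
#' @export
carreau_viscosity <- function(shear_rate, params = flow_params()) {
  stopifnot(all(shear_rate >= 0))
  params$mu_inf + (params$mu0 - params$mu_inf) *
    (1 + (params$lambda_relax * shear_rate)^2)^((params$n_index - 1) / 2)
}

#' Poiseuille wall shear stress
#'
#' Fully developed laminar pipe flow: `tau = 4 mu U / R` with the radius
#' converted from mm to metres internally.
#'
#' @param mean_velocity cross-section mean velocity, m/s.
#' @param radius lumen radius, mm (> 0).
#' @param viscosity dynamic viscosity, Pa s.
#' @return Wall shear stress in Pa.
#' @export
poiseuille_wss <- function(mean_velocity, radius, viscosity = 0.0035) {
  if (any(radius <= 0)) stop("domain: radius must be positive")
  4 * viscosity * mean_velocity / (radius * 1e-3)
}

# ---- quasi-1D WSS oracle ----------------------------------------------------

#' Reduced-order ground-truth WSS field
#'
#' A quasi-one-dimensional hemodynamic stand-in for full CFD. The axial
#' backbone is the Poiseuille stress of the local mean velocity obtained by
#' mass conservation, `tau_i = 4 mu_eff U(s) / R_eq(s)` with
#' `U(s) = Q / A(s)` and `Q` fixed by the mean inlet velocity and the nominal
#' area; the effective viscosity is evaluated at the local Poiseuille wall
#' shear rate `4 U / R`. The backbone is modulated circumferentially by
#' (i) the inverse in-plane wall distance from the section centroid
#' (normalized to ring mean 1; captures oval compression along the minor
#' axis), (ii) an eccentric asymmetry factor peaked along the lesion offset
#' direction, and (iii) a curvature factor
#' `1 + c_kappa * kappa_i * R_i * cos(theta - theta_curv)`. Downstream of
#' each throat a decaying low-WSS wake sector is carved out (exponential
#' recovery length proportional to the throat diameter; ring-wide for
#' concentric lesions, centred on the wide side for eccentric ones).
#' Optional seeded smooth multiplicative noise; all values clipped at 0.
#'
#' @param lattice a `surface_lattice` (full axial extent).
#' @param params a [flow_params()] object.
#' @param seed integer seed for the noise field (ignored when
#'   `noise_sd = 0`).
#' @param noise_sd relative sd of the smooth multiplicative noise
#'   (default 0).
#' @param rheology `"carreau"` (default) or `"newtonian"`.
#' @param mu_newtonian viscosity used in Newtonian mode, Pa s.
#' @param curvature_gain `c_kappa` of the curvature modulation (default 0.5).
#' @param eccentric_gain gain of the eccentric asymmetry factor (default 0.8).
#' @param wake_depth relative depth of the post-stenotic wake (default 0.6).
#' @param wake_recovery recovery length as a multiple of the throat diameter
#'   (default 6).
#' @param wake_concentration angular concentration of the eccentric wake
#'   sector (von Mises kappa, default 2).
#' @param crop margin in mm excluded at each end of the analysis window
#'   (default 5; set 0 to keep the full lattice).
#' @return A `wss_field`: `values` (n_kept x n_theta, Pa), `station_s`,
#'   `station_index`, `n_theta`.
#' @export
oracle_wss_field <- function(lattice, params = flow_params(), seed = NULL,
                             noise_sd = 0,
                             rheology = c("carreau", "newtonian"),
                             mu_newtonian = 0.0035,
                             curvature_gain = 0.5, eccentric_gain = 0.8,
                             wake_depth = 0.6, wake_recovery = 6,
                             wake_concentration = 2, crop = 5) {
  stopifnot(inherits(lattice, "surface_lattice"))
  rheology <- match.arg(rheology)
  n <- lattice$n_axial; m <- lattice$n_theta
  prof <- lattice$profile
  A <- lattice$station_area                      # mm^2
  A0 <- pi * attr(prof, "nominal_radius")^2
  U <- params$mean_inlet_velocity * A0 / A       # mass conservation, m/s
  R_eq <- sqrt(A / pi)                           # mm
  gamma_w <- 4 * U / (R_eq * 1e-3)               # Poiseuille wall shear rate
  mu_eff <- if (rheology == "carreau")
    carreau_viscosity(gamma_w, params) else rep(mu_newtonian, n)
  tau_axial <- 4 * mu_eff * U / (R_eq * 1e-3)    # Pa

  theta <- 2 * pi * (seq_len(m) - 1L) / m
  fr <- lattice$frames
  cxyz <- lattice$centerline$xyz
  wss <- matrix(0, n, m)
  # curvature direction (principal normal) expressed in the section frame
  h <- lattice$station_s[2] - lattice$station_s[1]
  acc <- .fd_mat(.fd_mat(cxyz, h), h)
  for (i in seq_len(n)) {
    rel <- sweep(matrix(lattice$node_xyz[i, , ], m, 3L), 2L, cxyz[i, ])
    u2 <- rel %*% fr$normal[i, ]
    v2 <- rel %*% fr$binormal[i, ]
    cx <- mean(u2); cy <- mean(v2)               # section centroid (in-plane)
    dist <- sqrt((u2 - cx)^2 + (v2 - cy)^2)
    modi <- (1 / dist) / mean(1 / dist)
    if (prof$off[i] > 0)
      modi <- modi * (1 + eccentric_gain * (prof$off[i] / R_eq[i]) *
                        cos(theta - prof$off_angle[i]))
    ka <- lattice$station_curvature[i]
    if (ka > 1e-9) {
      an <- sum(acc[i, ] * fr$normal[i, ]); ab <- sum(acc[i, ] * fr$binormal[i, ])
      th_c <- atan2(ab, an)
      modi <- modi * (1 + curvature_gain * ka * R_eq[i] * cos(theta - th_c))
    }
    wss[i, ] <- tau_axial[i] * modi
  }

  # post-stenotic wakes
  throats <- which(diff(sign(diff(A))) > 0) + 1L
  throats <- throats[A[throats] < 0.98 * A0]
  s <- lattice$station_s
  for (it in throats) {
    D_t <- 2 * R_eq[it]
    L_rec <- wake_recovery * D_t
    half_ext <- max(s[it] - s[max(which(A[1:it] >= 0.999 * A0), 1L)], h)
    ds <- s - s[it]
    ramp <- pmin(1, pmax(0, ds / half_ext))
    decay <- wake_depth * ramp * exp(-pmax(ds, 0) / L_rec)
    sector <- if (prof$off[it] > 0)
      exp(wake_concentration * (cos(theta - prof$off_angle[it] - pi) - 1))
    else rep(1, m)
    wss <- wss * (1 - outer(decay, sector))
  }

  if (noise_sd > 0) {
    wss <- wss * (1 + noise_sd * smooth_noise_field(n, m, seed))
  }
  wss[wss < 0] <- 0

  keep <- crop_station_indices(n, s, crop)
  new_wss_field(wss[keep, , drop = FALSE], s[keep], keep, m)
}

# smooth random field on the lattice: low-order Fourier modes, unit sd
smooth_noise_field <- function(n, m, seed = NULL) {
  with_seed(seed, {
    u <- seq(0, 1, length.out = n)
    th <- 2 * pi * (seq_len(m) - 1L) / m
    f <- matrix(0, n, m)
    for (p in 0:3) for (q in 0:2) {
      if (p == 0 && q == 0) next
      f <- f + rnorm(1) * outer(cos(2 * pi * p * u + runif(1, 0, 2 * pi)),
                                cos(q * th + runif(1, 0, 2 * pi)))
    }
    f / sd(as.vector(f))
  })
}

#' Analysis-window station indices
#'
#' Indices of the stations kept after excluding `margin` mm transition zones
#' at the inlet and outlet (e.g. 640 stations over 80 mm with a 5 mm margin
#' keep exactly 560 stations).
#'
#' @param n_axial number of stations.
#' @param station_s arc coordinates (mm).
#' @param margin excluded length at each end, mm.
#' @return Integer vector of kept station indices.
#' @export
crop_station_indices <- function(n_axial, station_s, margin = 5) {
  if (margin <= 0) return(seq_len(n_axial))
  h <- station_s[2] - station_s[1]
  k <- round(margin / h)
  seq.int(k + 1L, n_axial - k)
}

# ---- WSS field container ----------------------------------------------------

#' Construct a WSS field on the cropped analysis lattice
#'
#' @param values numeric matrix (n_kept x n_theta) of WSS magnitudes, Pa,
#'   all finite and non-negative.
#' @param station_s arc coordinates of the kept stations, mm.
#' @param station_index indices of the kept stations in the full lattice.
#' @param n_theta circumferential resolution.
#' @return An object of class `wss_field`.
#' @export
new_wss_field <- function(values, station_s, station_index, n_theta) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("invalid: WSS values must be finite")
  if (any(values < 0)) stop("invalid: WSS values must be non-negative")
  structure(list(values = values, station_s = station_s,
                 station_index = station_index, n_theta = as.integer(n_theta)),
            class = "wss_field")
}

#' @export
print.wss_field <- function(x, ...) {
  cat(sprintf("<wss_field> %d x %d nodes, %.2f-%.2f Pa\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Write / read a WSS field as flat CSV
#'
#' Columns `i, k, s_mm, wss_pa` (station index within the crop, sector,
#' arc coordinate, magnitude); the round trip is exact.
#'
#' @param field a `wss_field`.
#' @param path output file.
#' @return `write_wss_csv` the path invisibly; `read_wss_csv` a `wss_field`.
#' @export
write_wss_csv <- function(field, path) {
  n <- nrow(field$values); m <- ncol(field$values)
  df <- data.frame(i = rep(seq_len(n), each = m),
                   k = rep(seq_len(m), n),
                   station_index = rep(field$station_index, each = m),
                   s_mm = rep(field$station_s, each = m),
                   wss_pa = as.vector(t(field$values)))
  write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_wss_csv
#' @export
read_wss_csv <- function(path) {
  df <- read.csv(path)
  n <- max(df$i); m <- max(df$k)
  vals <- matrix(df$wss_pa[order(df$i, df$k)], n, m, byrow = TRUE)
  new_wss_field(vals, unique(df$s_mm[order(df$i)]),
                unique(df$station_index[order(df$i)]), m)
}
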