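# ---- grid presets and cohort synthesis --------------------------------------

#' Lattice grid presets
#'
#' `full`: the full-resolution 640 axial stations x 40 sectors over 80 mm, 5 mm crop margins
#' (560 kept stations). `desk`: 160 x 20 over the same length (140 kept), a
#' reduced grid on which the full pipeline runs in minutes on one CPU.
#'
#' @param name `"full"` or `"desk"`.
#' @return list with `n_axial`, `n_theta`, `length`, `margin`, `n_kept`.
#' @export
grid_preset <- function(name = c("desk", "full")) {
  name <- match.arg(name)
  g <- switch(name,
    full  = list(n_axial = 640L, n_theta = 40L, length = 80, margin = 5),
    desk  = list(n_axial = 160L, n_theta = 20L, length = 80, margin = 5))
  h <- g$length / (g$n_axial - 1L)
  g$n_kept <- g$n_axial - 2L * round(g$margin / h)
  g$name <- name
  g
}

#' Assemble a WSS dataset
#' @param samples list of samples, each a list with `tensor`, `target`
#'   (`wss_field`), `graph` (`vessel_graph`), and optional metadata
#'   (`specs`, `template`, `seed`).
#' @param preset the [grid_preset()] used.
#' @return object of class `wss_dataset`.
#' @export
make_wss_dataset <- function(samples, preset = grid_preset("desk")) {
  structure(list(samples = samples, preset = preset,
                 n_models = length(samples)), class = "wss_dataset")
}

#' @export
print.wss_dataset <- function(x, ...) {
  cat(sprintf("<wss_dataset> %d models on the %s grid (%d x %d kept)\n",
              x$n_models, x$preset$name, x$preset$n_kept, x$preset$n_theta))
  invisible(x)
}

#' @export
length.wss_dataset <- function(x) x$n_models

.bounds_cache <- new.env(parent = emptyenv())

cached_descriptor_bounds <- function() {
  if (is.null(.bounds_cache$b)) .bounds_cache$b <- default_descriptor_bounds()
  .bounds_cache$b
}

#' Synthesize one stenotic vessel model
#'
#' Template selection, descriptor-constrained centerline synthesis, lesion
#' placement (1 or 2 focal stenoses of random morphology, severity,
#' position, eccentricity and orientation), lattice construction, oracle
#' WSS, feature tensor and vessel graph — fully determined by `seed`.
#'
#' @param seed integer seed.
#' @param preset a [grid_preset()].
#' @param params a [flow_params()].
#' @param amplitude centerline deformation amplitude, mm (default 1).
#' @param dual_fraction probability of a second lesion (default 0.25).
#' @param noise_sd oracle smooth-noise level (default 0.05).
#' @param severity optional fixed severity label or AR value for all lesions
#'   (default `NULL`: AR uniform in [0.1, 0.9]).
#' @param morphology optional fixed morphology class (default random).
#' @param spatial_radius graph proximity threshold, mm.
#' @return A sample list (`tensor`, `target`, `graph`, `lattice`, `specs`,
#'   `template`, `seed`).
#' @export
synthesize_model <- function(seed, preset = grid_preset("desk"),
                             params = flow_params(), amplitude = 1,
                             dual_fraction = 0.25, noise_sd = 0.05,
                             severity = NULL, morphology = NULL,
                             spatial_radius = 2.5 * preset$length /
                               (preset$n_axial - 1)) {
  geo <- synthesize_geometry(seed, preset, amplitude = amplitude,
                             dual_fraction = dual_fraction,
                             severity = severity, morphology = morphology)
  fld <- oracle_wss_field(geo$lattice, params, seed = geo$oracle_seed,
                          noise_sd = noise_sd, crop = preset$margin)
  tx <- build_feature_tensor(geo$lattice, margin = preset$margin)
  gr <- build_graph(geo$lattice, tx, spatial_radius = spatial_radius)
  list(tensor = tx, target = fld, graph = gr, lattice = geo$lattice,
       specs = geo$specs, template = geo$template, seed = seed)
}

#' @rdname synthesize_model
#' @details `synthesize_geometry` performs only the geometric part
#'   (template draw, centerline synthesis, lesion placement, lattice) and
#'   additionally draws the `oracle_seed` used for the oracle's noise, so
#'   the geometry and WSS stages can run separately yet reproducibly.
#' @export
synthesize_geometry <- function(seed, preset = grid_preset("desk"),
                                amplitude = 1, dual_fraction = 0.25,
                                severity = NULL, morphology = NULL) {
  with_seed(seed, {
    kind <- sample(c("straight", "single_bend", "s_bend", "helical"), 1L)
    cl <- synthesize_centerline(make_template_centerline(kind),
                                amplitude = amplitude, seed = NULL,
                                bounds = cached_descriptor_bounds(),
                                n = preset$n_axial,
                                target_length = preset$length)
    n_lesions <- 1L + (runif(1) < dual_fraction)
    ar <- if (is.null(severity)) "random" else severity
    mo <- if (is.null(morphology)) "random" else morphology
    specs <- list()
    for (attempt in 1:50) {
      specs <- lapply(seq_len(n_lesions), function(j)
        make_stenosis_spec(morphology = mo, area_ratio = ar,
                           position = "random", seed = NULL))
      if (n_lesions == 1L) break
      pos <- vapply(specs, `[[`, numeric(1), "position")
      ext <- max(vapply(specs, `[[`, numeric(1), "axial_extent"))
      if (abs(diff(pos)) >= ext) break
    }
    prof <- apply_stenosis(cl, specs)
    lat <- build_surface(cl, prof, preset$n_theta)
    oracle_seed <- sample.int(.Machine$integer.max - 1L, 1L)
    list(lattice = lat, specs = specs, template = kind,
         oracle_seed = oracle_seed, seed = seed)
  })
}

#' Generate a cohort of synthetic stenotic vessels
#'
#' @param n_models cohort size.
#' @param preset a [grid_preset()] (or its name).
#' @param seed master seed; per-model seeds are drawn from it, so the cohort
#'   is reproducible end to end.
#' @param ... forwarded to [synthesize_model()].
#' @return A `wss_dataset`.
#' @export
generate_wss_cohort <- function(n_models, preset = grid_preset("desk"),
                                seed = 1L, ...) {
  if (is.character(preset)) preset <- grid_preset(preset)
  model_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                            n_models))
  samples <- lapply(model_seeds, synthesize_model, preset = preset, ...)
  make_wss_dataset(samples, preset)
}
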