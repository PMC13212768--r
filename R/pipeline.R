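# ---- pipeline configuration -------------------------------------------------

#' End-to-end pipeline configuration
#'
#' One config drives the five stages generate -> oracle -> encode -> train
#' -> evaluate. Each stage writes under `out_root`, records the config hash,
#' and refuses to resume on top of outputs produced under a different
#' config.
#'
#' @param preset grid preset name (`"desk"` or `"full"`).
#' @param cohort_size number of vessel models.
#' @param seed global seed; propagates to every stochastic stage.
#' @param out_root output directory root.
#' @param model_kinds surrogate kinds to train/evaluate.
#' @param morphology_mix named fractions over the four morphology classes
#'   (default equal; must sum to 1).
#' @param severity optional fixed severity (`"mild"/"moderate"/"severe"` or
#'   an AR value) applied to every lesion; default `NULL` (AR uniform in
#'   \[0.1, 0.9\]).
#' @param dual_fraction probability of a second lesion (default 0.25).
#' @param amplitude centerline deformation amplitude, mm.
#' @param noise_sd oracle smooth-noise level.
#' @param flow a [flow_params()] list.
#' @param train a [train_config()]; its `seed`/`split` are used as given.
#' @param max_epochs named per-kind epoch caps (default desk budgets).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = "desk", cohort_size = 20L, seed = 1L,
                            out_root = file.path(tempdir(), "stenowss_run"),
                            model_kinds = c("pignn", "unet", "mlp"),
                            morphology_mix = NULL, severity = NULL,
                            dual_fraction = 0.25, amplitude = 1,
                            noise_sd = 0.05, flow = flow_params(),
                            train = train_config(split = c(0.6, 0.2, 0.2)),
                            max_epochs = c(pignn = 20L, unet = 8L,
                                           mlp = 200L)) {
  if (is.null(morphology_mix)) {
    morphology_mix <- rep(0.25, 4)
    names(morphology_mix) <- stenosis_morphologies()
  }
  if (abs(sum(morphology_mix) - 1) > 1e-9)
    stop("schema: morphology_mix must sum to 1")
  if (!all(names(morphology_mix) %in% stenosis_morphologies()))
    stop("schema: unknown morphology class in morphology_mix")
  model_kinds <- match.arg(model_kinds, c("pignn", "unet", "mlp"),
                           several.ok = TRUE)
  structure(list(preset = grid_preset(preset), cohort_size = cohort_size,
                 seed = seed, out_root = out_root,
                 model_kinds = model_kinds,
                 morphology_mix = morphology_mix, severity = severity,
                 dual_fraction = dual_fraction, amplitude = amplitude,
                 noise_sd = noise_sd, flow = flow, train = train,
                 max_epochs = max_epochs),
            class = "pipeline_config")
}

#' Read / write a pipeline config as YAML
#'
#' The YAML document holds the scalar fields of [pipeline_config()]
#' (nested `flow` and `train` blocks override their defaults field by
#' field).
#'
#' @param path YAML file.
#' @return `read_pipeline_config` a `pipeline_config`;
#'   `write_pipeline_config` the path invisibly.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  flow <- do.call(flow_params, y$flow %||% list())
  tr_args <- y$train %||% list()
  if (!is.null(tr_args$split)) tr_args$split <- as.numeric(tr_args$split)
  train <- do.call(train_config, tr_args)
  args <- y[setdiff(names(y), c("flow", "train"))]
  if (!is.null(args$morphology_mix))
    args$morphology_mix <- unlist(args$morphology_mix)
  if (!is.null(args$max_epochs)) args$max_epochs <- unlist(args$max_epochs)
  if (!is.null(args$model_kinds)) args$model_kinds <- unlist(args$model_kinds)
  do.call(pipeline_config, c(args, list(flow = flow, train = train)))
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  y <- list(preset = config$preset$name, cohort_size = config$cohort_size,
            seed = config$seed, out_root = config$out_root,
            model_kinds = as.list(config$model_kinds),
            morphology_mix = as.list(config$morphology_mix),
            severity = config$severity,
            dual_fraction = config$dual_fraction,
            amplitude = config$amplitude, noise_sd = config$noise_sd,
            max_epochs = as.list(config$max_epochs))
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hash of the configuration fields that determine stage outputs
config_hash <- function(config) {
  key <- config[setdiff(names(config), "out_root")]
  rlang::hash(key)
}

stage_dir <- function(config, stage) file.path(config$out_root, stage)

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

write_stage_marker <- function(config, stage, extra = list()) {
  jsonlite::write_json(
    c(list(stage = stage, config_hash = config_hash(config)), extra),
    file.path(stage_dir(config, stage), "stage.json"), auto_unbox = TRUE)
}

check_upstream <- function(config, stage) {
  marker <- file.path(stage_dir(config, stage), "stage.json")
  if (!file.exists(marker))
    stop(sprintf("missing upstream artifact: run stage '%s' first", stage))
  info <- jsonlite::read_json(marker)
  if (!identical(info$config_hash, config_hash(config)))
    stop(sprintf(
      "stage '%s' was produced under a different config (hash %s != %s); refusing mixed-config resumption",
      stage, info$config_hash, config_hash(config)))
  invisible(TRUE)
}

stage_done <- function(config, stage) {
  marker <- file.path(stage_dir(config, stage), "stage.json")
  file.exists(marker) &&
    identical(jsonlite::read_json(marker)$config_hash, config_hash(config))
}

# deterministic per-model draws shared by the generate stage
cohort_plan <- function(config) {
  n <- config$cohort_size
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1L, n))
  counts <- floor(config$morphology_mix * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    o <- order(config$morphology_mix * n - counts, decreasing = TRUE)
    counts[o[seq_len(rem)]] <- counts[o[seq_len(rem)]] + 1L
  }
  morphs <- rep(names(counts), counts)
  morphs <- with_seed(config$seed + 1L, sample(morphs))
  data.frame(model = seq_len(n), seed = seeds, morphology = morphs,
             stringsAsFactors = FALSE)
}

# ---- stages -----------------------------------------------------------------

#' Pipeline stages
#'
#' `cmd_generate` synthesizes the cohort geometry (STL walls, VTP
#' centerlines, CSV node tables, lattice archives, spec manifest);
#' `cmd_oracle` computes the reduced-order ground-truth WSS fields;
#' `cmd_encode` builds the feature tensors and vessel graphs and assembles
#' the dataset; `cmd_train` trains the configured surrogates;
#' `cmd_evaluate` writes per-scenario metric tables (concentric /
#' eccentric / all) and a report bundle for the first test case of each
#' kind. Every stage is deterministic given the config and seed, records
#' the config hash, skips work that is already up to date, and refuses to
#' resume over outputs from a different config.
#'
#' @param config a [pipeline_config()].
#' @return The stage output directory, invisibly.
#' @export
cmd_generate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir <- stage_dir(config, "generate")
  if (stage_done(config, "generate")) {
    log_stage("generate", "up to date (hash %s)", config_hash(config))
    return(invisible(dir))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  plan <- cohort_plan(config)
  log_stage("generate", "synthesizing %d models (hash %s)",
            nrow(plan), config_hash(config))
  rows <- list()
  for (i in plan$model) {
    geo <- synthesize_geometry(plan$seed[i], config$preset,
                               amplitude = config$amplitude,
                               dual_fraction = config$dual_fraction,
                               severity = config$severity,
                               morphology = plan$morphology[i])
    mdir <- file.path(dir, sprintf("model_%04d", i))
    dir.create(mdir, showWarnings = FALSE)
    export_geometry(geo$lattice,
                    stl_path = file.path(mdir, "surface.stl"),
                    vtp_path = file.path(mdir, "centerline.vtp"),
                    csv_path = file.path(mdir, "nodes.csv"))
    saveRDS(geo, file.path(mdir, "geometry.rds"))
    for (j in seq_along(geo$specs)) {
      sp <- geo$specs[[j]]
      rows[[length(rows) + 1L]] <- data.frame(
        model = i, seed = plan$seed[i], template = geo$template,
        lesion = j, n_lesions = length(geo$specs),
        morphology = sp$morphology, area_ratio = sp$area_ratio,
        position = sp$position, eccentric_distance = sp$eccentric_distance,
        orientation = sp$orientation, semi_major = sp$semi_major,
        semi_minor = sp$semi_minor, axial_extent = sp$axial_extent)
    }
  }
  write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
            row.names = FALSE)
  write_stage_marker(config, "generate", list(n_models = nrow(plan)))
  invisible(dir)
}

#' @rdname cmd_generate
#' @export
cmd_oracle <- function(config) {
  check_upstream(config, "generate")
  dir <- stage_dir(config, "oracle")
  if (stage_done(config, "oracle")) {
    log_stage("oracle", "up to date")
    return(invisible(dir))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gdir <- stage_dir(config, "generate")
  models <- sort(list.files(gdir, pattern = "^model_"))
  log_stage("oracle", "computing %d WSS fields", length(models))
  for (md in models) {
    geo <- readRDS(file.path(gdir, md, "geometry.rds"))
    fld <- oracle_wss_field(geo$lattice, config$flow,
                            seed = geo$oracle_seed,
                            noise_sd = config$noise_sd,
                            crop = config$preset$margin)
    saveRDS(fld, file.path(dir, paste0(md, "_wss.rds")))
    write_wss_csv(fld, file.path(dir, paste0(md, "_wss.csv")))
  }
  write_stage_marker(config, "oracle")
  invisible(dir)
}

#' @rdname cmd_generate
#' @export
cmd_encode <- function(config) {
  check_upstream(config, "generate")
  check_upstream(config, "oracle")
  dir <- stage_dir(config, "encode")
  if (stage_done(config, "encode")) {
    log_stage("encode", "up to date")
    return(invisible(dir))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gdir <- stage_dir(config, "generate")
  odir <- stage_dir(config, "oracle")
  models <- sort(list.files(gdir, pattern = "^model_"))
  log_stage("encode", "building tensors/graphs for %d models",
            length(models))
  radius <- 2.5 * config$preset$length / (config$preset$n_axial - 1)
  samples <- vector("list", length(models))
  for (k in seq_along(models)) {
    geo <- readRDS(file.path(gdir, models[k], "geometry.rds"))
    fld <- readRDS(file.path(odir, paste0(models[k], "_wss.rds")))
    tx <- build_feature_tensor(geo$lattice, margin = config$preset$margin)
    gr <- build_graph(geo$lattice, tx, spatial_radius = radius)
    samples[[k]] <- list(tensor = tx, target = fld, graph = gr,
                         specs = geo$specs, template = geo$template,
                         seed = geo$seed)
  }
  ds <- make_wss_dataset(samples, config$preset)
  saveRDS(ds, file.path(dir, "dataset.rds"))
  write_stage_marker(config, "encode",
                     list(tensor_dims = dim(samples[[1]]$tensor)))
  invisible(dir)
}

#' @rdname cmd_generate
#' @export
cmd_train <- function(config) {
  check_upstream(config, "encode")
  dir <- stage_dir(config, "train")
  if (stage_done(config, "train")) {
    log_stage("train", "up to date")
    return(invisible(dir))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- readRDS(file.path(stage_dir(config, "encode"), "dataset.rds"))
  for (kind in config$model_kinds) {
    log_stage("train", "training %s", kind)
    cfg <- config$train
    cfg$seed <- config$seed
    cfg$max_epochs <- unname(config$max_epochs[kind] %||% cfg$max_epochs)
    fit <- train_surrogate(ds, kind, cfg)
    saveRDS(fit, file.path(dir, paste0(kind, "_fit.rds")))
    write.csv(fit$history, file.path(dir, paste0(kind, "_history.csv")),
              row.names = FALSE)
  }
  write_stage_marker(config, "train")
  invisible(dir)
}

#' @rdname cmd_generate
#' @export
cmd_evaluate <- function(config) {
  check_upstream(config, "encode")
  check_upstream(config, "train")
  dir <- stage_dir(config, "evaluate")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- readRDS(file.path(stage_dir(config, "encode"), "dataset.rds"))
  tdir <- stage_dir(config, "train")
  all_rows <- list()
  for (kind in config$model_kinds) {
    fit <- readRDS(file.path(tdir, paste0(kind, "_fit.rds")))
    ev <- evaluate_surrogate(fit, ds)
    write.csv(ev$per_case, file.path(dir, paste0("metrics_", kind, ".csv")),
              row.names = FALSE)
    all_rows[[kind]] <- ev$per_case
    s <- ds$samples[[fit$split$test[1]]]
    render_report(sprintf("%s test case %d", kind, fit$split$test[1]),
                  predict_surrogate(fit, s), s$target,
                  file.path(dir, paste0("report_", kind)))
  }
  per_case <- do.call(rbind, all_rows)
  scenarios <- list(
    all = rep(TRUE, nrow(per_case)),
    concentric = grepl("^concentric", per_case$morphology),
    eccentric = grepl("^eccentric", per_case$morphology))
  for (sc in names(scenarios)) {
    sub <- per_case[scenarios[[sc]], , drop = FALSE]
    if (!nrow(sub)) next
    agg <- do.call(rbind, lapply(split(sub, sub$model), function(d)
      data.frame(model = d$model[1], n_cases = nrow(d),
                 MAE = mean(d$MAE), MdnAE = mean(d$MdnAE),
                 p75AE = mean(d$p75AE), StdError = mean(d$StdError),
                 RMSE = mean(d$RMSE), PearsonR = mean(d$PearsonR),
                 R2 = mean(d$R2))))
    write.csv(agg, file.path(dir, sprintf("table_%s.csv", sc)),
              row.names = FALSE)
  }
  write_stage_marker(config, "evaluate")
  log_stage("evaluate", "wrote metric tables for %d kinds",
            length(config$model_kinds))
  invisible(dir)
}

#' Run all pipeline stages in order
#' @param config a [pipeline_config()].
#' @return The evaluate stage directory, invisibly.
#' @export
run_pipeline <- function(config) {
  cmd_generate(config)
  cmd_oracle(config)
  cmd_encode(config)
  cmd_train(config)
  cmd_evaluate(config)
}
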