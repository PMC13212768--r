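# ---- training configuration -------------------------------------------------

#' Surrogate training configuration
#'
#' Shared optimizer policy: Adam at `lr` 1e-3, learning-rate halving on a
#' validation plateau (factor 0.5, patience 10), early stopping
#' (patience 30), at most `max_epochs` epochs with gradient accumulation
#' over mini-batches of `batch_size` models, and a seeded 80/10/10
#' train/validation/test split by default. Architecture sub-lists carry the
#' per-model hyperparameters; the defaults are sized for the desk grid.
#'
#' @param lr initial Adam learning rate (default 1e-3).
#' @param plateau_factor,plateau_patience learning-rate schedule
#'   (defaults 0.5, 10).
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (default 30).
#' @param max_epochs cap on training epochs (default 500).
#' @param batch_size gradient-accumulation batch (default 4).
#' @param split train/validation/test fractions, summing to 1.
#' @param seed master seed for split, initialization, shuffling and dropout.
#' @param verbose print per-epoch progress.
#' @param pignn,unet,mlp architecture hyperparameter lists.
#' @param physics a [physics_loss_config()] for the PI-GNN.
#' @param unet_loss a [unet_loss_config()].
#' @return list of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, plateau_factor = 0.5,
                         plateau_patience = 10L, early_stop_patience = 30L,
                         max_epochs = 500L, batch_size = 4L,
                         split = c(0.8, 0.1, 0.1), seed = 1L,
                         verbose = FALSE,
                         pignn = list(hidden = 64L, n_layers = 4L),
                         unet = list(channels = c(8L, 16L),
                                     bottleneck = 32L),
                         mlp = list(bottleneck = 128L, ch = c(8L, 16L),
                                    ae_hidden = 256L, ae_epochs = 30L,
                                    mapper_hidden = 100L, dropout = 0.2),
                         physics = physics_loss_config(),
                         unet_loss = unet_loss_config()) {
  if (abs(sum(split) - 1) > 1e-9)
    stop("configuration: split fractions must sum to 1")
  structure(list(lr = lr, plateau_factor = plateau_factor,
                 plateau_patience = plateau_patience,
                 early_stop_patience = early_stop_patience,
                 max_epochs = max_epochs, batch_size = batch_size,
                 split = split, seed = seed, verbose = verbose,
                 pignn = pignn, unet = unet, mlp = mlp,
                 physics = physics, unet_loss = unet_loss),
            class = "train_config")
}

#' Seeded train/validation/test split
#'
#' Deterministic shuffled partition: the first `round(n * split[1])` shuffled
#' indices train, the next `round(n * split[2])` validate, the rest test
#' (1000 models at 80/10/10 give exactly 800/100/100).
#'
#' @param n number of models.
#' @param split fractions summing to 1.
#' @param seed integer seed.
#' @return list with integer vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(n, split = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(split) - 1) > 1e-9)
    stop("configuration: split fractions must sum to 1")
  idx <- with_seed(seed, sample.int(n))
  n_tr <- round(n * split[1]); n_va <- round(n * split[2])
  if (n_tr < 1L || n_va < 1L || n_tr + n_va >= n)
    stop("configuration: a split partition is empty")
  list(train = idx[seq_len(n_tr)],
       val = idx[n_tr + seq_len(n_va)],
       test = idx[(n_tr + n_va + 1L):n])
}

# clamp the normalized prediction before exponentiation (numerical guard)
.Z_CLAMP <- 8

denorm_clamped <- function(z, stats) {
  zc <- pmin(pmax(z, -.Z_CLAMP), .Z_CLAMP)
  list(y = denormalize_wss(zc, stats), active = (z > -.Z_CLAMP) & (z < .Z_CLAMP))
}

# ---- shared training loop ---------------------------------------------------

#' Train a WSS surrogate
#'
#' Trains one of the three surrogates on a [make_wss_dataset()] cohort with
#' the shared optimizer policy. Targets are log-transformed and standardized
#' with statistics frozen on the training split; input features are
#' standardized per channel the same way. The PI-GNN minimizes the composite
#' physics loss (on Pa-scale fields, via the exact inverse transform); the
#' U-Net minimizes its composite loss on the normalized scale; the MLP is
#' trained in stages (input autoencoder, output autoencoder, latent mapper).
#' Best-validation weights are restored at the end.
#'
#' @param dataset a `wss_dataset` with at least 10 models.
#' @param model_kind `"pignn"`, `"unet"` or `"mlp"`.
#' @param config a [train_config()].
#' @return An object of class `wss_surrogate`: `kind`, `model`,
#'   `normalizer`, `split`, `history` (epoch, train_loss, val_loss, lr,
#'   gamma), `config`.
#' @export
train_surrogate <- function(dataset, model_kind = c("pignn", "unet", "mlp"),
                            config = train_config()) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(dataset, "wss_dataset"))
  if (length(dataset) < 10L) stop("configuration: need at least 10 models")
  sp <- split_dataset(length(dataset), config$split, config$seed)
  tr <- dataset$samples[sp$train]
  va <- dataset$samples[sp$val]

  stats <- wss_normalizer(lapply(tr, `[[`, "target"))
  Xall <- do.call(rbind, lapply(tr, function(s) tensor_to_node_matrix(s$tensor)))
  in_stats <- list(mean = colMeans(Xall), sd = pmax(apply(Xall, 2L, sd), 1e-9))
  rm(Xall)
  ztr <- lapply(tr, function(s) normalize_wss(s$target, stats))
  zva <- lapply(va, function(s) normalize_wss(s$target, stats))

  fit <- switch(model_kind,
    pignn = train_pignn(tr, va, ztr, zva, stats, in_stats, config),
    unet  = train_unet(tr, va, ztr, zva, stats, in_stats, config),
    mlp   = train_mlp(tr, va, ztr, zva, stats, in_stats, config))

  structure(list(kind = model_kind, model = fit$model,
                 normalizer = stats, split = sp, history = fit$history,
                 config = config),
            class = "wss_surrogate")
}

#' @export
print.wss_surrogate <- function(x, ...) {
  cat(sprintf("<wss_surrogate> %s, %d epochs trained, best val loss %.4g\n",
              x$kind, nrow(x$history),
              if (nrow(x$history)) min(x$history$val_loss) else NA))
  invisible(x)
}

# generic epoch loop with plateau LR, early stopping and best-weight restore;
# step_fn(params, sample_idx, epoch, lr_state) -> list(grads, loss)
# val_fn(params, epoch) -> scalar
run_epochs <- function(params, n_train, config, step_fn, val_fn,
                       gamma_fn = function(e) NA_real_) {
  st <- adam_init(params)
  lr <- config$lr
  best <- list(val = Inf, params = params)
  plateau <- 0L; stale <- 0L
  hist <- data.frame()
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n_train)
    ep_loss <- 0
    for (b0 in seq(1L, n_train, by = config$batch_size)) {
      batch <- ord[b0:min(b0 + config$batch_size - 1L, n_train)]
      acc <- NULL
      for (i in batch) {
        out <- step_fn(params, i, epoch)
        acc <- grad_add(acc, out$grads)
        ep_loss <- ep_loss + out$loss
      }
      acc <- grad_scale(acc, 1 / length(batch))
      upd <- adam_step(params, acc, st, lr = lr)
      params <- upd$params; st <- upd$state
    }
    val <- val_fn(params, epoch)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = ep_loss / n_train,
                                   val_loss = val, lr = lr,
                                   gamma = gamma_fn(epoch)))
    if (config$verbose)
      message(sprintf("epoch %3d  train %.5g  val %.5g  lr %.2g",
                      epoch, ep_loss / n_train, val, lr))
    if (val < best$val - 1e-12) {
      best <- list(val = val, params = params)
      plateau <- 0L; stale <- 0L
    } else {
      plateau <- plateau + 1L; stale <- stale + 1L
      if (plateau >= config$plateau_patience) {
        lr <- lr * config$plateau_factor
        plateau <- 0L
      }
      if (stale >= config$early_stop_patience) break
    }
  }
  list(params = best$params, history = hist)
}

# ---- per-kind trainers ------------------------------------------------------

train_pignn <- function(tr, va, ztr, zva, stats, in_stats, config) {
  arch <- config$pignn
  pcfg <- config$physics
  prep_one <- function(s) list(
    ops = list(gcn = gcn_operator(s$graph), sage = sage_operator(s$graph),
               X = standardize_features(tensor_to_node_matrix(s$tensor),
                                        in_stats)),
    phys = physics_prep(s$graph, pcfg))
  ptr <- lapply(tr, prep_one)
  pva <- lapply(va, prep_one)

  with_seed(config$seed, {
    model <- pignn_init(n_features = dim(tr[[1]]$tensor)[3],
                        hidden = arch$hidden, n_layers = arch$n_layers,
                        seed = NULL)
    model$input_stats <- in_stats

    loss_and_grad <- function(params, s, pp, epoch, want_grad = TRUE) {
      model$params <- params
      fw <- pignn_forward(s$tensor, s$graph, model, ops = pp$ops,
                          return_cache = want_grad)
      z <- if (want_grad) fw$pred else fw
      dn <- denorm_clamped(z, stats)
      pl <- physics_loss(dn$y, s$target$values, s$graph, pcfg, epoch,
                         prep = pp$phys, return_grad = want_grad)
      if (!want_grad) return(list(loss = pl$total))
      dz <- pl$grad * stats$sd * (dn$y + stats$eps_log) * dn$active
      list(grads = pignn_backward(dz, model, fw$cache), loss = pl$total)
    }
    step_fn <- function(params, i, epoch)
      loss_and_grad(params, tr[[i]], ptr[[i]], epoch)
    val_fn <- function(params, epoch)
      mean(vapply(seq_along(va), function(i)
        loss_and_grad(params, va[[i]], pva[[i]], epoch,
                      want_grad = FALSE)$loss, numeric(1)))
    out <- run_epochs(model$params, length(tr), config, step_fn, val_fn,
                      gamma_fn = function(e) gamma_schedule(e, pcfg))
    model$params <- out$params
    list(model = model, history = out$history)
  })
}

train_unet <- function(tr, va, ztr, zva, stats, in_stats, config) {
  arch <- config$unet
  shape <- dim(tr[[1]]$tensor)[1:2]
  lcfg <- config$unet_loss
  with_seed(config$seed, {
    model <- unet_init(shape, in_channels = dim(tr[[1]]$tensor)[3],
                       channels = arch$channels,
                       bottleneck = arch$bottleneck, seed = NULL)
    model$input_stats <- in_stats
    step_fn <- function(params, i, epoch) {
      model$params <- params
      fw <- unet_forward(tr[[i]]$tensor, model, train = TRUE,
                         return_cache = TRUE)
      ls <- unet_loss(fw$pred, ztr[[i]], lcfg, return_grad = TRUE)
      list(grads = unet_backward(ls$grad, model, fw$cache), loss = ls$total)
    }
    val_fn <- function(params, epoch) {
      model$params <- params
      mean(vapply(seq_along(va), function(i)
        unet_loss(unet_forward(va[[i]]$tensor, model), zva[[i]],
                  lcfg)$total, numeric(1)))
    }
    out <- run_epochs(model$params, length(tr), config, step_fn, val_fn)
    model$params <- out$params
    list(model = model, history = out$history)
  })
}

train_mlp <- function(tr, va, ztr, zva, stats, in_stats, config) {
  arch <- config$mlp
  shape <- dim(tr[[1]]$tensor)[1:2]
  C <- dim(tr[[1]]$tensor)[3]
  q <- arch$bottleneck
  Xtr <- lapply(tr, function(s)
    standardize_features(tensor_to_node_matrix(s$tensor), in_stats))
  Xva <- lapply(va, function(s)
    standardize_features(tensor_to_node_matrix(s$tensor), in_stats))
  Ztr <- do.call(rbind, lapply(ztr, flatten_field))
  Zva <- do.call(rbind, lapply(zva, flatten_field))

  with_seed(config$seed, {
    # stage 1: convolutional input autoencoder
    qin <- min(q, (shape[1] %/% 4L) * (shape[2] %/% 4L) * arch$ch[2])
    iae <- input_ae_init(shape, C, arch$ch, qin)
    st <- adam_init(iae)
    for (ep in seq_len(arch$ae_epochs)) {
      ord <- sample.int(length(Xtr))
      for (b0 in seq(1L, length(Xtr), by = config$batch_size)) {
        batch <- ord[b0:min(b0 + config$batch_size - 1L, length(Xtr))]
        acc <- NULL
        for (i in batch)
          acc <- grad_add(acc, input_ae_grad(Xtr[[i]], iae, shape,
                                             arch$ch, C)$grads)
        upd <- adam_step(iae, grad_scale(acc, 1 / length(batch)), st,
                         lr = config$lr)
        iae <- upd$params; st <- upd$state
      }
    }
    # stage 2: output (WSS) autoencoder on the normalized fields
    oae <- dense_ae_fit(Ztr, q = min(q, ncol(Ztr)), hidden = arch$ae_hidden,
                        epochs = arch$ae_epochs, lr = config$lr,
                        seed = NULL)$p
    # stage 3: latent mapper with the shared optimizer policy
    Ltr <- do.call(rbind, lapply(Xtr, function(X)
      input_ae_encode(X, iae, shape, arch$ch)))
    Lva <- do.call(rbind, lapply(Xva, function(X)
      input_ae_encode(X, iae, shape, arch$ch)))
    Ttr <- ae_encode(oae, Ztr)
    Tva <- ae_encode(oae, Zva)
    mp <- mapper_init(ncol(Ltr), ncol(Ttr), arch$mapper_hidden)
    step_fn <- function(params, i, epoch) {
      out <- mapper_grad(Ltr[i, , drop = FALSE], Ttr[i, , drop = FALSE],
                         params, dropout = arch$dropout)
      out
    }
    val_fn <- function(params, epoch)
      mean((mapper_forward(Lva, params) - Tva)^2)
    out <- run_epochs(mp, nrow(Ltr), config, step_fn, val_fn)
    bundle <- list(input_ae = iae, output_ae = oae, mapper = out$params,
                   shape = shape, ch = arch$ch, input_stats = in_stats,
                   bottleneck = q)
    list(model = bundle, history = out$history)
  })
}

# ---- prediction -------------------------------------------------------------

#' Run the desk-scale surrogate benchmark
#'
#' Generates a seeded desk-preset cohort, trains the three surrogates with
#' the desk epoch budgets (PI-GNN 20, U-Net 8, MLP 30 autoencoder + up to
#' 200 mapper epochs; one-CPU scale), and evaluates each on the held-out
#' test split.
#'
#' @param seed master seed (cohort and training).
#' @param cohort_size number of vessels (default 100).
#' @param split train/validation/test fractions (default 60/20/20).
#' @param kinds model kinds to run.
#' @return list with `pearson_r` (named vector), `evals` (per-kind
#'   [evaluate_surrogate()] results) and `dataset` size metadata.
#' @export
run_desk_benchmark <- function(seed, cohort_size = 100L,
                               split = c(0.6, 0.2, 0.2),
                               kinds = c("pignn", "unet", "mlp")) {
  ds <- generate_wss_cohort(cohort_size, "desk", seed = seed)
  evals <- list()
  for (kind in kinds) {
    cfg <- train_config(max_epochs = switch(kind, pignn = 20L, unet = 8L,
                                            200L),
                        split = split, seed = seed)
    fit <- train_surrogate(ds, kind, cfg)
    evals[[kind]] <- evaluate_surrogate(fit, ds)
  }
  list(pearson_r = vapply(evals, function(e) e$pooled$PearsonR, numeric(1)),
       evals = evals,
       n_models = cohort_size, grid = c(ds$preset$n_kept,
                                        ds$preset$n_theta))
}

#' Predict a WSS field with a trained surrogate
#'
#' Runs the surrogate forward and inverts the log-z target transform;
#' negative values are clipped to 0 Pa.
#'
#' @param fit a `wss_surrogate` from [train_surrogate()].
#' @param sample one dataset sample (list with `tensor`, `graph`, `target`).
#' @return A `wss_field` of predicted WSS in Pa.
#' @export
predict_surrogate <- function(fit, sample) {
  z <- switch(fit$kind,
    pignn = pignn_forward(sample$tensor, sample$graph, fit$model),
    unet = unet_forward(sample$tensor, fit$model),
    mlp = mlp_forward(sample$tensor, fit$model))
  y <- denorm_clamped(z, fit$normalizer)$y
  y[y < 0] <- 0
  tg <- sample$target
  new_wss_field(y, tg$station_s, tg$station_index, tg$n_theta)
}
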