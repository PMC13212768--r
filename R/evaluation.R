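# ---- metrics ----------------------------------------------------------------

as_values <- function(x) {
  if (inherits(x, "wss_field")) x$values else as.matrix(x)
}

#' Node-wise error metrics between predicted and reference WSS
#'
#' Absolute-error summaries (mean, median, 75th percentile), the standard
#' deviation of the signed errors (the "standard error of the prediction
#' error"; population convention), the root mean squared error, the Pearson
#' correlation of the node-wise scatter and its square as R^2.
#'
#' @param pred,ref `wss_field`s or numeric arrays of matching size
#'   (>= 2 nodes).
#' @return A list of class `metrics_record`: `MAE`, `MdnAE`, `p75AE`,
#'   `StdError`, `RMSE`, `PearsonR`, `R2`, `n_nodes` (Pa where
#'   dimensional).
#' @export
compute_metrics <- function(pred, ref) {
  p <- as.vector(as_values(pred)); r <- as.vector(as_values(ref))
  if (length(p) != length(r)) stop("shape: pred/ref disagree")
  if (length(p) < 2L) stop("shape: need at least 2 nodes")
  if (sd(p) == 0 || sd(r) == 0)
    stop("correlation-undefined: constant field")
  err <- p - r
  ae <- abs(err)
  R <- stats::cor(p, r)
  structure(list(
    MAE = mean(ae),
    MdnAE = stats::median(ae),
    p75AE = unname(stats::quantile(ae, 0.75)),
    StdError = sqrt(mean((err - mean(err))^2)),
    RMSE = sqrt(mean(err^2)),
    PearsonR = R, R2 = R^2, n_nodes = length(p)),
    class = "metrics_record")
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf(
    "<metrics> MAE %.3f  MdnAE %.3f  75thAE %.3f  Std %.3f  RMSE %.3f  R %.3f  R2 %.3f (n=%d)\n",
    x$MAE, x$MdnAE, x$p75AE, x$StdError, x$RMSE, x$PearsonR, x$R2,
    x$n_nodes))
  invisible(x)
}

#' Node-wise Bland-Altman agreement
#'
#' Differences `pred - ref` over all nodes; the bias is their mean and the
#' 95% limits of agreement are `bias +/- 1.96 sd` (population convention).
#'
#' @param pred,ref matching fields (>= 2 nodes).
#' @return list of class `agreement_record`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high` (Pa).
#' @export
bland_altman <- function(pred, ref) {
  p <- as.vector(as_values(pred)); r <- as.vector(as_values(ref))
  if (length(p) != length(r)) stop("shape: pred/ref disagree")
  if (length(p) < 2L) stop("shape: need at least 2 nodes")
  d <- p - r
  bias <- mean(d)
  sdd <- sqrt(mean((d - bias)^2))
  structure(list(bias = bias, sd_diff = sdd,
                 loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd),
            class = "agreement_record")
}

#' Axial mean WSS profile
#'
#' Mean over the circumferential nodes at each station, on the normalized
#' axial coordinate `l / l0` in [0, 1].
#'
#' @param field a `wss_field` or (n x m) matrix.
#' @return data.frame with `l_norm` and `wss_mean` (length n).
#' @export
axial_profile <- function(field) {
  v <- as_values(field)
  n <- nrow(v)
  data.frame(l_norm = seq(0, 1, length.out = n), wss_mean = rowMeans(v))
}

# ---- evaluation over a test split ------------------------------------------

#' Evaluate a surrogate on dataset indices
#'
#' Predicts every requested case and reports per-case metrics plus pooled
#' metrics over all nodes of all cases concatenated (per-case averages are
#' also implied by the table).
#'
#' @param fit a `wss_surrogate`.
#' @param dataset the `wss_dataset` it was trained on.
#' @param indices model indices (default: the fit's test split).
#' @return list with `per_case` (data.frame), `pooled` (`metrics_record`),
#'   `agreement` (`agreement_record` over pooled nodes).
#' @export
evaluate_surrogate <- function(fit, dataset, indices = fit$split$test) {
  preds <- list(); refs <- list(); rows <- list()
  for (j in seq_along(indices)) {
    s <- dataset$samples[[indices[j]]]
    pr <- predict_surrogate(fit, s)
    mt <- compute_metrics(pr, s$target)
    ba <- bland_altman(pr, s$target)
    rows[[j]] <- data.frame(model = fit$kind, case = indices[j],
                            morphology = s$specs[[1]]$morphology,
                            n_lesions = length(s$specs),
                            MAE = mt$MAE, MdnAE = mt$MdnAE, p75AE = mt$p75AE,
                            StdError = mt$StdError, RMSE = mt$RMSE,
                            PearsonR = mt$PearsonR, R2 = mt$R2,
                            bias = ba$bias, loa_low = ba$loa_low,
                            loa_high = ba$loa_high)
    preds[[j]] <- as.vector(pr$values)
    refs[[j]] <- as.vector(s$target$values)
  }
  pv <- unlist(preds); rv <- unlist(refs)
  list(per_case = do.call(rbind, rows),
       pooled = compute_metrics(pv, rv),
       agreement = bland_altman(pv, rv))
}

# ---- report rendering -------------------------------------------------------

#' Render the per-case evaluation report
#'
#' Writes seven artifacts to `out_dir`: unwrapped-surface heatmaps of the
#' reference, the prediction and the absolute error
#' (`heatmap_ref.png`, `heatmap_pred.png`, `heatmap_error.png`), the
#' node-wise scatter with identity line and R^2 (`scatter.png`), the
#' Bland-Altman plot with bias and limits of agreement
#' (`bland_altman.png`), the axial mean WSS profile overlay
#' (`axial_profile.png`), and the metrics table (`metrics.csv`).
#'
#' @param case a label for the case (used in titles).
#' @param pred,ref matching `wss_field`s.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the character vector of the seven written paths.
#' @export
render_report <- function(case, pred, ref, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("I/O: cannot create ", out_dir)
  P <- as_values(pred); Y <- as_values(ref)
  mt <- compute_metrics(pred, ref)
  ba <- bland_altman(pred, ref)
  paths <- file.path(out_dir, c("heatmap_ref.png", "heatmap_pred.png",
                                "heatmap_error.png", "scatter.png",
                                "bland_altman.png", "axial_profile.png",
                                "metrics.csv"))
  hm <- function(path, M, main) {
    grDevices::png(path, width = 900, height = 320)
    graphics::image(seq_len(nrow(M)), seq_len(ncol(M)), M,
                    xlab = "axial station", ylab = "sector",
                    main = main, col = grDevices::hcl.colors(64, "viridis"))
    grDevices::dev.off()
  }
  hm(paths[1], Y, sprintf("%s: reference WSS (Pa)", case))
  hm(paths[2], P, sprintf("%s: predicted WSS (Pa)", case))
  hm(paths[3], abs(P - Y), sprintf("%s: |error| (Pa)", case))

  grDevices::png(paths[4], width = 520, height = 520)
  graphics::plot(as.vector(Y), as.vector(P), pch = ".",
                 xlab = "reference WSS (Pa)", ylab = "predicted WSS (Pa)",
                 main = sprintf("%s: R2 = %.4f", case, mt$R2))
  graphics::abline(0, 1, col = "red")
  grDevices::dev.off()

  grDevices::png(paths[5], width = 520, height = 520)
  d <- as.vector(P) - as.vector(Y); a <- (as.vector(P) + as.vector(Y)) / 2
  graphics::plot(a, d, pch = ".", xlab = "mean of pair (Pa)",
                 ylab = "difference (Pa)",
                 main = sprintf("%s: bias %.2f, LoA [%.2f, %.2f]",
                                case, ba$bias, ba$loa_low, ba$loa_high))
  graphics::abline(h = c(ba$bias, ba$loa_low, ba$loa_high),
                   col = c("blue", "red", "red"), lty = c(1, 2, 2))
  grDevices::dev.off()

  grDevices::png(paths[6], width = 700, height = 420)
  pr <- axial_profile(ref); pp <- axial_profile(pred)
  graphics::plot(pr$l_norm, pr$wss_mean, type = "l",
                 xlab = "l / l0", ylab = "mean WSS (Pa)",
                 main = sprintf("%s: axial mean WSS", case))
  graphics::lines(pp$l_norm, pp$wss_mean, col = "red")
  graphics::legend("topright", c("reference", "predicted"),
                   col = c("black", "red"), lty = 1)
  grDevices::dev.off()

  write.csv(data.frame(case = case, MAE = mt$MAE, MdnAE = mt$MdnAE,
                       p75AE = mt$p75AE, StdError = mt$StdError,
                       RMSE = mt$RMSE, PearsonR = mt$PearsonR, R2 = mt$R2,
                       bias = ba$bias, loa_low = ba$loa_low,
                       loa_high = ba$loa_high),
            paths[7], row.names = FALSE)
  invisible(paths)
}
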