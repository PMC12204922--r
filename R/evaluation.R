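#' Effective (masked) image-quality metrics on the stress scale
#'
#' Computes the masked metrics between a predicted and a target field
#' render. Intensity differences are averaged over foreground pixels only
#' (each pixel contributing its channel mean), then converted to stress
#' units through the colormap span before normalization, so the normalized
#' metrics are relative to the physical stress scale:
#' \itemize{
#'   \item `EMAE` — masked mean absolute difference (Pa after conversion);
#'   \item `EMSE` — masked mean squared difference (Pa^2);
#'   \item `ERMSE` — `sqrt(EMSE)` (Pa);
#'   \item `NMAE = 100 * EMAE / max|S|`, `NRMSE = 100 * ERMSE / max|S|` (%),
#'     with `max|S|` the per-geometry maximum ground-truth stress;
#'   \item `NMSE = 100 * EMSE / max|S|` (%) — normalized by the first power
#'     of `max|S|`, the convention adopted here; set
#'     `nmse_squared_norm = TRUE` for the dimensionally consistent
#'     `EMSE / max|S|^2` variant;
#'   \item `EPSNR = 20 log10(MAX_I / sqrt(EMSE_intensity))` in dB, with
#'     `MAX_I = 1` the intensity ceiling; `+Inf` for a perfect prediction.
#' }
#'
#' @param predicted,target numeric `H x W x 3` intensity arrays in `[0, 1]`.
#' @param mask logical `H x W` foreground mask (at least one `TRUE`).
#' @param max_stress per-geometry maximum ground-truth stress `max|S|` (Pa).
#' @param span colormap scalar span (Pa per unit intensity);
#'   defaults to `max_stress` (a codec spanning `[0, max|S|]`).
#' @param max_intensity intensity ceiling `MAX_I`.
#' @param nmse_squared_norm normalize NMSE by `max|S|^2` instead.
#' @return one-row data frame with columns `EMAE`, `EMSE`, `ERMSE`, `NMAE`,
#'   `NMSE`, `NRMSE`, `EPSNR`, `n_pixels`.
#' @export
effective_metrics <- function(predicted, target, mask, max_stress,
                              span = max_stress, max_intensity = 1.0,
                              nmse_squared_norm = FALSE) {
  if (!identical(dim(predicted), dim(target)))
    stop("shape mismatch between predicted and target")
  ne <- sum(mask)
  if (ne == 0) stop("empty mask")
  if (max_stress <= 0) stop("max_stress must be positive")
  adiff <- abs(predicted - target)
  if (length(dim(adiff)) == 3L) {
    am <- (adiff[, , 1] + adiff[, , 2] + adiff[, , 3]) / 3
    sm <- (adiff[, , 1]^2 + adiff[, , 2]^2 + adiff[, , 3]^2) / 3
  } else { am <- adiff; sm <- adiff^2 }
  emae_i <- sum(am[mask]) / ne
  emse_i <- sum(sm[mask]) / ne
  emae <- emae_i * span
  emse <- emse_i * span^2
  ermse <- sqrt(emse)
  epsnr <- if (emse_i == 0) Inf else 20 * log10(max_intensity / sqrt(emse_i))
  data.frame(
    EMAE = emae, EMSE = emse, ERMSE = ermse,
    NMAE = 100 * emae / max_stress,
    NMSE = 100 * emse / if (nmse_squared_norm) max_stress^2 else max_stress,
    NRMSE = 100 * ermse / max_stress,
    EPSNR = epsnr, n_pixels = ne)
}

#' Evaluate a model on a test pair manifest
#'
#' Runs the model on every test input view, computes the per-image masked
#' metrics on the stress scale (per-geometry `max|S|` and colormap span from
#' the target view's recorded field range), and aggregates by unweighted
#' mean over test images; a per-geometry breakdown is included. `model` may
#' be an `mv_model` or any function mapping an `H x W x 3` input array to a
#' prediction array (e.g. a constant baseline).
#'
#' @param model an `mv_model` or a function.
#' @param test_pairs list of pairs from [make_pairs()].
#' @param nmse_squared_norm passed to [effective_metrics()].
#' @return object of class `mv_metric_report`: list with `per_image`,
#'   `per_geometry`, `aggregate` data frames and `counts`.
#' @export
evaluate_model <- function(model, test_pairs, nmse_squared_norm = FALSE) {
  if (!length(test_pairs)) stop("empty test manifest")
  predict_fun <- if (inherits(model, "mv_model")) {
    function(x) predict_model(model, x)[, , , 1]
  } else model
  rows <- lapply(test_pairs, function(p) {
    pred <- predict_fun(p$input$pixels)
    rg <- p$target$meta$range
    span <- rg[2] - rg[1]
    mx <- max(abs(rg))
    cbind(data.frame(id = p$id, axis = p$input$meta$axis,
                     step = p$input$meta$step_index,
                     stringsAsFactors = FALSE),
          effective_metrics(pred, p$target$pixels, p$target$mask,
                            max_stress = mx, span = span,
                            nmse_squared_norm = nmse_squared_norm))
  })
  per_image <- do.call(rbind, rows)
  mcols <- c("EMAE", "EMSE", "ERMSE", "NMAE", "NMSE", "NRMSE", "EPSNR")
  per_geometry <- do.call(rbind, lapply(split(per_image, per_image$id),
    function(g) cbind(data.frame(id = g$id[1], n_images = nrow(g)),
                      as.data.frame(as.list(colMeans(g[mcols]))))))
  rownames(per_geometry) <- NULL
  aggregate <- as.data.frame(as.list(colMeans(per_image[mcols])))
  structure(list(per_image = per_image, per_geometry = per_geometry,
                 aggregate = aggregate,
                 counts = c(images = nrow(per_image),
                            geometries = nrow(per_geometry)),
                 aggregation = "unweighted mean over test images"),
            class = "mv_metric_report")
}

#' @export
print.mv_metric_report <- function(x, ...) {
  cat(sprintf("mv_metric_report: %d images, %d geometries\n",
              x$counts["images"], x$counts["geometries"]))
  cat(sprintf("  NMAE %.3f%%  NMSE %.3f%%  NRMSE %.3f%%  EPSNR %.2f dB\n",
              x$aggregate$NMAE, x$aggregate$NMSE, x$aggregate$NRMSE,
              x$aggregate$EPSNR))
  invisible(x)
}

#' Write a metric report as CSV and JSON
#' @param report an `mv_metric_report`.
#' @param stem output path stem (writes `<stem>.csv`, `<stem>.json`).
#' @export
write_metric_report <- function(report, stem) {
  agg <- cbind(data.frame(id = "AGGREGATE", axis = NA, step = NA),
               report$aggregate,
               data.frame(n_pixels = NA))
  utils::write.csv(rbind(report$per_image, agg), paste0(stem, ".csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(aggregate = report$aggregate,
                            per_geometry = report$per_geometry,
                            counts = as.list(report$counts),
                            aggregation = report$aggregation),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(stem)
}

#' Compare metric reports from several models
#'
#' One row per model with the aggregate NMAE/NMSE/NRMSE/EPSNR columns, in
#' the given label order. All reports must have been computed on the same
#' test images.
#'
#' @param reports list of `mv_metric_report`.
#' @param labels character vector of model names.
#' @return data frame; pretty-print with [format_comparison()].
#' @export
compare_models <- function(reports, labels) {
  stopifnot(length(reports) >= 1L, length(reports) == length(labels))
  ref <- paste(reports[[1]]$per_image$id, reports[[1]]$per_image$axis,
               reports[[1]]$per_image$step)
  for (r in reports[-1]) {
    cur <- paste(r$per_image$id, r$per_image$axis, r$per_image$step)
    if (!identical(sort(ref), sort(cur)))
      stop("reports were computed on different test manifests")
  }
  out <- do.call(rbind, lapply(reports, function(r)
    r$aggregate[c("NMAE", "NMSE", "NRMSE", "EPSNR")]))
  cbind(data.frame(model = labels, stringsAsFactors = FALSE), out)
}

#' Fixed-width text rendering of a comparison table
#' @param comparison data frame from [compare_models()].
#' @export
format_comparison <- function(comparison) {
  hdr <- sprintf("%-16s %10s %10s %10s %10s", "Model", "NMAE", "NMSE",
                 "NRMSE", "EPSNR")
  rows <- vapply(seq_len(nrow(comparison)), function(i)
    sprintf("%-16s %9.3f%% %9.3f%% %9.3f%% %8.2fdB",
            comparison$model[i], comparison$NMAE[i], comparison$NMSE[i],
            comparison$NRMSE[i], comparison$EPSNR[i]), character(1))
  paste(c(hdr, rows), collapse = "\n")
}

#' Constant-mean baseline predictor
#'
#' Returns a predictor function that always outputs a constant image filled
#' with the mean foreground color of the training targets — the natural
#' no-information baseline for the surrogate.
#'
#' @param train_pairs list of training pairs from [make_pairs()].
#' @export
constant_mean_predictor <- function(train_pairs) {
  if (!length(train_pairs)) stop("no training pairs")
  sums <- c(0, 0, 0); n <- 0
  for (p in train_pairs) {
    for (ch in 1:3) sums[ch] <- sums[ch] + sum(p$target$pixels[, , ch][p$target$mask])
    n <- n + sum(p$target$mask)
  }
  mean_col <- sums / n
  function(x) {
    out <- array(0, dim(x))
    for (ch in 1:3) out[, , ch] <- mean_col[ch]
    out
  }
}
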