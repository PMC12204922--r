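#' End-to-end run configuration
#'
#' Bundles every stage configuration of the pipeline
#' (generate -> render -> split -> train -> evaluate) plus a single global
#' seed that fans out into independent per-stage seeds. The defaults mirror
#' the full-scale study design: 23 base geometries with 10 variants each,
#' 30-degree view steps rendered at 768 px and downsampled to 256 px,
#' curvature-colormap inputs, a depth-5 network and 300-epoch training with
#' patience 30. [smoke_run_config()] provides the desk-scale preset used by
#' the test suite.
#'
#' @param n_base base geometries.
#' @param variants_per_base variants per base geometry.
#' @param params_ranges sampling ranges forwarded to [build_dataset()].
#' @param wss_noise_sd pseudo-CFD noise (Pa).
#' @param n_synthetic_test synthetic geometries placed in the test set.
#' @param input_mode `"field"` (curvature colormap) or `"shaded"` (raw
#'   geometry rendering).
#' @param step_degrees view-ring increment.
#' @param render_resolution capture resolution (px).
#' @param out_resolution post-downsampling image side (px).
#' @param network an [network_config()].
#' @param train an [train_config()].
#' @param train_baseline also train a vanilla UNet of equal width for
#'   comparison.
#' @param write_images write every rendered view as PNG + JSON sidecar.
#' @param seed global seed.
#' @export
run_config <- function(n_base = 23L, variants_per_base = 10L,
                       params_ranges = list(), wss_noise_sd = 0.02,
                       n_synthetic_test = 40L,
                       input_mode = c("field", "shaded"),
                       step_degrees = 30, render_resolution = 768L,
                       out_resolution = 256L,
                       network = network_config(depth = 5L, base_filters = 32L,
                                                input_size = 256L),
                       train = train_config(),
                       train_baseline = FALSE, write_images = FALSE,
                       seed = 1L) {
  input_mode <- match.arg(input_mode)
  if (network$input_size != out_resolution)
    stop("network input_size must equal out_resolution")
  if (render_resolution %% out_resolution != 0)
    stop("out_resolution must divide render_resolution")
  structure(list(n_base = as.integer(n_base),
                 variants_per_base = as.integer(variants_per_base),
                 params_ranges = params_ranges, wss_noise_sd = wss_noise_sd,
                 n_synthetic_test = as.integer(n_synthetic_test),
                 input_mode = input_mode, step_degrees = step_degrees,
                 render_resolution = as.integer(render_resolution),
                 out_resolution = as.integer(out_resolution),
                 network = network, train = train,
                 train_baseline = train_baseline,
                 write_images = write_images, seed = as.integer(seed)),
            class = "mv_runconfig")
}

#' Desk-scale pipeline preset
#'
#' The scaled-down study conditions used for validation on one CPU:
#' 8 families x (1 base + 4 variants) = 40 synthetic geometries, 2 families
#' (10 geometries) held out for testing, 120-degree view steps (3 z views
#' plus 6 x/y augmentation views per geometry) rendered at 128 px and
#' downsampled to 64 px, a depth-3 width-8 MultiViewUNet, and short Adam
#' training with early stopping (patience 5). The learning rate is raised
#' to 2e-3: with ~200 images per epoch and a tiny network, the full-scale
#' 1e-4 rate would barely move the weights within the epoch budget.
#'
#' @param seed global seed.
#' @param max_epochs epoch cap of the short training run.
#' @param train_baseline also train the vanilla UNet baseline.
#' @export
smoke_run_config <- function(seed = 1L, max_epochs = 12L,
                             train_baseline = TRUE) {
  run_config(
    n_base = 8L, variants_per_base = 4L, n_synthetic_test = 10L,
    step_degrees = 120, render_resolution = 128L, out_resolution = 64L,
    network = network_config(depth = 3L, base_filters = 8L, input_size = 64L),
    train = train_config(learning_rate = 2e-3, max_epochs = max_epochs,
                         early_stop_patience = 5L, batch_size = 8L,
                         seed = seed),
    train_baseline = train_baseline, seed = seed)
}

#' Render the input/target view set of one geometry
#'
#' Produces matching input views (curvature colormap or shaded) and target
#' TAWSS views from identical cameras: a z-axis ring plus x/y-axis
#' augmentation rings, rendered at `render_resolution` and downsampled to
#' `out_resolution`. Colormap ranges are the per-geometry field ranges
#' recorded in the view metadata.
#'
#' @param mesh an `mv_mesh` carrying `curvature` and `tawss` fields.
#' @param config an [run_config()].
#' @param geometry_id id recorded in metadata.
#' @return list with `input` and `target` lists of `mv_view`.
#' @export
render_geometry <- function(mesh, config, geometry_id = "") {
  render_set <- function(mode, field) {
    codec <- if (mode == "field")
      colormap_codec(mesh$fields[[field]]$range) else NULL
    z <- render_views(mesh, mode = mode, field = field, codec = codec,
                      axis = "z", step_degrees = config$step_degrees,
                      resolution = config$render_resolution,
                      geometry_id = geometry_id)
    aug <- augment_axes(mesh, mode = mode, field = field, codec = codec,
                        step_degrees = config$step_degrees,
                        resolution = config$render_resolution,
                        geometry_id = geometry_id)
    lapply(c(z, aug), downsample, target = config$out_resolution)
  }
  list(input = if (config$input_mode == "field")
    render_set("field", "curvature") else render_set("shaded", NULL),
    target = render_set("field", "tawss"))
}

#' Run the full pipeline
#'
#' Executes generate -> render -> split -> train -> evaluate under one
#' global seed and writes all artifacts (manifests, optional images,
#' checkpoints, history, metric reports, comparison table, logs and the
#' resolved configuration) into `out_dir`. Rerunning with the same config
#' and seed reproduces every manifest and metric. When `train_baseline` is
#' set, a vanilla UNet of equal width and a constant-mean predictor are
#' evaluated on the same test pairs and a comparison table is produced.
#'
#' @param config an [run_config()].
#' @param out_dir run directory (created if missing).
#' @param quiet suppress progress output.
#' @return list with split, histories, metric reports, the comparison data
#'   frame and file paths.
#' @export
run_pipeline <- function(config, out_dir = tempfile("mvwss_run"),
                         quiet = TRUE) {
  stopifnot(inherits(config, "mv_runconfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run_log.jsonl")
  if (file.exists(logf)) file.remove(logf)
  yaml::write_yaml(resolved_config_list(config),
                   file.path(out_dir, "config.yaml"))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log_jsonl(logf, list(stage = name,
                         seed = stage_seed(config$seed, name),
                         elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                         units = "secs"))))
    res
  }
  log_jsonl(logf, list(event = "start", r_version = R.version.string,
                       package_version = as.character(
                         utils::packageVersion("mvwss")),
                       config_hash = config_hash(config$network),
                       global_seed = config$seed))

  ds <- stage("generate",
              build_dataset(config$n_base, config$variants_per_base,
                            config$params_ranges,
                            seed = stage_seed(config$seed, "generate"),
                            dir = file.path(out_dir, "dataset"),
                            noise_sd = config$wss_noise_sd))

  renders <- stage("render", {
    r <- lapply(ds$manifest$id, function(id)
      render_geometry(ds$meshes[[id]], config, geometry_id = id))
    names(r) <- ds$manifest$id
    if (config$write_images) {
      imgdir <- file.path(out_dir, "images")
      dir.create(imgdir, showWarnings = FALSE)
      for (id in names(r))
        for (role in c("input", "target"))
          for (v in r[[id]][[role]])
            save_view(v, file.path(imgdir, sprintf(
              "%s_%s_%s%02d%s", id, role, v$meta$axis, v$meta$step_index,
              if (isTRUE(v$meta$augmented)) "_aug" else "")))
    }
    r
  })

  split <- stage("split",
                 split_dataset(ds$manifest, config$n_synthetic_test,
                               seed = stage_seed(config$seed, "split")))
  jsonlite::write_json(list(train = split$train, test = split$test),
                       file.path(out_dir, "split.json"))

  pairs <- stage("pairs", make_pairs(split, renders))
  fam <- stats::setNames(ds$manifest$family, ds$manifest$id)

  tconf <- config$train
  tconf$seed <- stage_seed(config$seed, "train")
  model <- build_model(config$network,
                       seed = stage_seed(config$seed, "init"))
  fit <- stage("train", train_model(model, pairs$train, fam, tconf,
                                    quiet = quiet))
  utils::write.csv(fit$history, file.path(out_dir, "history_multiview.csv"),
                   row.names = FALSE)
  save_checkpoint(fit$model, file.path(out_dir, "model_multiview.rds"))

  report <- stage("evaluate", evaluate_model(fit$model, pairs$test))
  write_metric_report(report, file.path(out_dir, "metrics_multiview"))

  reports <- list(multiview = report)
  histories <- list(multiview = fit$history)
  comparison <- NULL
  if (config$train_baseline) {
    vcfg <- config$network; vcfg$mode <- "vanilla_unet"
    vmodel <- build_model(vcfg, seed = stage_seed(config$seed, "init"))
    vfit <- stage("train_vanilla", train_model(vmodel, pairs$train, fam,
                                               tconf, quiet = quiet))
    utils::write.csv(vfit$history, file.path(out_dir, "history_vanilla.csv"),
                     row.names = FALSE)
    save_checkpoint(vfit$model, file.path(out_dir, "model_vanilla.rds"))
    vreport <- stage("evaluate_vanilla", evaluate_model(vfit$model,
                                                        pairs$test))
    write_metric_report(vreport, file.path(out_dir, "metrics_vanilla"))
    creport <- evaluate_model(constant_mean_predictor(pairs$train),
                              pairs$test)
    write_metric_report(creport, file.path(out_dir, "metrics_constant"))
    reports$vanilla_unet <- vreport
    reports$constant_mean <- creport
    histories$vanilla_unet <- vfit$history
    comparison <- compare_models(reports,
                                 c("MultiViewUNet", "UNet", "ConstantMean"))
    utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
    writeLines(format_comparison(comparison),
               file.path(out_dir, "comparison.txt"))
  }
  log_jsonl(logf, list(event = "done"))
  list(out_dir = out_dir, manifest = ds$manifest, split = split,
       histories = histories, reports = reports, comparison = comparison)
}

resolved_config_list <- function(config) {
  x <- unclass(config)
  x$network <- unclass(x$network)
  x$train <- unclass(x$train)
  x
}
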