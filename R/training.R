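#' Training configuration
#'
#' Optimization settings for [train_model()]: Adam with learning rate 1e-4,
#' at most 300 epochs, early stopping on the validation loss with a patience
#' of 30 epochs and best-weights restoration, runtime random-zoom
#' augmentation of training pairs, and a family-stratified validation
#' hold-out carved from the training families.
#'
#' @param learning_rate Adam step size.
#' @param max_epochs epoch cap.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping; must be smaller than `max_epochs`.
#' @param batch_size images per optimization step.
#' @param seed master seed (shuffling, zoom, validation split).
#' @param zoom_range runtime random-zoom factor range for training pairs.
#' @param validation_fraction fraction of training families held out to
#'   monitor the validation loss, in (0, 0.5).
#' @export
train_config <- function(learning_rate = 1e-4, max_epochs = 300L,
                         early_stop_patience = 30L, batch_size = 8L,
                         seed = 1L, zoom_range = c(0.9, 1.1),
                         validation_fraction = 0.1) {
  if (early_stop_patience >= max_epochs)
    stop("early_stop_patience must be smaller than max_epochs")
  if (validation_fraction <= 0 || validation_fraction >= 0.5)
    stop("validation_fraction must lie in (0, 0.5)")
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 zoom_range = zoom_range,
                 validation_fraction = validation_fraction),
            class = "mv_trainconfig")
}

#' Split a geometry manifest into train and test partitions
#'
#' All real-flagged geometries go to the test set; `n_synthetic_test`
#' synthetic geometries join them, chosen as whole seeded-random families so
#' that no family (a base geometry plus its variants) ever spans both
#' partitions. Splitting happens at the geometry level, before any image is
#' rendered, so no rendered view of a test geometry can leak into training.
#'
#' @param manifest data frame with columns `id`, `family`, `real`.
#' @param n_synthetic_test number of synthetic geometries to place in the
#'   test set (must be reachable with whole families).
#' @param seed integer seed for the family draw.
#' @return an object of class `mv_split` with `train` and `test` id vectors.
#' @export
split_dataset <- function(manifest, n_synthetic_test, seed = 1L) {
  stopifnot(all(c("id", "family", "real") %in% names(manifest)))
  mixed <- tapply(manifest$real, manifest$family, function(r) length(unique(r)))
  if (any(mixed > 1))
    stop("a family mixes real and synthetic geometries (manifest error)")
  syn <- manifest[!manifest$real, , drop = FALSE]
  if (n_synthetic_test > nrow(syn))
    stop("n_synthetic_test exceeds the number of synthetic geometries")
  test_ids <- manifest$id[manifest$real]
  if (n_synthetic_test > 0) {
    fams <- unique(syn$family)
    ord <- with_seed(seed, sample(fams))
    sizes <- table(syn$family)[ord]
    take <- integer(0); total <- 0L
    for (f in ord) {
      if (total == n_synthetic_test) break
      if (total + sizes[[f]] > n_synthetic_test)
        stop("cannot reach n_synthetic_test = ", n_synthetic_test,
             " with whole families; choose a multiple of the family size")
      take <- c(take, f); total <- total + sizes[[f]]
    }
    if (total != n_synthetic_test)
      stop("cannot reach n_synthetic_test with whole families")
    test_ids <- c(test_ids, syn$id[syn$family %in% take])
  }
  train_ids <- setdiff(manifest$id, test_ids)
  if (!length(test_ids)) warning("empty test partition")
  structure(list(train = train_ids, test = test_ids,
                 manifest = manifest), class = "mv_split")
}

#' Pair input and target views for training and evaluation
#'
#' Each pair joins the input render (curvature colormap or shaded geometry)
#' with the target TAWSS render taken from the same camera, so their
#' silhouette masks are identical rasters. Training pairs include the
#' x/y-axis augmentation views; test pairs contain z-axis views only and
#' never an augmentation-flagged image.
#'
#' @param split an [split_dataset()] result.
#' @param renders named list: `renders[[id]]$input` and `renders[[id]]$target`
#'   are lists of `mv_view` covering the same cameras.
#' @return list with `train` and `test` lists of pairs
#'   (`id`, `input`, `target`).
#' @export
make_pairs <- function(split, renders) {
  pair_geometry <- function(id, test_only) {
    rin <- renders[[id]]$input
    rtg <- renders[[id]]$target
    if (is.null(rin) || is.null(rtg)) stop("missing renders for ", id)
    key <- function(v) paste(v$meta$axis, v$meta$step_index)
    tkeys <- vapply(rtg, key, character(1))
    out <- list()
    for (v in rin) {
      if (test_only && (v$meta$axis != "z" || isTRUE(v$meta$augmented))) next
      j <- match(key(v), tkeys)
      if (is.na(j)) stop("missing counterpart target view for ", id,
                         " (", key(v), ")")
      out[[length(out) + 1L]] <- list(id = id, input = v, target = rtg[[j]])
    }
    out
  }
  train <- do.call(c, lapply(split$train, pair_geometry, test_only = FALSE))
  test <- do.call(c, lapply(split$test, pair_geometry, test_only = TRUE))
  list(train = train, test = test)
}

#' Effective (background-masked) mean squared error
#'
#' Mean over foreground pixels — and, for multichannel images, over channels
#' — of the squared intensity difference. Background pixels contribute
#' nothing, so the loss is invariant to anything outside the geometry; with
#' an all-true mask it reduces to the plain MSE.
#'
#' @param predicted,target numeric arrays of identical shape
#'   (`H x W` or `H x W x C`).
#' @param mask logical `H x W` matrix with at least one `TRUE` pixel.
#' @return scalar loss.
#' @export
emse_loss <- function(predicted, target, mask) {
  if (!identical(dim(predicted), dim(target)))
    stop("predicted and target shapes differ")
  ne <- sum(mask)
  if (ne == 0) stop("empty mask: effective pixel count N_e is zero")
  d2 <- (predicted - target)^2
  if (length(dim(d2)) == 3L) {
    d2 <- apply(d2, c(1, 2), mean)
  }
  sum(d2[mask]) / ne
}

## ---- optimizer ------------------------------------------------------------

adam_new <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  st$v <- st$m
  st$t <- 0L
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

adam_step <- function(st, params, grads) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  corr1 <- 1 - b1^st$t; corr2 <- 1 - b2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      st$lr * (st$m[[nm]] / corr1) / (sqrt(st$v[[nm]] / corr2) + st$eps)
  }
  params
}

## ---- training loop --------------------------------------------------------

assemble_batch <- function(pairs, zoomed = NULL) {
  H <- nrow(pairs[[1]]$input$mask); W <- ncol(pairs[[1]]$input$mask)
  B <- length(pairs)
  x <- array(0, c(H, W, 3L, B)); y <- array(0, c(H, W, 3L, B))
  m <- array(0, c(H, W, 1L, B))
  for (b in seq_len(B)) {
    pin <- if (is.null(zoomed)) pairs[[b]]$input else zoomed[[b]]$input
    ptg <- if (is.null(zoomed)) pairs[[b]]$target else zoomed[[b]]$target
    x[, , , b] <- pin$pixels
    y[, , , b] <- ptg$pixels
    m[, , 1L, b] <- ptg$mask * 1
  }
  list(x = x, y = y, mask = m)
}

batch_loss <- function(model, batch, training = FALSE) {
  fw <- model_forward(model, batch$x, training = training)
  tape <- fw$tape
  loss <- ad_masked_mse(tape, fw$out, batch$y, batch$mask)
  list(fw = fw, tape = tape, loss = loss)
}

#' Train a model on paired views
#'
#' Minimizes the effective (masked) MSE with Adam. Runtime random zoom is
#' applied to training pairs only, one factor per pair shared by input and
#' target. The validation loss is monitored every epoch on a
#' family-stratified hold-out of the training families (never the test set);
#' training stops after `early_stop_patience` epochs without improvement and
#' the best-validation weights are restored. Fully deterministic for a fixed
#' config and seed.
#'
#' @param model an `mv_model` from [build_model()].
#' @param pairs list of training pairs from [make_pairs()].
#' @param families named character vector mapping geometry id to family id
#'   (used for the validation split); if `NULL`, every id is its own family.
#' @param config an [train_config()].
#' @param quiet suppress per-epoch console output.
#' @return list with the trained `model` and a `history` data frame of
#'   per-epoch train/validation loss.
#' @export
train_model <- function(model, pairs, families = NULL,
                        config = train_config(), quiet = TRUE) {
  if (!length(pairs)) stop("no training pairs")
  ids <- vapply(pairs, `[[`, character(1), "id")
  fam <- if (is.null(families)) stats::setNames(unique(ids), unique(ids))
  else families
  pfam <- unname(fam[ids])
  ufam <- unique(pfam)
  n_val_fam <- max(if (length(ufam) > 1L) 1L else 0L,
                   floor(config$validation_fraction * length(ufam)))
  val_fams <- if (n_val_fam > 0)
    with_seed(stage_seed(config$seed, "valsplit"),
              sample(ufam, n_val_fam)) else character(0)
  val_pairs <- pairs[pfam %in% val_fams]
  tr_pairs <- pairs[!(pfam %in% val_fams)]
  if (!length(tr_pairs)) { tr_pairs <- pairs; val_pairs <- list() }
  monitor_train <- length(val_pairs) == 0L
  adam <- adam_new(model$params, config$learning_rate)
  best <- list(loss = Inf, params = NULL, bn = NULL, epoch = 0L)
  wait <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  eval_loss <- function(vp) {
    if (!length(vp)) return(NA_real_)
    tot <- 0
    bs <- config$batch_size
    for (i in seq(1, length(vp), by = bs)) {
      chunk <- vp[i:min(i + bs - 1L, length(vp))]
      batch <- assemble_batch(chunk, NULL)
      bl <- batch_loss(model, batch, training = FALSE)
      tot <- tot + as.numeric(bl$loss$value) * length(chunk)
    }
    tot / length(vp)
  }
  snapshot_bn <- function() {
    bn <- lapply(ls(model$bn_state), function(k)
      list(mean = model$bn_state[[k]]$mean, var = model$bn_state[[k]]$var))
    stats::setNames(bn, ls(model$bn_state))
  }
  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(stage_seed(config$seed, paste0("shuffle", epoch)),
                     sample(length(tr_pairs)))
    ep_loss <- 0; seen <- 0L
    bs <- config$batch_size
    for (i in seq(1, length(ord), by = bs)) {
      sel <- ord[i:min(i + bs - 1L, length(ord))]
      chunk <- tr_pairs[sel]
      zoomed <- lapply(seq_along(chunk), function(b) {
        zseed <- stage_seed(config$seed,
                            sprintf("zoom_e%d_p%d", epoch, sel[b]))
        f <- with_seed(zseed, stats::runif(1, config$zoom_range[1],
                                           config$zoom_range[2]))
        list(input = random_zoom(chunk[[b]]$input, factor = f),
             target = random_zoom(chunk[[b]]$target, factor = f))
      })
      batch <- assemble_batch(chunk, zoomed)
      bl <- batch_loss(model, batch, training = TRUE)
      lv <- as.numeric(bl$loss$value)
      if (!is.finite(lv))
        stop("non-finite training loss at epoch ", epoch,
             " (batch starting at pair ", i, ")")
      ad_backward(bl$tape, bl$loss)
      grads <- lapply(bl$fw$pnodes, function(nd) nd$grad)
      model$params <- adam_step(adam, model$params, grads)
      ep_loss <- ep_loss + lv * length(sel)
      seen <- seen + length(sel)
    }
    tr_l <- ep_loss / seen
    vl <- if (monitor_train) tr_l else eval_loss(val_pairs)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = tr_l,
                                         val_loss = vl))
    if (!quiet)
      message(sprintf("epoch %3d  train %.6f  val %.6f", epoch, tr_l, vl))
    if (vl < best$loss - 1e-12) {
      best <- list(loss = vl, params = model$params, bn = snapshot_bn(),
                   epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$early_stop_patience) break
    }
  }
  if (!is.null(best$params)) {
    model$params <- best$params
    for (k in names(best$bn)) {
      model$bn_state[[k]]$mean <- best$bn[[k]]$mean
      model$bn_state[[k]]$var <- best$bn[[k]]$var
    }
  }
  list(model = model, history = history, best_epoch = best$epoch)
}
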