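#' Network configuration
#'
#' Describes a depth-`D` encoder-decoder image-to-image network. Channel
#' width at level `d` (1-indexed from the top) is `base_filters * 2^(d-1)`,
#' i.e. the width doubles after every downsampling, starting from
#' `base_filters` at the full-resolution level. `mode = "multiview"` enables
#' the full skip-connection system (full-scale inter-skips with 1x1 channel
#' reduction, sigmoid-gated intra-skips in both paths); `mode =
#' "vanilla_unet"` restricts skips to the classic same-level encoder copy,
#' recovering the plain UNet baseline.
#'
#' @param depth number of levels `D` (default 5).
#' @param base_filters channels `n` at the top level.
#' @param input_size square image side; must be divisible by `2^(depth-1)`.
#' @param in_channels,out_channels image channel counts (RGB in/out).
#' @param mode `"multiview"` or `"vanilla_unet"`.
#' @export
network_config <- function(depth = 5L, base_filters = 32L, input_size = 256L,
                           in_channels = 3L, out_channels = 3L,
                           mode = c("multiview", "vanilla_unet")) {
  mode <- match.arg(mode)
  depth <- as.integer(depth)
  if (depth < 2L) stop("depth must be >= 2")
  if (input_size %% 2^(depth - 1L) != 0L)
    stop("input_size must be divisible by 2^(depth-1) (config error)")
  structure(list(depth = depth, base_filters = as.integer(base_filters),
                 input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels), mode = mode),
            class = "mv_netconfig")
}

level_channels <- function(config, d) config$base_filters * 2L^(d - 1L)

init_conv <- function(kh, kw, cin, cout) {
  w <- array(stats::rnorm(kh * kw * cin * cout, 0,
                          sqrt(2 / (kh * kw * cin))),
             c(kh, kw, cin, cout))
  list(w = w, b = numeric(cout))
}

init_block <- function(params, prefix, cin, cout) {
  c1 <- init_conv(3L, 3L, cin, cout)
  c2 <- init_conv(3L, 3L, cout, cout)
  params[[paste0(prefix, ".conv1.w")]] <- c1$w
  params[[paste0(prefix, ".conv1.b")]] <- c1$b
  params[[paste0(prefix, ".bn1.gamma")]] <- rep(1, cout)
  params[[paste0(prefix, ".bn1.beta")]] <- rep(0, cout)
  params[[paste0(prefix, ".conv2.w")]] <- c2$w
  params[[paste0(prefix, ".conv2.b")]] <- c2$b
  params[[paste0(prefix, ".bn2.gamma")]] <- rep(1, cout)
  params[[paste0(prefix, ".bn2.beta")]] <- rep(0, cout)
  params
}

#' Build a MultiViewUNet (or vanilla UNet) model
#'
#' Constructs the parameter set of the configured network with He-normal
#' initialization, deterministically from `seed`. The returned model is a
#' plain list (`config`, `params`, `bn_state`, `structure`); run it with
#' [predict_model()] or train it with [train_model()]. `structure` records
#' the pooling/upsampling factors instantiated for every skip connection,
#' e.g. at full depth the encoder intra-skips pool by 16, 8, 4, 2 and the
#' top decoder level gathers upsampled maps by factors 2, 4, 8, 16.
#'
#' @param config an [network_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `mv_model`.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "mv_netconfig"))
  D <- config$depth
  ch <- function(d) level_channels(config, d)
  mv <- config$mode == "multiview"
  params <- list()
  with_seed(seed, {
    for (d in seq_len(D)) {
      cin <- if (d == 1L) config$in_channels
      else if (mv) ch(d - 1L) + sum(ch(seq_len(d - 1L)))
      else ch(d - 1L)
      params <- init_block(params, sprintf("enc%d", d), cin, ch(d))
    }
    if (mv) {
      for (d in seq_len(D - 1L)) {
        pc <- init_conv(1L, 1L, sum(ch(seq_len(d))), ch(d))
        params[[sprintf("inter%d.w", d)]] <- pc$w
        params[[sprintf("inter%d.b", d)]] <- pc$b
      }
    }
    for (d in rev(seq_len(D - 1L))) {
      cin <- if (mv) ch(d + 1L) + sum(ch(seq(d + 1L, D))) + ch(d)
      else ch(d + 1L) + ch(d)
      params <- init_block(params, sprintf("dec%d", d), cin, ch(d))
    }
    oc <- init_conv(1L, 1L, ch(1L), config$out_channels)
    params[["out.w"]] <- oc$w
    params[["out.b"]] <- oc$b
  })
  bn_state <- new.env(parent = emptyenv())
  for (nm in names(params)) {
    if (grepl("\\.bn[12]\\.gamma$", nm)) {
      key <- sub("\\.gamma$", "", nm)
      st <- new.env(parent = emptyenv())
      st$mean <- numeric(length(params[[nm]]))
      st$var <- rep(1, length(params[[nm]]))
      st$momentum <- 0.1
      bn_state[[key]] <- st
    }
  }
  structure_info <- list(
    encoder_intra_pool = lapply(seq_len(D), function(d)
      if (d >= 2) 2L^(d - seq_len(d - 1L)) else integer(0)),
    decoder_intra_up = lapply(seq_len(D - 1L), function(d)
      2L^(seq(d + 1L, D) - d)),
    inter_scale = lapply(seq_len(D - 1L), function(d) 2L^(d - seq_len(d))))
  structure(list(config = config, params = params, bn_state = bn_state,
                 structure = structure_info),
            class = "mv_model")
}

#' Number of trainable parameters
#' @param model an `mv_model`.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.mv_model <- function(x, ...) {
  cat(sprintf("mv_model [%s] depth=%d n=%d input=%dpx, %d parameters\n",
              x$config$mode, x$config$depth, x$config$base_filters,
              x$config$input_size, count_parameters(x)))
  invisible(x)
}

# Two 3x3 conv + BN + ReLU layers on the tape.
block_fwd <- function(tape, x, pnodes, bn_state, prefix, training) {
  h <- ad_conv2d(tape, x, pnodes[[paste0(prefix, ".conv1.w")]],
                 pnodes[[paste0(prefix, ".conv1.b")]])
  h <- ad_batchnorm(tape, h, pnodes[[paste0(prefix, ".bn1.gamma")]],
                    pnodes[[paste0(prefix, ".bn1.beta")]],
                    bn_state[[paste0(prefix, ".bn1")]], training)
  h <- ad_relu(tape, h)
  h <- ad_conv2d(tape, h, pnodes[[paste0(prefix, ".conv2.w")]],
                 pnodes[[paste0(prefix, ".conv2.b")]])
  h <- ad_batchnorm(tape, h, pnodes[[paste0(prefix, ".bn2.gamma")]],
                    pnodes[[paste0(prefix, ".bn2.beta")]],
                    bn_state[[paste0(prefix, ".bn2")]], training)
  ad_relu(tape, h)
}

# Full forward pass on a fresh tape. Returns the tape, output node and the
# named list of parameter nodes (for gradient harvesting).
model_forward <- function(model, x, training = FALSE) {
  cfg <- model$config
  D <- cfg$depth
  mv <- cfg$mode == "multiview"
  tape <- new_tape()
  pnodes <- lapply(model$params, function(p) ad_input(tape, p))
  xn <- ad_input(tape, x)
  enc <- vector("list", D)
  for (d in seq_len(D)) {
    if (d == 1L) inp <- xn
    else {
      main <- ad_maxpool(tape, enc[[d - 1L]], 2L)
      if (mv) {
        gates <- lapply(seq_len(d - 1L), function(i)
          ad_sigmoid(tape, ad_maxpool(tape, enc[[i]], 2L^(d - i))))
        inp <- ad_concat(tape, c(list(main), gates))
      } else inp <- main
    }
    enc[[d]] <- block_fwd(tape, inp, pnodes, model$bn_state,
                          sprintf("enc%d", d), training)
  }
  dec <- vector("list", D)
  dec[[D]] <- enc[[D]]
  for (d in rev(seq_len(D - 1L))) {
    main <- ad_upsample(tape, dec[[d + 1L]], 2L)
    if (mv) {
      scaled <- lapply(seq_len(d), function(i)
        if (i < d) ad_maxpool(tape, enc[[i]], 2L^(d - i)) else enc[[i]])
      finter <- ad_conv2d(tape, ad_concat(tape, scaled),
                          pnodes[[sprintf("inter%d.w", d)]],
                          pnodes[[sprintf("inter%d.b", d)]])
      gates <- lapply(seq(d + 1L, D), function(i)
        ad_sigmoid(tape, ad_upsample(tape, dec[[i]], 2L^(i - d))))
      inp <- ad_concat(tape, c(list(main), gates, list(finter)))
    } else {
      inp <- ad_concat(tape, list(main, enc[[d]]))
    }
    dec[[d]] <- block_fwd(tape, inp, pnodes, model$bn_state,
                          sprintf("dec%d", d), training)
  }
  out <- ad_sigmoid(tape, ad_conv2d(tape, dec[[1L]], pnodes[["out.w"]],
                                    pnodes[["out.b"]]))
  list(tape = tape, out = out, pnodes = pnodes, input = xn)
}

#' Run the network on a batch of images
#'
#' @param model an `mv_model`.
#' @param x numeric array `H x W x C x N` (a single `H x W x C` image is
#'   promoted to a batch of one).
#' @param training use batch statistics for normalization (TRUE) or the
#'   running moments (FALSE, the inference default).
#' @return array of the same spatial shape with values in (0, 1).
#' @export
predict_model <- function(model, x, training = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  model_forward(model, x, training = training)$out$value
}

## ---- spec-level operation wrappers ---------------------------------------
# Standalone, seed-initialized versions of the network's building blocks,
# operating on plain arrays. They exercise exactly the code paths used
# inside build_model()/model_forward().

as_batch <- function(x) { if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L); x }

#' Convolution block: two 3x3 conv + batch-norm + ReLU layers
#' @param input array `H x W x C (x N)`.
#' @param out_channels output channel count.
#' @param seed weight-initialization seed.
#' @export
conv_block <- function(input, out_channels, seed = 1L) {
  input <- as_batch(input)
  cin <- dim(input)[3]
  params <- with_seed(seed, init_block(list(), "blk", cin, out_channels))
  st <- new.env(parent = emptyenv())
  for (k in c("blk.bn1", "blk.bn2")) {
    e <- new.env(parent = emptyenv())
    e$mean <- numeric(out_channels); e$var <- rep(1, out_channels)
    e$momentum <- 0.1
    st[[k]] <- e
  }
  tape <- new_tape()
  pnodes <- lapply(params, function(p) ad_input(tape, p))
  block_fwd(tape, ad_input(tape, input), pnodes, st, "blk", TRUE)$value
}

#' Full-scale inter-skip aggregation
#'
#' Scales every encoder map from levels `1..d` to the spatial size of level
#' `d` (max pooling for shallower maps, identity at level `d`), concatenates
#' them and reduces the channel dimension with a 1x1 convolution to the
#' configured level-`d` width.
#'
#' @param encoder_maps list of arrays, level 1 (largest) first.
#' @param target_level level `d` whose size the output matches.
#' @param out_channels width of the 1x1 reduction.
#' @param seed weight-initialization seed.
#' @export
inter_skip <- function(encoder_maps, target_level, out_channels, seed = 1L) {
  encoder_maps <- lapply(encoder_maps, as_batch)
  d <- target_level
  tape <- new_tape()
  nodes <- lapply(seq_len(d), function(i) {
    nd <- ad_input(tape, encoder_maps[[i]])
    if (i < d) ad_maxpool(tape, nd, 2L^(d - i)) else nd
  })
  cat_nd <- ad_concat(tape, nodes)
  cin <- dim(cat_nd$value)[3]
  pc <- with_seed(seed, init_conv(1L, 1L, cin, out_channels))
  ad_conv2d(tape, cat_nd, ad_input(tape, pc$w), ad_input(tape, pc$b))$value
}

#' Encoder intra-skip aggregation
#'
#' The cascading encoder input at level `d`: the previous level's output max
#' pooled by 2 (the main path), concatenated with sigmoid-gated copies of
#' every previous level pooled by `2^(d-i)`, then passed through a
#' convolution block.
#'
#' @param previous_maps list of encoder outputs for levels `1..d-1`.
#' @param out_channels width of the convolution block.
#' @param seed weight-initialization seed.
#' @export
encoder_intra_skip <- function(previous_maps, out_channels, seed = 1L) {
  previous_maps <- lapply(previous_maps, as_batch)
  d <- length(previous_maps) + 1L
  if (d < 2L) stop("encoder intra-skip needs at least one previous level")
  tape <- new_tape()
  nds <- lapply(previous_maps, function(m) ad_input(tape, m))
  main <- ad_maxpool(tape, nds[[d - 1L]], 2L)
  gates <- lapply(seq_len(d - 1L), function(i)
    ad_sigmoid(tape, ad_maxpool(tape, nds[[i]], 2L^(d - i))))
  inp <- ad_concat(tape, c(list(main), gates))
  cin <- dim(inp$value)[3]
  params <- with_seed(seed, init_block(list(), "blk", cin, out_channels))
  st <- new.env(parent = emptyenv())
  for (k in c("blk.bn1", "blk.bn2")) {
    e <- new.env(parent = emptyenv())
    e$mean <- numeric(out_channels); e$var <- rep(1, out_channels)
    e$momentum <- 0.1
    st[[k]] <- e
  }
  pnodes <- lapply(params, function(p) ad_input(tape, p))
  block_fwd(tape, inp, pnodes, st, "blk", TRUE)$value
}

#' Decoder intra-skip aggregation
#'
#' The decoder input at level `d`: the next-deeper decoder output bilinearly
#' upsampled by 2 (main path), sigmoid-gated upsampled copies of every
#' deeper decoder map (factors `2^(i-d)`), and the inter-skip aggregate,
#' concatenated and passed through a convolution block.
#'
#' @param deeper_maps list of decoder outputs for levels `d+1..D`
#'   (shallowest first).
#' @param inter_features the level-`d` inter-skip aggregate array.
#' @param out_channels width of the convolution block.
#' @param seed weight-initialization seed.
#' @export
decoder_intra_skip <- function(deeper_maps, inter_features, out_channels,
                               seed = 1L) {
  deeper_maps <- lapply(deeper_maps, as_batch)
  inter_features <- as_batch(inter_features)
  tape <- new_tape()
  nds <- lapply(deeper_maps, function(m) ad_input(tape, m))
  main <- ad_upsample(tape, nds[[1L]], 2L)
  gates <- lapply(seq_along(nds), function(j)
    ad_sigmoid(tape, ad_upsample(tape, nds[[j]], 2L^j)))
  inp <- ad_concat(tape, c(list(main), gates,
                           list(ad_input(tape, inter_features))))
  cin <- dim(inp$value)[3]
  params <- with_seed(seed, init_block(list(), "blk", cin, out_channels))
  st <- new.env(parent = emptyenv())
  for (k in c("blk.bn1", "blk.bn2")) {
    e <- new.env(parent = emptyenv())
    e$mean <- numeric(out_channels); e$var <- rep(1, out_channels)
    e$momentum <- 0.1
    st[[k]] <- e
  }
  pnodes <- lapply(params, function(p) ad_input(tape, p))
  block_fwd(tape, inp, pnodes, st, "blk", TRUE)$value
}

#' Save model weights and config
#' @param model an `mv_model`.
#' @param path weights file; a `.json` config sidecar is written next to it.
#' @export
save_checkpoint <- function(model, path) {
  bn <- lapply(ls(model$bn_state), function(k)
    list(mean = model$bn_state[[k]]$mean, var = model$bn_state[[k]]$var))
  names(bn) <- ls(model$bn_state)
  saveRDS(list(params = model$params, bn = bn), path)
  cfgfile <- paste0(tools::file_path_sans_ext(path), ".json")
  cfg <- unclass(model$config)
  cfg$config_hash <- config_hash(model$config)
  jsonlite::write_json(cfg, cfgfile, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model saved with [save_checkpoint()]
#' @param path weights file path.
#' @export
load_checkpoint <- function(path) {
  cfgfile <- paste0(tools::file_path_sans_ext(path), ".json")
  cfg <- jsonlite::read_json(cfgfile, simplifyVector = TRUE)
  config <- network_config(cfg$depth, cfg$base_filters, cfg$input_size,
                           cfg$in_channels, cfg$out_channels, cfg$mode)
  if (!is.null(cfg$config_hash) && cfg$config_hash != config_hash(config))
    stop("checkpoint config hash mismatch")
  model <- build_model(config, seed = 1L)
  blob <- readRDS(path)
  stopifnot(identical(sort(names(blob$params)), sort(names(model$params))))
  model$params <- blob$params
  for (k in names(blob$bn)) {
    model$bn_state[[k]]$mean <- blob$bn[[k]]$mean
    model$bn_state[[k]]$var <- blob$bn[[k]]$var
  }
  model
}

config_hash <- function(config) {
  s <- paste(config$depth, config$base_filters, config$input_size,
             config$in_channels, config$out_channels, config$mode)
  h <- 17
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
  sprintf("%d", h)
}
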