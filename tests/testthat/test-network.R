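test_that("conv blocks preserve spatial size, set channels, stay non-negative", {
  x <- array(rnorm(64 * 64 * 3), c(64, 64, 3))
  y <- conv_block(x, 8L, seed = 2L)
  expect_equal(dim(y), c(64L, 64L, 8L, 1L))
  expect_gte(min(y), 0)
})

test_that("two stacked 3x3 convolutions have a 5x5 receptive field", {
  # gradient footprint of one output pixel through the raw conv kernels
  set.seed(4)
  x <- array(rnorm(16 * 16 * 1), c(16, 16, 1, 1))
  w1 <- array(rnorm(9), c(3, 3, 1, 1)); b <- 0
  w2 <- array(rnorm(9), c(3, 3, 1, 1))
  h <- mvwss:::.conv2d_fwd(x, w1, b)
  y <- mvwss:::.conv2d_fwd(h, w2, b)
  dy <- array(0, dim(y)); dy[8, 8, 1, 1] <- 1
  dh <- mvwss:::.conv2d_bwd(h, w2, dy)$dx
  dx <- mvwss:::.conv2d_bwd(x, w1, dh)$dx
  nz <- which(dx != 0, arr.ind = TRUE)
  expect_lte(max(abs(nz[, 1] - 8)), 2)
  expect_lte(max(abs(nz[, 2] - 8)), 2)
  expect_equal(sort(unique(nz[, 1])), 6:10)
})

test_that("inter-skip aggregation reduces to the configured width at every level", {
  n <- 4L
  maps <- lapply(1:5, function(d)
    array(rnorm(32 / 2^(d - 1) * 32 / 2^(d - 1) * n * 2^(d - 1)),
          c(32L / 2^(d - 1), 32L / 2^(d - 1), n * 2^(d - 1))))
  for (d in 1:5) {
    out <- inter_skip(maps[seq_len(d)], d, out_channels = n * 2^(d - 1))
    expect_equal(dim(out)[1:3],
                 c(32L / 2^(d - 1), 32L / 2^(d - 1), n * 2^(d - 1)))
  }
  # d = 1 degenerates to a 1x1 convolution of the single top map
  o1 <- inter_skip(maps[1], 1L, out_channels = n)
  expect_equal(dim(o1)[1:3], c(32L, 32L, n))
})

test_that("full-depth skip scale factors match the architecture design", {
  cfg <- network_config(depth = 5L, base_filters = 2L, input_size = 32L)
  mod <- build_model(cfg, seed = 1L)
  # encoder intra-skips into the bottleneck pool by 16, 8, 4, 2
  expect_equal(mod$structure$encoder_intra_pool[[5]], c(16L, 8L, 4L, 2L))
  # top decoder level gathers deeper maps upsampled by 2, 4, 8, 16
  expect_equal(mod$structure$decoder_intra_up[[1]], c(2L, 4L, 8L, 16L))
  # inter-skip scaling at level 4 pools encoder levels 1..4 by 8, 4, 2, 1
  expect_equal(mod$structure$inter_scale[[4]], c(8L, 4L, 2L, 1L))
})

test_that("encoder intra-skip gates are live and bounded", {
  maps <- list(array(rnorm(32 * 32 * 4), c(32, 32, 4)),
               array(rnorm(16 * 16 * 8), c(16, 16, 8)))
  out <- encoder_intra_skip(maps, out_channels = 16L, seed = 3L)
  expect_equal(dim(out)[1:3], c(8L, 8L, 16L))
  # zeroing the shallow (gated-only) input changes the output
  maps0 <- maps; maps0[[1]][] <- 0
  out0 <- encoder_intra_skip(maps0, out_channels = 16L, seed = 3L)
  expect_gt(sum(abs(out - out0)), 0)
  # sigmoid gating stays strictly inside (0, 1)
  tape <- mvwss:::new_tape()
  g <- mvwss:::ad_sigmoid(tape, mvwss:::ad_input(tape,
                                                 array(rnorm(64), c(4, 4, 4, 1))))
  expect_true(all(g$value > 0 & g$value < 1))
})

test_that("decoder intra-skip output matches the level size for every depth", {
  D <- 4L; n <- 2L; size <- 32L
  for (d in (D - 1L):1L) {
    deeper <- lapply((d + 1L):D, function(i)
      array(rnorm((size / 2^(i - 1))^2 * n * 2^(i - 1)),
            c(size / 2^(i - 1), size / 2^(i - 1), n * 2^(i - 1))))
    finter <- array(rnorm((size / 2^(d - 1))^2 * n * 2^(d - 1)),
                    c(size / 2^(d - 1), size / 2^(d - 1), n * 2^(d - 1)))
    out <- decoder_intra_skip(deeper, finter, out_channels = n * 2^(d - 1))
    expect_equal(dim(out)[1:2], rep(size / 2^(d - 1), 2))
  }
  # d = D - 1: exactly one gated skip, upsampled by 2
  one <- decoder_intra_skip(list(array(rnorm(8 * 8 * 4), c(8, 8, 4))),
                            array(rnorm(16 * 16 * 2), c(16, 16, 2)),
                            out_channels = 2L)
  expect_equal(dim(one)[1:2], c(16L, 16L))
})

test_that("models map images to same-shape sigmoid outputs across configs", {
  for (spec in list(list(D = 2L, s = 32L), list(D = 3L, s = 64L),
                    list(D = 5L, s = 256L))) {
    cfg <- network_config(depth = spec$D, base_filters = 2L,
                          input_size = spec$s)
    mod <- build_model(cfg, seed = 1L)
    x <- array(runif(spec$s^2 * 3), c(spec$s, spec$s, 3, 1))
    y <- predict_model(mod, x, training = TRUE)
    expect_equal(dim(y), dim(x))
    expect_true(all(y > 0 & y < 1))
  }
  expect_error(network_config(depth = 5L, input_size = 100L), "divisible")
})

test_that("encoder widths double per level from the base width", {
  cfg <- network_config(depth = 5L, base_filters = 8L, input_size = 32L)
  mod <- build_model(cfg, seed = 1L)
  widths <- vapply(1:5, function(d)
    dim(mod$params[[sprintf("enc%d.conv2.w", d)]])[4], integer(1))
  expect_equal(widths, 8L * 2L^(0:4))
})

test_that("the vanilla UNet mode has strictly fewer parameters", {
  cfg <- network_config(depth = 3L, base_filters = 8L, input_size = 64L)
  vcfg <- cfg; vcfg$mode <- "vanilla_unet"
  expect_lt(count_parameters(build_model(vcfg, seed = 1L)),
            count_parameters(build_model(cfg, seed = 1L)))
})

test_that("gradients reach every trainable tensor and one step reduces the loss", {
  cfg <- network_config(depth = 3L, base_filters = 4L, input_size = 32L)
  for (mode in c("multiview", "vanilla_unet")) {
    c2 <- cfg; c2$mode <- mode
    mod <- build_model(c2, seed = 5L)
    set.seed(8)
    x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
    y <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
    mask <- array(1, c(32, 32, 1, 2))
    fw <- mvwss:::model_forward(mod, x, training = TRUE)
    loss <- mvwss:::ad_masked_mse(fw$tape, fw$out, y, mask)
    mvwss:::ad_backward(fw$tape, loss)
    grads <- lapply(fw$pnodes, function(nd) nd$grad)
    expect_true(all(!vapply(grads, is.null, logical(1))))
    expect_true(all(vapply(grads, function(g) any(g != 0), logical(1))))
    # a small gradient step must reduce the loss on the same batch
    l0 <- as.numeric(loss$value)
    mod$params <- mapply(function(p, g) p - 1e-3 * g, mod$params, grads,
                         SIMPLIFY = FALSE)
    fw2 <- mvwss:::model_forward(mod, x, training = TRUE)
    l1 <- as.numeric(mvwss:::ad_masked_mse(fw2$tape, fw2$out, y, mask)$value)
    expect_lt(l1, l0)
  }
})

test_that("whole-model analytic gradients agree with finite differences", {
  cfg <- network_config(depth = 3L, base_filters = 2L, input_size = 16L)
  mod <- build_model(cfg, seed = 9L)
  set.seed(10)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  y <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  mask <- array(1, c(16, 16, 1, 1))
  lossfun <- function(m) {
    fw <- mvwss:::model_forward(m, x, training = TRUE)
    as.numeric(mvwss:::ad_masked_mse(fw$tape, fw$out, y, mask)$value)
  }
  fw <- mvwss:::model_forward(mod, x, training = TRUE)
  loss <- mvwss:::ad_masked_mse(fw$tape, fw$out, y, mask)
  mvwss:::ad_backward(fw$tape, loss)
  for (p in c("enc1.conv1.w", "inter2.w", "enc3.bn1.gamma", "out.w")) {
    g <- fw$pnodes[[p]]$grad
    i <- which.max(abs(g))
    eps <- 1e-5
    m2 <- mod; m2$params[[p]][i] <- m2$params[[p]][i] + eps
    lp <- lossfun(m2)
    m2$params[[p]][i] <- m2$params[[p]][i] - 2 * eps
    lm <- lossfun(m2)
    expect_equal(g[i], (lp - lm) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("checkpoints round-trip weights, running stats and config", {
  cfg <- network_config(depth = 2L, base_filters = 4L, input_size = 32L)
  mod <- build_model(cfg, seed = 3L)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  invisible(predict_model(mod, x, training = TRUE))  # move running stats
  path <- tempfile(fileext = ".rds")
  save_checkpoint(mod, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, mod$params)
  expect_equal(predict_model(back, x), predict_model(mod, x))
})
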