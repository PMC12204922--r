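test_that("codec endpoints map to the first and last LUT colors", {
  cod <- colormap_codec(c(0, 2))
  expect_equal(encode_field(0, cod)[1, ], cod$lut[1, ])
  expect_equal(encode_field(2, cod)[1, ], cod$lut[256, ])
  # out-of-range values clip to the endpoints
  expect_equal(encode_field(-5, cod)[1, ], cod$lut[1, ])
  expect_equal(encode_field(9, cod)[1, ], cod$lut[256, ])
  expect_error(encode_field(NaN, cod), "non-finite")
})

test_that("encode/decode round trip is exact on LUT levels and within half a step elsewhere", {
  cod <- colormap_codec(c(-1, 3))
  lv <- codec_levels(cod)
  # exhaustive sweep over all 256 LUT entries
  cols <- encode_field(lv, cod)
  img <- array(c(cols[, 1], cols[, 2], cols[, 3]), c(256L, 1L, 3L))
  view <- structure(list(pixels = img, mask = matrix(TRUE, 256, 1),
                         meta = list(mode = "field")), class = "mv_view")
  dec <- decode_image(view, cod)
  expect_equal(dec$values[, 1], lv, tolerance = 1e-12)
  # random in-range scalars: quantization error at most span / L
  set.seed(1)
  x <- runif(500, -1, 3)
  cx <- encode_field(x, cod)
  imgx <- array(c(cx[, 1], cx[, 2], cx[, 3]), c(500L, 1L, 3L))
  vx <- structure(list(pixels = imgx, mask = matrix(TRUE, 500, 1),
                       meta = list(mode = "field")), class = "mv_view")
  dx <- decode_image(vx, cod)
  expect_lt(max(abs(dx$values[, 1] - x)), 4 / 255 / 2 + 1e-12)
})

test_that("the background color is never a LUT entry", {
  cod <- colormap_codec(c(0, 1))
  d <- sqrt(rowSums(sweep(cod$lut, 2, cod$background)^2))
  expect_gt(min(d), 0.1)
})

test_that("a 30-degree ring yields 12 deterministic views with exact background", {
  m <- fixture_aorta()
  vs <- render_views(m, "field", "tawss", axis = "z", step_degrees = 30,
                     resolution = 128L)
  expect_length(vs, 12L)
  expect_setequal(vapply(vs, function(v) v$meta$step_index, integer(1)), 0:11)
  for (v in vs[c(1, 5, 9)]) {
    expect_gt(sum(v$mask), 0)
    expect_lt(sum(v$mask), length(v$mask))
    for (ch in 1:3) expect_true(all(v$pixels[, , ch][!v$mask] == 1))
  }
  v1 <- render_views(m, "field", "tawss", axis = "z", step_degrees = 360,
                     resolution = 128L)
  expect_length(v1, 1L)
  expect_identical(v1[[1]]$pixels, vs[[1]]$pixels)
  vs2 <- render_views(m, "field", "tawss", axis = "z", step_degrees = 30,
                      resolution = 128L)
  expect_identical(vs[[7]]$pixels, vs2[[7]]$pixels)
})

test_that("rotating the mesh equals advancing the camera", {
  m <- fixture_aorta()
  for (ax in c("z", "x")) {
    vs <- render_views(m, "field", "tawss", axis = ax, step_degrees = 30,
                       resolution = 128L)
    mr <- transform_mesh(m, mvwss:::rotation_matrix(ax, 30))
    vr <- render_views(mr, "field", "tawss", axis = ax, step_degrees = 30,
                       resolution = 128L)
    expect_gte(mean(vr[[1]]$mask == vs[[2]]$mask), 0.995)
  }
})

test_that("captured views downsample 768 -> 256 by area averaging", {
  m <- fixture_aorta()
  v <- render_views(m, "field", "tawss", axis = "z", step_degrees = 360,
                    resolution = 768L)[[1]]
  d <- downsample(v, 256L)
  expect_equal(dim(d$pixels), c(256L, 256L, 3L))
  expect_equal(dim(d$mask), c(256L, 256L))
  for (ch in 1:3) expect_true(all(d$pixels[, , ch][!d$mask] == 1))
  expect_identical(downsample(v, 768L), v)
  expect_error(downsample(v, 100L), "divide")
})

test_that("downsampling preserves constant foreground color away from edges", {
  m <- fixture_aorta()
  mc <- m
  mc$fields$tawss$values[] <- mean(mc$fields$tawss$range)
  cod <- colormap_codec(mc$fields$tawss$range)
  v <- render_views(mc, "field", "tawss", codec = cod, axis = "z",
                    step_degrees = 360, resolution = 256L)[[1]]
  d <- downsample(v, 64L)
  # interior pixels: mask true and all 8 neighbours true
  mk <- d$mask
  interior <- mk
  interior[] <- FALSE
  for (i in 2:(nrow(mk) - 1)) for (j in 2:(ncol(mk) - 1))
    interior[i, j] <- all(mk[(i - 1):(i + 1), (j - 1):(j + 1)])
  expect_gt(sum(interior), 0)
  want <- encode_field(mean(mc$fields$tawss$range), cod)[1, ]
  for (ch in 1:3)
    expect_lt(max(abs(d$pixels[, , ch][interior] - want[ch])), 1e-9)
})

test_that("x/y augmentation doubles the ring and is flagged", {
  m <- fixture_aorta()
  aug <- augment_axes(m, "field", "tawss", step_degrees = 30,
                      resolution = 128L)
  expect_length(aug, 24L)
  expect_true(all(vapply(aug, function(v) isTRUE(v$meta$augmented),
                         logical(1))))
  expect_setequal(unique(vapply(aug, function(v) v$meta$axis, character(1))),
                  c("x", "y"))
  # z views differ pixelwise from x/y views of the same step (asymmetric mesh)
  z0 <- render_views(m, "field", "tawss", axis = "z", step_degrees = 30,
                     resolution = 128L)[[1]]
  expect_gt(sum(abs(z0$pixels - aug[[1]]$pixels)), 0)
})

test_that("random zoom scales mask area by the squared factor", {
  m <- fixture_aorta()
  v <- render_views(m, "field", "tawss", axis = "z", step_degrees = 360,
                    resolution = 128L)[[1]]
  expect_identical(random_zoom(v, zoom_range = c(1, 1))$pixels, v$pixels)
  z <- random_zoom(v, factor = 0.5)
  expect_lt(abs(sum(z$mask) / sum(v$mask) - 0.25), 0.05 * 0.25)
  for (ch in 1:3) expect_true(all(z$pixels[, , ch][!z$mask] == 1))
  # paired input/target with one factor keep identical masks
  vt <- render_views(m, "field", "curvature", axis = "z", step_degrees = 360,
                     resolution = 128L)[[1]]
  f <- 0.83
  expect_identical(random_zoom(v, factor = f)$mask,
                   random_zoom(vt, factor = f)$mask)
  expect_error(random_zoom(v, zoom_range = c(0, 1)), "invalid zoom")
})

test_that("constant-field renders decode to the constant and background to NA", {
  m <- fixture_aorta()
  cod <- colormap_codec(c(0, 2))
  mc <- m; mc$fields$tawss$values[] <- 1; mc$fields$tawss$range <- c(0, 2)
  v <- render_views(mc, "field", "tawss", codec = cod, axis = "z",
                    step_degrees = 360, resolution = 128L)[[1]]
  dec <- decode_image(v, cod)
  expect_true(all(is.na(dec$values[!v$mask])))
  expect_lt(max(abs(dec$values[v$mask] - 1)), 2 / 255)
  # decoded values of any field render stay within the codec range
  v2 <- render_views(m, "field", "tawss", axis = "z", step_degrees = 360,
                     resolution = 128L)[[1]]
  cod2 <- colormap_codec(m$fields$tawss$range)
  d2 <- decode_image(v2, cod2)
  expect_gte(min(d2$values[v2$mask]), cod2$range[1])
  expect_lte(max(d2$values[v2$mask]), cod2$range[2])
})

test_that("shaded mode renders without a codec and keeps the mask exact", {
  m <- fixture_aorta()
  v <- render_views(m, "shaded", axis = "z", step_degrees = 120,
                    resolution = 128L)
  expect_length(v, 3L)
  expect_gt(sum(v[[1]]$mask), 0)
  for (ch in 1:3) expect_true(all(v[[1]]$pixels[, , ch][!v[[1]]$mask] == 1))
  # foreground shading never reaches pure white
  fg <- sapply(1:3, function(ch) max(v[[1]]$pixels[, , ch][v[[1]]$mask]))
  expect_lt(max(fg), 1)
})

test_that("views survive a PNG + sidecar round trip", {
  v <- downsample(render_views(fixture_aorta(), "field", "tawss", axis = "z",
                               step_degrees = 360, resolution = 128L)[[1]],
                  64L)
  stem <- tempfile()
  save_view(v, stem)
  back <- load_view(stem)
  expect_identical(back$mask, v$mask)
  expect_lt(max(abs(back$pixels - v$pixels)), 1 / 255)
  expect_equal(back$meta$geometry_id, v$meta$geometry_id)
  expect_equal(back$meta$range, v$meta$range)
})
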