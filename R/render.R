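#' Render a ring of snapshot views of a mesh
#'
#' The domain transformation: the mesh is rotated counterclockwise (viewed
#' from the positive end of `axis`) in increments of `step_degrees` and an
#' orthographic snapshot is taken after each step, producing exactly
#' `360 / step_degrees` square images with exact foreground masks. Framing
#' is locked per geometry (centred on the vertex centroid, scaled from
#' rotation-invariant bounds with a fixed 5% margin) so the apparent size is
#' identical at every angle. In `"field"` mode per-vertex scalars are
#' encoded through the colormap codec and interpolated across triangles; in
#' `"shaded"` mode a deterministic headlight shading with a
#' metallic/roughness-style response renders the bare geometry. The mask is
#' taken from triangle coverage (a silhouette pass), never from white-pixel
#' detection, so bright shading can never punch holes in it.
#'
#' @param mesh an `mv_mesh`.
#' @param mode `"field"` or `"shaded"`.
#' @param field name of the per-vertex field to encode (field mode).
#' @param codec an [colormap_codec()]; default: a rainbow codec over the
#'   field's recorded range.
#' @param axis rotation axis, `"x"`, `"y"` or `"z"`.
#' @param step_degrees rotation increment; must divide 360.
#' @param resolution image side in pixels (>= 64).
#' @param margin framing margin as a fraction of the image side.
#' @param geometry_id identifier recorded in the view metadata.
#' @param augmented logical flag recorded in metadata (x/y-axis views used
#'   for training-time augmentation only).
#' @return list of `mv_view` objects.
#' @export
render_views <- function(mesh, mode = c("field", "shaded"), field = "tawss",
                         codec = NULL, axis = c("z", "x", "y"),
                         step_degrees = 30, resolution = 256L, margin = 0.05,
                         geometry_id = "", augmented = FALSE) {
  mode <- match.arg(mode)
  axis <- match.arg(axis)
  if (360 %% step_degrees != 0) stop("step_degrees must divide 360")
  if (resolution < 64L) stop("resolution must be >= 64")
  v <- mesh$vertices
  center <- colMeans(v)   # vertex centroid: rotation-equivariant framing
  vc <- sweep(v, 2L, center)
  basis <- switch(axis,
                  z = list(u = c(1, 0, 0), v = c(0, 0, 1), d = c(0, 1, 0)),
                  x = list(u = c(0, 1, 0), v = c(1, 0, 0), d = c(0, 0, 1)),
                  y = list(u = c(0, 0, 1), v = c(0, 1, 0), d = c(1, 0, 0)))
  ax_vec <- basis$v
  r_perp <- sqrt(max(rowSums((vc - outer(as.vector(vc %*% ax_vec), ax_vec))^2)))
  h_ax <- diff(range(vc %*% ax_vec))
  extent <- max(2 * r_perp, h_ax)
  if (extent <= 0) stop("degenerate mesh with zero extent")
  scale <- resolution * (1 - 2 * margin) / extent
  if (mode == "field") {
    fl <- mesh$fields[[field]]
    if (is.null(fl)) stop("mesh has no field '", field, "'")
    if (is.null(codec)) {
      rg <- fl$range
      if (rg[1] >= rg[2]) rg <- rg + c(-0.5, 0.5)  # constant field
      codec <- colormap_codec(rg)
    }
    base_colors <- encode_field(fl$values, codec)
  } else {
    normals <- vertex_normals(mesh)
  }
  n_views <- as.integer(360 / step_degrees)
  H <- W <- as.integer(resolution)
  lapply(seq_len(n_views) - 1L, function(k) {
    ang <- (k * step_degrees) %% 360
    R <- rotation_matrix(axis, ang)
    p <- vc %*% t(R)
    px <- as.vector(p %*% basis$u) * scale + W / 2
    py <- H / 2 - as.vector(p %*% basis$v) * scale
    pz <- as.vector(p %*% basis$d)
    if (mode == "shaded") {
      nd <- abs(as.vector((normals %*% t(R)) %*% basis$d))
      shade <- pmin(0.97, 0.08 + 0.62 * nd + 0.28 * nd^9)
      cols <- cbind(0.80 * shade, 0.81 * shade, 0.84 * shade) / 0.84
    } else cols <- base_colors
    ras <- .rasterize(px, py, pz, mesh$faces - 1L, cols, H, W, c(1, 1, 1))
    if (!any(ras$mask)) stop("geometry not visible (degenerate render)")
    structure(list(
      pixels = ras$pixels, mask = ras$mask,
      meta = list(geometry_id = geometry_id, axis = axis, step_index = k,
                  step_degrees = step_degrees, mode = mode,
                  field = if (mode == "field") field else NA_character_,
                  range = if (mode == "field") codec$range else NULL,
                  codec_name = if (mode == "field") codec$name else NULL,
                  resolution = H, augmented = augmented)),
      class = "mv_view")
  })
}

vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  e2 <- v[f[, 3], ] - v[f[, 1], ]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  N <- rowsum(rbind(fn, fn, fn), c(f[, 1], f[, 2], f[, 3]), reorder = FALSE)
  Nf <- matrix(0, nrow(v), 3L)
  Nf[as.integer(rownames(N)), ] <- N
  nn <- sqrt(rowSums(Nf^2)); nn[nn == 0] <- 1
  Nf / nn
}

#' @export
print.mv_view <- function(x, ...) {
  cat(sprintf("mv_view %dx%d [%s axis=%s step=%d%s] geometry=%s\n",
              nrow(x$mask), ncol(x$mask), x$meta$mode, x$meta$axis,
              x$meta$step_index,
              if (isTRUE(x$meta$augmented)) " augmented" else "",
              x$meta$geometry_id))
  invisible(x)
}

#' Downsample a rendered view
#'
#' Area-averaged (box-filter) downsampling of the color raster; the mask is
#' resampled by strict majority vote and background pixels are restored to
#' the exact background color.
#'
#' @param image an `mv_view`.
#' @param target output side in pixels; must divide the source resolution.
#' @return an `mv_view` of size `target x target`.
#' @export
downsample <- function(image, target) {
  H <- nrow(image$mask)
  if (target == H) return(image)
  if (H %% target != 0) stop("target must divide the source resolution")
  f <- H %/% target
  blockmean <- function(m) {
    # rows first, then columns
    s1 <- colMeans(array(m, c(f, target, ncol(m))))        # target x W
    t(colMeans(array(t(s1), c(f, target, target))))        # target x target
  }
  px <- array(0, c(target, target, 3L))
  for (ch in 1:3) px[, , ch] <- blockmean(image$pixels[, , ch])
  mk <- blockmean(image$mask * 1) > 0.5
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[!mk] <- 1
    px[, , ch] <- plane
  }
  out <- image
  out$pixels <- px
  out$mask <- mk
  out$meta$resolution <- as.integer(target)
  out
}

#' Augmentation views around the x and y axes
#'
#' Renders the same ring of views around the x axis and the y axis and flags
#' them as augmentation-only; the dataset splitter keeps flagged views out
#' of every test manifest, so test-time evaluation sees z-axis views only.
#'
#' @inheritParams render_views
#' @return list of `mv_view` objects (x views then y views).
#' @export
augment_axes <- function(mesh, mode = "field", field = "tawss", codec = NULL,
                         step_degrees = 30, resolution = 256L,
                         geometry_id = "") {
  c(render_views(mesh, mode, field, codec, axis = "x",
                 step_degrees = step_degrees, resolution = resolution,
                 geometry_id = geometry_id, augmented = TRUE),
    render_views(mesh, mode, field, codec, axis = "y",
                 step_degrees = step_degrees, resolution = resolution,
                 geometry_id = geometry_id, augmented = TRUE))
}

#' Runtime random-zoom augmentation
#'
#' Scales image and mask about the image centre by one seeded factor drawn
#' uniformly from `zoom_range` (nearest-neighbour resampling, so colormap
#' colors are never blended). Factors below 1 shrink the geometry and refill
#' the border with exact background; factors above 1 crop. The input and
#' target of a training pair must receive the same factor: draw it once (or
#' pass `factor`) and apply it to both. If a crop removes the entire
#' foreground the draw is retried a bounded number of times.
#'
#' @param image an `mv_view`.
#' @param zoom_range length-2 `(low, high)`, `0 < low <= high`.
#' @param seed integer seed for the factor draw.
#' @param factor optional explicit factor (overrides the draw).
#' @param max_retries retries allowed when the crop empties the mask.
#' @return an `mv_view`; the applied factor is in `meta$zoom_factor`.
#' @export
random_zoom <- function(image, zoom_range = c(0.9, 1.1), seed = 1L,
                        factor = NULL, max_retries = 10L) {
  if (zoom_range[1] <= 0 || zoom_range[1] > zoom_range[2])
    stop("invalid zoom range")
  H <- nrow(image$mask); W <- ncol(image$mask)
  draw_seed <- seed
  for (attempt in seq_len(max_retries + 1L)) {
    f <- factor %||% with_seed(draw_seed,
                               stats::runif(1, zoom_range[1], zoom_range[2]))
    cy <- H / 2; cx <- W / 2
    src_r <- floor(cy + ((seq_len(H) - 0.5) - cy) / f) + 1L
    src_c <- floor(cx + ((seq_len(W) - 0.5) - cx) / f) + 1L
    ok_r <- src_r >= 1L & src_r <= H
    ok_c <- src_c >= 1L & src_c <= W
    px <- array(1, c(H, W, 3L))
    mk <- matrix(FALSE, H, W)
    mk[ok_r, ok_c] <- image$mask[src_r[ok_r], src_c[ok_c]]
    for (ch in 1:3) {
      plane <- matrix(1, H, W)
      plane[ok_r, ok_c] <- image$pixels[src_r[ok_r], src_c[ok_c], ch]
      plane[!mk] <- 1
      px[, , ch] <- plane
    }
    if (any(mk)) {
      out <- image
      out$pixels <- px; out$mask <- mk
      out$meta$zoom_factor <- f
      return(out)
    }
    if (!is.null(factor)) stop("zoom factor crops away the entire geometry")
    draw_seed <- draw_seed + 1L
  }
  stop("random zoom failed to keep the geometry in frame after ",
       max_retries, " retries")
}

#' Write a view to disk (PNG + mask PNG + JSON sidecar)
#' @param image an `mv_view`.
#' @param stem output path without extension.
#' @export
save_view <- function(image, stem) {
  png::writePNG(image$pixels, paste0(stem, ".png"))
  png::writePNG(image$mask * 1, paste0(stem, "_mask.png"))
  meta <- image$meta
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(stem)
}

#' Read a view written by [save_view()]
#' @param stem path stem used when saving.
#' @export
load_view <- function(stem) {
  px <- png::readPNG(paste0(stem, ".png"))
  mk <- png::readPNG(paste0(stem, "_mask.png")) >= 0.5
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  structure(list(pixels = px, mask = mk, meta = meta), class = "mv_view")
}
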