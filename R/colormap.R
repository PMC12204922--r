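#' Invertible colormap codec
#'
#' The bridge between scalar fields and rendered images: a fixed lookup
#' table of `L` colors spanning an explicit scalar `range`. Encoding maps a
#' scalar linearly onto the LUT (out-of-range values clip to the endpoints);
#' decoding assigns each foreground pixel the scalar of its nearest LUT
#' color, so stress values can be recovered from predicted images. The
#' reserved background color (pure white) is never a LUT entry. LUT entries
#' are 8-bit-exact so PNG round trips do not perturb decoding.
#'
#' @param range length-2 numeric `(min, max)`, `min < max`.
#' @param n_colors LUT length `L`.
#' @param name colormap identifier; `"rainbow"` is the built-in
#'   blue-to-red map.
#' @return an object of class `mv_codec`.
#' @export
colormap_codec <- function(range, n_colors = 256L, name = "rainbow") {
  range <- as.numeric(range)
  if (length(range) != 2L || !all(is.finite(range)) || range[1] >= range[2])
    stop("codec range must be finite with min < max")
  anchors <- c("#00007F", "#0000FF", "#00FFFF", "#00FF00",
               "#FFFF00", "#FF0000", "#7F0000")
  lut <- round(grDevices::colorRamp(anchors, space = "rgb")(
    seq(0, 1, length.out = n_colors))) / 255
  structure(list(name = name, lut = lut, range = range,
                 background = c(1, 1, 1), max_intensity = 1.0),
            class = "mv_codec")
}

#' Encode per-vertex scalars as LUT colors
#'
#' @param values finite numeric vector.
#' @param codec an [colormap_codec()].
#' @return numeric `length(values) x 3` matrix of RGB in `[0, 1]`.
#' @export
encode_field <- function(values, codec) {
  if (any(!is.finite(values))) stop("cannot encode non-finite scalars")
  L <- nrow(codec$lut)
  span <- codec$range[2] - codec$range[1]
  x <- pmin(pmax(values, codec$range[1]), codec$range[2])
  idx <- 1L + as.integer(round((x - codec$range[1]) / span * (L - 1L)))
  codec$lut[idx, , drop = FALSE]
}

#' Scalar value represented by each LUT entry
#' @param codec an [colormap_codec()].
#' @return numeric vector of length `L`.
#' @export
codec_levels <- function(codec) {
  L <- nrow(codec$lut)
  codec$range[1] + (seq_len(L) - 1L) / (L - 1L) *
    (codec$range[2] - codec$range[1])
}

#' Decode a rendered field image back to scalars
#'
#' Each foreground (masked) pixel is assigned the scalar of the nearest LUT
#' color in RGB space; background pixels get `NA`. The distance to the
#' nearest LUT color is returned for diagnostics (large distances flag
#' pixels that are far from any valid colormap color).
#'
#' @param image an `mv_view` rendered in `"field"` mode.
#' @param codec the same [colormap_codec()] used for rendering.
#' @return list with `values` (H x W matrix, `NA` off-geometry) and `dist`.
#' @export
decode_image <- function(image, codec) {
  nn <- .nearest_lut(image$pixels, image$mask, codec$lut)
  lv <- codec_levels(codec)
  vals <- matrix(NA_real_, nrow(nn$index), ncol(nn$index))
  ok <- !is.na(nn$index)
  vals[ok] <- lv[nn$index[ok]]
  list(values = vals, dist = nn$dist)
}
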