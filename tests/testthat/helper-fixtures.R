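# Shared fixtures and independent oracles, all built in code.

fixture_sphere <- function(subdiv = 4L, radius = 1) {
  mvwss:::icosphere(subdiv, radius)
}

fixture_cylinder <- function(radius = 2, height = 8, n_ax = 40L, n_circ = 48L) {
  mvwss:::cylinder_mesh(radius, height, n_ax, n_circ)
}

fixture_plane <- function(n = 14L) mvwss:::plane_mesh(n)

# A small aneurysm mesh with curvature + TAWSS fields attached.
fixture_aorta <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- generate_aorta(aorta_params(axial_resolution = 48L,
                                       circumferential_resolution = 20L,
                                       seed = 7L))
      cv <- mean_curvature(m)
      m <- attach_field(m, scalar_field("curvature",
                                        clip_percentiles(cv$values),
                                        units = "1/mm"))
      s <- pseudo_cfd_wss(m, noise_sd = 0)
      m <- attach_field(m, tawss(s, 3L))
      cache <<- m
    }
    cache
  }
})

interior_vertices <- function(mesh) {
  setdiff(seq_len(nrow(mesh$vertices)),
          mvwss:::boundary_vertices(mesh$faces))
}

# Independent per-pixel loops implementing the masked loss and metric
# definitions; deliberately scalar and definition-literal.
brute_emse <- function(pred, target, mask) {
  tot <- 0; ne <- 0L
  C <- if (length(dim(pred)) == 3L) dim(pred)[3] else 1L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j]) next
    ne <- ne + 1L
    s <- 0
    for (ch in seq_len(C)) {
      d <- if (C > 1L) pred[i, j, ch] - target[i, j, ch]
      else pred[i, j] - target[i, j]
      s <- s + d * d
    }
    tot <- tot + s / C
  }
  tot / ne
}

brute_metrics <- function(pred, target, mask, max_stress, span) {
  sa <- 0; sq <- 0; ne <- 0L
  C <- dim(pred)[3]
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j]) next
    ne <- ne + 1L
    aa <- 0; qq <- 0
    for (ch in seq_len(C)) {
      d <- pred[i, j, ch] - target[i, j, ch]
      aa <- aa + abs(d); qq <- qq + d * d
    }
    sa <- sa + aa / C; sq <- sq + qq / C
  }
  emae_i <- sa / ne; emse_i <- sq / ne
  list(EMAE = emae_i * span, EMSE = emse_i * span^2,
       ERMSE = sqrt(emse_i) * span,
       NMAE = 100 * emae_i * span / max_stress,
       NMSE = 100 * emse_i * span^2 / max_stress,
       NRMSE = 100 * sqrt(emse_i) * span / max_stress,
       EPSNR = if (emse_i == 0) Inf else 20 * log10(1 / sqrt(emse_i)))
}

# Random masked image pair on [0,1]^3 with a guaranteed non-trivial mask.
random_pair <- function(n = 16L, seed = 1L) {
  set.seed(seed)
  pred <- array(runif(n * n * 3), c(n, n, 3))
  target <- array(runif(n * n * 3), c(n, n, 3))
  mask <- matrix(runif(n * n) < 0.6, n, n)
  if (!any(mask)) mask[1, 1] <- TRUE
  if (all(mask)) mask[1, 1] <- FALSE
  list(pred = pred, target = target, mask = mask)
}

# Minimal rendered pair set (input = curvature render, target = TAWSS
# render) for one geometry at low resolution.
fixture_pairs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- fixture_aorta()
      mk <- function(field) render_views(m, "field", field, axis = "z",
                                         step_degrees = 90,
                                         resolution = 64L,
                                         geometry_id = "fix")
      rin <- mk("curvature"); rtg <- mk("tawss")
      cache <<- lapply(seq_along(rin), function(i)
        list(id = "fix", input = rin[[i]], target = rtg[[i]]))
    }
    cache
  }
})
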