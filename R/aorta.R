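#' Parameters of the procedural aneurysm generator
#'
#' Describes an AAA-like geometry: a circular cross-section swept along a
#' (optionally bent) centerline whose radius profile is
#' `base_radius * (1 + bulge_factor * G(s))`, with `G` a smooth Gaussian bump
#' centred at `bulge_center` (fraction of arclength) whose full axial extent
#' is `bulge_width` mm (4 standard deviations). The default `bulge_factor`
#' of 0.75 makes the maximum diameter exceed the base diameter by more than
#' 50%, the clinical threshold for calling a dilatation an aneurysm. The
#' seed perturbs the bend direction, a mild sac asymmetry and low-order
#' smooth radius noise, so one parameter set spawns a family of distinct but
#' related geometries.
#'
#' @param centerline_length vessel length (mm).
#' @param base_radius radius of the undilated lumen (mm).
#' @param bulge_factor sac radius = `base_radius * (1 + bulge_factor)`.
#' @param bulge_center sac centre as a fraction of arclength, in (0, 1).
#' @param bulge_width full axial extent of the sac (mm).
#' @param centerline_curvature dimensionless bend amplitude (lateral offset
#'   as a fraction of length).
#' @param axial_resolution,circumferential_resolution vertex counts (>= 8).
#' @param radius_noise relative amplitude of smooth radius noise.
#' @param seed integer controlling all stochastic perturbations.
#' @export
aorta_params <- function(centerline_length = 120, base_radius = 10,
                         bulge_factor = 0.75, bulge_center = 0.5,
                         bulge_width = 45, centerline_curvature = 0.08,
                         axial_resolution = 72L, circumferential_resolution = 28L,
                         radius_noise = 0.01, seed = 1L) {
  p <- list(centerline_length = centerline_length, base_radius = base_radius,
            bulge_factor = bulge_factor, bulge_center = bulge_center,
            bulge_width = bulge_width,
            centerline_curvature = centerline_curvature,
            axial_resolution = as.integer(axial_resolution),
            circumferential_resolution = as.integer(circumferential_resolution),
            radius_noise = radius_noise, seed = as.integer(seed))
  if (p$base_radius <= 0) stop("base_radius must be positive")
  if (p$bulge_factor < 0) stop("bulge_factor must be >= 0")
  if (p$bulge_center <= 0 || p$bulge_center >= 1)
    stop("bulge_center must lie strictly inside (0, 1)")
  if (p$bulge_width > p$centerline_length)
    stop("bulge_width exceeds centerline_length (self-intersecting sac)")
  if (p$axial_resolution < 8L || p$circumferential_resolution < 8L)
    stop("resolutions must be >= 8")
  structure(p, class = "mv_aorta_params")
}

#' Generate an AAA-like surface mesh
#'
#' Sweeps a circular cross-section along a bent centerline with a Gaussian
#' sac bump, closes both ends with triangle-fan caps (watertight), and
#' stores the sweep parameterization (per-vertex arclength fraction, local
#' lumen radius and axial tangent) in the `"sweep"` attribute for use by the
#' pseudo-CFD oracle. Deterministic given `params$seed`.
#'
#' @param params an [aorta_params()] object.
#' @return an `mv_mesh`.
#' @export
generate_aorta <- function(params) {
  stopifnot(inherits(params, "mv_aorta_params"))
  p <- params
  na <- p$axial_resolution; nc <- p$circumferential_resolution
  with_seed(p$seed, {
    bend_dir <- stats::runif(1, 0, 2 * pi)
    asym <- stats::runif(1, 0, 0.25)
    namp <- stats::rnorm(3, 0, 1)
    nph <- stats::runif(3, 0, 2 * pi)
  })
  u <- seq(0, 1, length.out = na)
  L <- p$centerline_length
  # centerline: z along the vessel, planar bend rotated by bend_dir
  off <- p$centerline_curvature * L * sin(pi * u)
  cx <- off * cos(bend_dir); cy <- off * sin(bend_dir); cz <- u * L
  C <- cbind(cx, cy, cz)
  # radius profile: Gaussian bump + smooth low-order noise
  sig_u <- (p$bulge_width / 4) / L
  G <- exp(-0.5 * ((u - p$bulge_center) / sig_u)^2)
  noise <- rep(0, na)
  for (k in 1:3) noise <- noise + namp[k] * sin(2 * pi * k * u + nph[k])
  radius <- p$base_radius * (1 + p$bulge_factor * G) *
    (1 + p$radius_noise * noise / sqrt(3))
  if (any(radius <= 0)) stop("negative lumen radius; parameters invalid")
  # tangent frames (centered differences) and a stable normal pair
  Tg <- rbind(C[2, ] - C[1, ],
              C[3:na, , drop = FALSE] - C[1:(na - 2), , drop = FALSE],
              C[na, ] - C[na - 1, ])
  Tg <- Tg / sqrt(rowSums(Tg^2))
  ref <- c(cos(bend_dir + pi / 2), sin(bend_dir + pi / 2), 0)
  N1 <- matrix(ref, na, 3L, byrow = TRUE) - Tg * as.vector(Tg %*% ref)
  N1 <- N1 / sqrt(rowSums(N1^2))
  N2 <- cbind(Tg[, 2] * N1[, 3] - Tg[, 3] * N1[, 2],
              Tg[, 3] * N1[, 1] - Tg[, 1] * N1[, 3],
              Tg[, 1] * N1[, 2] - Tg[, 2] * N1[, 1])
  th <- seq(0, 2 * pi, length.out = nc + 1L)[-(nc + 1L)]
  # sac asymmetry: shift the sac centreline sideways, radius unchanged
  shift <- asym * p$base_radius * p$bulge_factor * G
  verts <- matrix(0, na * nc, 3L)
  for (i in seq_len(na)) {
    ring <- C[rep(i, nc), ] + shift[i] * N1[rep(i, nc), ] +
      radius[i] * (outer(cos(th), N1[i, ]) + outer(sin(th), N2[i, ]))
    verts[((i - 1) * nc + 1):(i * nc), ] <- ring
  }
  faces <- ring_strip_faces(na, nc)
  # end caps: apex at the centerline ends
  a0 <- nrow(verts) + 1L; a1 <- nrow(verts) + 2L
  verts <- rbind(verts, C[1, ], C[na, ])
  j <- seq_len(nc); jn <- c(seq_len(nc)[-1], 1L)
  cap0 <- cbind(a0, jn, j)                               # inward-facing end
  capN <- cbind(a1, (na - 1L) * nc + j, (na - 1L) * nc + jn)
  mesh <- tri_mesh(verts, rbind(faces, cap0, capN))
  attr(mesh, "sweep") <- list(
    u = c(rep(u, each = nc), 0, 1),
    radius = c(rep(radius, each = nc), radius[1], radius[na]),
    tangent = rbind(Tg[rep(seq_len(na), each = nc), ], Tg[1, ], Tg[na, ]),
    params = p)
  mesh
}

#' Two-phase pulsatile inlet waveform template
#'
#' A periodic velocity waveform over one cardiac cycle with a systolic peak
#' at 30% of the cycle and a low diastolic baseline; a smooth stand-in for a
#' physiological aortic inlet profile.
#'
#' @param n_samples samples per cycle (>= 10).
#' @param peak systolic peak velocity (m/s).
#' @param baseline diastolic velocity (m/s).
#' @param cycle_period cycle duration (s).
#' @return list with `times` (s), `velocity` (m/s), `cycle_period`;
#'   first and last samples are equal (periodicity).
#' @export
flow_waveform <- function(n_samples = 50L, peak = 0.8, baseline = 0.08,
                          cycle_period = 1) {
  if (n_samples < 10L) stop("need at least 10 samples per cycle")
  tt <- seq(0, cycle_period, length.out = n_samples + 1L)
  u <- tt / cycle_period
  d <- pmin(abs(u - 0.3), 1 - abs(u - 0.3))
  v <- baseline + (peak - baseline) * exp(-0.5 * (d / 0.11)^2)
  structure(list(times = tt, velocity = v, cycle_period = cycle_period),
            class = "mv_waveform")
}

# Reference mean velocity: tau0 is calibrated to the default template.
.waveform_ref_mean <- function() mean(flow_waveform()$velocity)

#' Analytic pseudo-CFD wall shear stress oracle
#'
#' Produces a per-vertex WSS vector time series from a Poiseuille-like law:
#' the instantaneous magnitude at arclength s and time t is
#' `tau0 * (base_radius / r(s))^3 * w(t) / w_ref`, directed along the local
#' axial tangent, where r(s) is the local lumen radius and w the inlet
#' waveform (w_ref is the mean of the default template, so `tau0` is the
#' time-averaged wall shear stress of the undilated tube under the default
#' waveform). The inverse-cube law reproduces the qualitative pattern that
#' motivates the surrogate: markedly lower stress inside the dilated sac.
#' Optional zero-mean Gaussian noise (sd `noise_sd`, Pa) is added to the
#' signed magnitude.
#'
#' @param mesh a mesh from [generate_aorta()] (carries the sweep
#'   parameterization) or any mesh with a `"sweep"` attribute.
#' @param waveform a [flow_waveform()].
#' @param noise_sd noise standard deviation (Pa).
#' @param seed integer seed for the noise.
#' @param dt time step (s).
#' @param n_cycles number of cardiac cycles simulated.
#' @param tau0 reference wall shear stress of the straight tube (Pa).
#' @return an object of class `mv_wss_series`: list with `values`
#'   (n_steps x n_vertices x 3 array, Pa), `dt`, `n_steps`, `cycle_period`.
#' @export
pseudo_cfd_wss <- function(mesh, waveform = flow_waveform(), noise_sd = 0,
                           seed = 1L, dt = 0.01, n_cycles = 3L, tau0 = 1.5) {
  sweep <- attr(mesh, "sweep")
  if (is.null(sweep)) stop("mesh lacks a sweep parameterization; generate it",
                           " with generate_aorta()")
  r <- sweep$radius
  if (any(r <= 0)) stop("non-positive lumen radius r(s)")
  R0 <- sweep$params$base_radius
  Tper <- waveform$cycle_period
  n_steps <- as.integer(round(n_cycles * Tper / dt))
  tt <- (seq_len(n_steps) - 0.5) * dt
  wt <- periodic_interp(waveform, tt %% Tper)
  mag_s <- tau0 * (R0 / r)^3                 # per-vertex spatial factor
  scale_t <- wt / .waveform_ref_mean()       # per-step temporal factor
  nv <- nrow(mesh$vertices)
  m <- outer(scale_t, mag_s)                 # n_steps x nv signed magnitude
  if (noise_sd > 0) {
    m <- m + with_seed(seed, matrix(stats::rnorm(n_steps * nv, 0, noise_sd),
                                    n_steps, nv))
  }
  values <- array(0, c(n_steps, nv, 3L))
  for (k in 1:3) values[, , k] <- m * matrix(sweep$tangent[, k], n_steps, nv,
                                             byrow = TRUE)
  wss_series(values, dt = dt, cycle_period = Tper)
}

periodic_interp <- function(waveform, t) {
  stats::approx(waveform$times, waveform$velocity, xout = t, rule = 2)$y
}

#' Wall shear stress vector time series
#'
#' @param values numeric array `n_steps x n_vertices x 3` (Pa).
#' @param dt time step (s).
#' @param cycle_period cardiac cycle duration (s); `n_steps * dt` must be an
#'   integer number (>= 1) of cycles.
#' @export
wss_series <- function(values, dt, cycle_period) {
  d <- dim(values)
  if (length(d) != 3L || d[3] != 3L)
    stop("values must be an n_steps x n_vertices x 3 array")
  ncyc <- d[1] * dt / cycle_period
  if (ncyc < 1 - 1e-9 || abs(ncyc - round(ncyc)) > 1e-6)
    stop("series must cover an integer number (>= 1) of cycles")
  structure(list(values = values, dt = dt, n_steps = d[1],
                 cycle_period = cycle_period),
            class = "mv_wss_series")
}

#' Time-averaged wall shear stress over one cardiac cycle
#'
#' Per-vertex arithmetic mean, over the time steps of the selected cycle, of
#' the instantaneous WSS vector magnitude. With the conventional 0.01 s step
#' and 1 s cycle each cycle contributes exactly 100 steps; downstream
#' analyses use the last simulated cycle so that start-up transients of the
#' preceding cycles are excluded.
#'
#' @param series an `mv_wss_series`.
#' @param cycle_index 1-based cycle to average (must lie within the series).
#' @return an [scalar_field()] named `"tawss"` (Pa).
#' @export
tawss <- function(series, cycle_index) {
  stopifnot(inherits(series, "mv_wss_series"))
  spc <- as.integer(round(series$cycle_period / series$dt))
  first <- (cycle_index - 1L) * spc + 1L
  last <- cycle_index * spc
  if (cycle_index < 1L || last > series$n_steps)
    stop("cycle ", cycle_index, " extends past the available ",
         series$n_steps, " steps (range error)")
  sl <- series$values[first:last, , , drop = FALSE]
  mags <- sqrt(sl[, , 1]^2 + sl[, , 2]^2 + sl[, , 3]^2)
  if (spc == 1L) mags <- matrix(mags, nrow = 1L)
  scalar_field("tawss", colMeans(mags), units = "Pa")
}

#' Build a synthetic geometry dataset with TAWSS ground truth
#'
#' Generates `n_base` base geometries, each with `variants_per_base`
#' perturbed variants sharing the base's family identifier (the unit of
#' leakage-free train/test splitting). Every geometry gets a clipped mean
#' curvature field and a TAWSS field from the pseudo-CFD oracle (last cycle
#' of a three-cycle series). If `dir` is given, meshes are written as VTK
#' polydata and the manifest as JSON lines; meshes are always returned
#' in-memory as well.
#'
#' @param n_base number of base geometries (>= 1).
#' @param variants_per_base perturbed variants per base (>= 0).
#' @param params_ranges named list of length-2 numeric ranges overriding the
#'   sampling ranges for [aorta_params()] fields (e.g.
#'   `list(bulge_factor = c(0.5, 1.1))`).
#' @param seed integer master seed.
#' @param dir optional output directory.
#' @param noise_sd pseudo-CFD noise (Pa) applied to every geometry.
#' @return list with `manifest` (data frame: id, family, real, seed,
#'   mesh_path) and `meshes` (named list of `mv_mesh`).
#' @export
build_dataset <- function(n_base, variants_per_base = 0L,
                          params_ranges = list(), seed = 1L, dir = NULL,
                          noise_sd = 0.02) {
  if (n_base < 1L) stop("n_base must be >= 1")
  if (variants_per_base < 0L) stop("variants_per_base must be >= 0")
  rg <- utils::modifyList(list(
    centerline_length = c(100, 140), base_radius = c(8, 12),
    bulge_factor = c(0.55, 1.0), bulge_center = c(0.35, 0.65),
    bulge_width = c(35, 55), centerline_curvature = c(0.02, 0.12)),
    params_ranges)
  draw <- function(s) with_seed(s, {
    aorta_params(
      centerline_length = stats::runif(1, rg$centerline_length[1], rg$centerline_length[2]),
      base_radius = stats::runif(1, rg$base_radius[1], rg$base_radius[2]),
      bulge_factor = stats::runif(1, rg$bulge_factor[1], rg$bulge_factor[2]),
      bulge_center = stats::runif(1, rg$bulge_center[1], rg$bulge_center[2]),
      bulge_width = stats::runif(1, rg$bulge_width[1], rg$bulge_width[2]),
      centerline_curvature = stats::runif(1, rg$centerline_curvature[1],
                                          rg$centerline_curvature[2]),
      seed = sample.int(2^31 - 2, 1))
  })
  perturb <- function(base, s) with_seed(s, {
    jit <- function(x, f, lo = -Inf, hi = Inf)
      min(max(x * stats::runif(1, 1 - f, 1 + f), lo), hi)
    aorta_params(
      centerline_length = base$centerline_length,
      base_radius = jit(base$base_radius, 0.08),
      bulge_factor = jit(base$bulge_factor, 0.15, lo = 0.5),
      bulge_center = jit(base$bulge_center, 0.1, lo = 0.2, hi = 0.8),
      bulge_width = jit(base$bulge_width, 0.15,
                        hi = base$centerline_length * 0.9),
      centerline_curvature = jit(base$centerline_curvature, 0.3),
      seed = sample.int(2^31 - 2, 1))
  })
  rows <- list(); meshes <- list()
  for (b in seq_len(n_base)) {
    fam <- sprintf("fam%03d", b)
    base_seed <- stage_seed(seed, paste0("base", b))
    base_par <- draw(base_seed)
    pars <- c(list(base_par),
              lapply(seq_len(variants_per_base), function(k)
                perturb(base_par, stage_seed(base_seed, paste0("var", k)))))
    for (k in seq_along(pars)) {
      id <- sprintf("%s_g%02d", fam, k - 1L)
      mesh <- generate_aorta(pars[[k]])
      curv <- mean_curvature(mesh)
      mesh <- attach_field(mesh, scalar_field(
        "curvature", clip_percentiles(curv$values), units = "1/mm"))
      series <- pseudo_cfd_wss(mesh, noise_sd = noise_sd,
                               seed = stage_seed(pars[[k]]$seed, "wssnoise"))
      mesh <- attach_field(mesh, tawss(series, 3L))
      mesh_path <- NA_character_
      if (!is.null(dir)) {
        dir.create(file.path(dir, "meshes"), recursive = TRUE,
                   showWarnings = FALSE)
        mesh_path <- file.path(dir, "meshes", paste0(id, ".vtk"))
        save_mesh(mesh, mesh_path)
      }
      rows[[id]] <- data.frame(id = id, family = fam, real = FALSE,
                               seed = pars[[k]]$seed, mesh_path = mesh_path,
                               stringsAsFactors = FALSE)
      meshes[[id]] <- mesh
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(dir)) {
    mf <- file.path(dir, "manifest.jsonl")
    if (file.exists(mf)) file.remove(mf)
    for (i in seq_len(nrow(manifest)))
      log_jsonl(mf, as.list(manifest[i, ]))
  }
  list(manifest = manifest, meshes = meshes, dir = dir)
}
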