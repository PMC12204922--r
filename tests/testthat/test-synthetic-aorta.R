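test_that("a bulge-free tube has maximum diameter 2 * base_radius", {
  p <- aorta_params(bulge_factor = 0, radius_noise = 0,
                    centerline_curvature = 0, seed = 3L)
  m <- generate_aorta(p)
  sw <- attr(m, "sweep")
  step <- 2 * p$base_radius * (1 - cos(pi / p$circumferential_resolution))
  expect_lt(abs(2 * max(sw$radius) - 2 * p$base_radius), step + 1e-9)
  # measured on the mesh: max pairwise extent within one ring
  ring <- m$vertices[1:p$circumferential_resolution, ]
  d <- max(dist(ring))
  expect_lt(abs(d - 2 * p$base_radius), step + 1e-9)
})

test_that("generation is deterministic in the seed", {
  p <- aorta_params(seed = 11L)
  expect_identical(generate_aorta(p)$vertices, generate_aorta(p)$vertices)
  p2 <- aorta_params(seed = 12L)
  expect_false(identical(generate_aorta(p)$vertices,
                         generate_aorta(p2)$vertices))
})

test_that("default parameters produce an aneurysmal dilatation (> 50%)", {
  m <- generate_aorta(aorta_params(seed = 5L))
  sw <- attr(m, "sweep")
  expect_gte(max(sw$radius) / aorta_params()$base_radius, 1.5)
})

test_that("parameter validation rejects impossible sacs", {
  expect_error(aorta_params(bulge_width = 200), "self-intersecting")
  expect_error(aorta_params(base_radius = -1), "positive")
  expect_error(aorta_params(bulge_center = 1.2), "inside")
  expect_error(aorta_params(axial_resolution = 4), ">= 8")
})

test_that("pseudo-CFD stress is uniform on a constant-radius tube", {
  p <- aorta_params(bulge_factor = 0, radius_noise = 0,
                    centerline_curvature = 0, seed = 3L)
  tw <- tawss(pseudo_cfd_wss(generate_aorta(p), noise_sd = 0), 3L)$values
  expect_lt(stats::sd(tw) / mean(tw), 1e-6)
  expect_gt(min(tw), 0)
})

test_that("doubling the sac radius divides sac stress by 8 (r^-3 law)", {
  p <- aorta_params(bulge_factor = 1, radius_noise = 0,
                    centerline_curvature = 0, seed = 3L)
  m <- generate_aorta(p)
  tw <- tawss(pseudo_cfd_wss(m, noise_sd = 0), 3L)$values
  sw <- attr(m, "sweep")
  apex <- which.max(sw$radius)
  tube <- which.min(abs(sw$u - 0.05))
  expect_lt(abs(tw[apex] / tw[tube] - 1 / 8), 0.02 * 1 / 8)
})

test_that("high-curvature sac vertices carry low stress (negative rank correlation)", {
  m <- generate_aorta(aorta_params(seed = 11L))
  cv <- mean_curvature(m)$values
  tw <- tawss(pseudo_cfd_wss(m, noise_sd = 0), 3L)$values
  sw <- attr(m, "sweep")
  sac <- which(abs(sw$u - sw$params$bulge_center) <
                 (sw$params$bulge_width / 2) / sw$params$centerline_length)
  rho <- stats::cor(abs(cv[sac]), tw[sac], method = "spearman")
  expect_lt(rho, 0)
})

test_that("TAWSS of a constant 2 Pa series is 2 Pa everywhere", {
  nv <- 5L
  vals <- array(0, c(30L, nv, 3L))
  vals[, , 1] <- 2
  s <- wss_series(vals, dt = 0.1, cycle_period = 1)
  expect_equal(tawss(s, 2L)$values, rep(2, nv))
})

test_that("cycle selection averages exactly the steps of that cycle", {
  # step value equals the step index, so the cycle mean identifies the steps
  nv <- 3L
  vals <- array(0, c(300L, nv, 3L))
  vals[, , 2] <- matrix(seq_len(300L), 300L, nv)
  s <- wss_series(vals, dt = 0.01, cycle_period = 1)
  expect_equal(s$n_steps, 300L)
  expect_equal(tawss(s, 3L)$values, rep(mean(201:300), nv))
  expect_error(tawss(s, 4L), "range error")
})

test_that("tawss matches a brute-force per-vertex loop", {
  set.seed(99)
  vals <- array(rnorm(20 * 7 * 3), c(20L, 7L, 3L))
  s <- wss_series(vals, dt = 0.05, cycle_period = 0.5)
  got <- tawss(s, 2L)$values
  want <- numeric(7L)
  for (v in 1:7) {
    acc <- 0
    for (k in 11:20) acc <- acc + sqrt(sum(vals[k, v, ]^2))
    want[v] <- acc / 10
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("tawss is identical across identical concatenated cycles", {
  set.seed(7)
  one <- array(rnorm(10 * 4 * 3), c(10L, 4L, 3L))
  vals <- array(0, c(30L, 4L, 3L))
  for (k in 0:2) vals[k * 10 + 1:10, , ] <- one
  s <- wss_series(vals, dt = 0.1, cycle_period = 1)
  t1 <- tawss(s, 1L)$values
  for (ci in 2:3) expect_equal(tawss(s, ci)$values, t1, tolerance = 1e-12)
})

test_that("TAWSS rides rigidly with the mesh and scales with the waveform", {
  m <- fixture_aorta()
  tw <- m$fields$tawss$values
  mr <- transform_mesh(m, mvwss:::rotation_matrix("y", 63), c(1, 2, 3))
  expect_identical(mr$fields$tawss$values, tw)
  wf <- flow_waveform()
  wf2 <- wf; wf2$velocity <- 3 * wf2$velocity
  base <- tawss(pseudo_cfd_wss(m, wf, noise_sd = 0), 3L)$values
  scaled <- tawss(pseudo_cfd_wss(m, wf2, noise_sd = 0), 3L)$values
  expect_equal(scaled, 3 * base, tolerance = 1e-12)
})

test_that("noise level controls the TAWSS perturbation linearly", {
  p <- aorta_params(bulge_factor = 0, radius_noise = 0,
                    centerline_curvature = 0, axial_resolution = 30L,
                    circumferential_resolution = 16L, seed = 3L)
  m <- generate_aorta(p)
  clean <- tawss(pseudo_cfd_wss(m, noise_sd = 0), 3L)$values
  d1 <- tawss(pseudo_cfd_wss(m, noise_sd = 0.05, seed = 21L), 3L)$values - clean
  d2 <- tawss(pseudo_cfd_wss(m, noise_sd = 0.10, seed = 22L), 3L)$values - clean
  expect_equal(stats::sd(d2) / stats::sd(d1), 2, tolerance = 0.15)
})

test_that("waveform template is periodic with enough samples", {
  wf <- flow_waveform()
  expect_equal(wf$velocity[1], wf$velocity[length(wf$velocity)])
  expect_gte(length(wf$times), 10L)
  expect_error(flow_waveform(n_samples = 5), "at least 10")
})

test_that("dataset manifests follow the base x variant structure deterministically", {
  ds <- build_dataset(2L, 2L, seed = 31L)
  expect_equal(nrow(ds$manifest), 6L)
  expect_equal(length(unique(ds$manifest$family)), 2L)
  expect_true(all(table(ds$manifest$family) == 3L))
  ds0 <- build_dataset(3L, 0L, seed = 31L)
  expect_equal(nrow(ds0$manifest), 3L)
  ds2 <- build_dataset(2L, 2L, seed = 31L)
  expect_identical(ds$manifest, ds2$manifest)
  # every geometry carries curvature + tawss fields
  expect_true(all(vapply(ds$meshes, function(m)
    all(c("curvature", "tawss") %in% names(m$fields)), logical(1))))
})

test_that("series invariants are enforced", {
  expect_error(wss_series(array(0, c(7L, 2L, 3L)), dt = 0.1,
                          cycle_period = 1), "integer number")
  expect_error(wss_series(array(0, c(10L, 2L, 2L)), dt = 0.1,
                          cycle_period = 1), "x 3 array")
})
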