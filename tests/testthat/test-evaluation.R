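test_that("a perfect prediction zeroes every error metric and saturates EPSNR", {
  rp <- random_pair(10L, seed = 2L)
  m <- effective_metrics(rp$target, rp$target, rp$mask, max_stress = 2,
                         span = 2)
  expect_equal(m$EMAE, 0); expect_equal(m$NMAE, 0)
  expect_equal(m$NMSE, 0); expect_equal(m$NRMSE, 0)
  expect_identical(m$EPSNR, Inf)
})

test_that("halving the masked MSE raises EPSNR by 10 log10(2) dB", {
  rp <- random_pair(10L, seed = 3L)
  m1 <- effective_metrics(rp$pred, rp$target, rp$mask, max_stress = 1)
  mid <- rp$target + (rp$pred - rp$target) / sqrt(2)
  m2 <- effective_metrics(mid, rp$target, rp$mask, max_stress = 1)
  expect_equal(m2$EPSNR - m1$EPSNR, 10 * log10(2), tolerance = 1e-9)
})

test_that("the 2x2 toy example evaluates to the hand-derived metrics", {
  # stress-unit differences {0, 1, 1} on 3 masked pixels, max|S| = 2:
  # intensity differences {0, 0.5, 0.5} with a colormap span of 2 Pa
  pred <- array(0, c(2, 2, 3)); targ <- array(0, c(2, 2, 3))
  for (ch in 1:3) { pred[, , ch] <- c(0.2, 0.9, 0.1, 0.4)
                    targ[, , ch] <- c(0.2, 0.4, 0.6, 0.7) }
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2)
  m <- effective_metrics(pred, targ, mask, max_stress = 2, span = 2)
  expect_equal(m$EMAE, 2 / 3, tolerance = 1e-12)
  expect_equal(m$NMAE, 100 / 3, tolerance = 1e-9)
  expect_equal(m$EMSE, 2 / 3, tolerance = 1e-12)
  expect_equal(m$ERMSE, 0.8165, tolerance = 1e-4)
  expect_equal(m$NRMSE, 40.8, tolerance = 0.05)
  # the dimensional variant divides by max|S|^2 instead
  m2 <- effective_metrics(pred, targ, mask, max_stress = 2, span = 2,
                          nmse_squared_norm = TRUE)
  expect_equal(m2$NMSE, m$NMSE / 2, tolerance = 1e-12)
})

test_that("metrics match independent brute-force loops", {
  for (s in 1:10) {
    rp <- random_pair(16L, seed = 100 + s)
    got <- effective_metrics(rp$pred, rp$target, rp$mask, max_stress = 1.7,
                             span = 0.9)
    want <- brute_metrics(rp$pred, rp$target, rp$mask, max_stress = 1.7,
                          span = 0.9)
    for (k in c("EMAE", "EMSE", "ERMSE", "NMAE", "NMSE", "NRMSE", "EPSNR"))
      expect_equal(got[[k]], want[[k]], tolerance = 1e-12)
  }
})

test_that("adding masked error never decreases EMAE/EMSE; EPSNR falls with EMSE", {
  rp <- random_pair(12L, seed = 9L)
  m0 <- effective_metrics(rp$pred, rp$target, rp$mask, max_stress = 1)
  worse <- rp$pred
  # scale one masked pixel's error away from the target (guaranteed worse)
  ad <- apply(abs(rp$pred - rp$target), c(1, 2), max) * rp$mask
  ij <- which(ad == max(ad), arr.ind = TRUE)[1, ]
  worse[ij[1], ij[2], ] <- rp$target[ij[1], ij[2], ] +
    1.5 * (rp$pred[ij[1], ij[2], ] - rp$target[ij[1], ij[2], ])
  m1 <- effective_metrics(worse, rp$target, rp$mask, max_stress = 1)
  expect_gte(m1$EMAE, m0$EMAE)
  expect_gt(m1$EMSE, m0$EMSE)
  expect_lt(m1$EPSNR, m0$EPSNR)
  # background-pixel changes leave every metric untouched
  bg <- rp$pred
  for (ch in 1:3) { p <- bg[, , ch]; p[!rp$mask] <- 0.123; bg[, , ch] <- p }
  expect_identical(effective_metrics(bg, rp$target, rp$mask, max_stress = 1),
                   m0)
})

test_that("an identity model scores zero error on self-paired views", {
  prs <- fixture_pairs()
  self_pairs <- lapply(prs, function(p) list(id = p$id, input = p$target,
                                             target = p$target))
  rep <- evaluate_model(function(x) x, self_pairs)
  expect_equal(rep$aggregate$NMAE, 0)
  expect_identical(rep$aggregate$EPSNR, Inf)
  expect_error(evaluate_model(function(x) x, list()), "empty test")
})

test_that("aggregates equal a flat recomputation over all test images", {
  prs <- fixture_pairs()
  const <- constant_mean_predictor(prs)
  rep <- evaluate_model(const, prs)
  flat <- sapply(prs, function(p) {
    rg <- p$target$meta$range
    effective_metrics(const(p$input$pixels), p$target$pixels, p$target$mask,
                      max_stress = max(abs(rg)), span = diff(rg))$NMAE
  })
  expect_equal(rep$aggregate$NMAE, mean(flat), tolerance = 1e-12)
  expect_equal(unname(rep$counts["images"]), length(prs))
})

test_that("comparison tables preserve label order and reject foreign reports", {
  prs <- fixture_pairs()
  r1 <- evaluate_model(constant_mean_predictor(prs), prs)
  r2 <- evaluate_model(function(x) x * 0 + 0.5, prs)
  tab <- compare_models(list(r1, r2, r1), c("a", "b", "c"))
  expect_equal(tab$model, c("a", "b", "c"))
  expect_equal(tab$NMAE[1], tab$NMAE[3])
  one <- compare_models(list(r1), "solo")
  expect_equal(nrow(one), 1L)
  # identical predictions give identical rows
  expect_equal(tab[1, -1], tab[3, -1], ignore_attr = TRUE)
  other <- evaluate_model(function(x) x, prs[1:2])
  expect_error(compare_models(list(r1, other), c("a", "b")),
               "different test manifests")
  txt <- format_comparison(tab)
  expect_match(txt, "NMAE")
  expect_length(strsplit(txt, "\n")[[1]], 4L)
})

test_that("reports serialize to CSV and JSON", {
  prs <- fixture_pairs()
  rep <- evaluate_model(constant_mean_predictor(prs), prs)
  stem <- tempfile()
  write_metric_report(rep, stem)
  csv <- utils::read.csv(paste0(stem, ".csv"))
  expect_equal(nrow(csv), length(prs) + 1L)
  js <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  expect_equal(js$aggregate$NMAE, rep$aggregate$NMAE, tolerance = 1e-12)
})
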