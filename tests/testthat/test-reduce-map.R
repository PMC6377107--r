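make_rank1_dataset <- function(n = 20, p = 60, seed = 1) {
  set.seed(seed)
  w <- default_wavenumbers(n = p)
  v <- sin(seq(0, 3 * pi, length.out = p))
  v <- v / sqrt(sum(v^2))
  a <- rnorm(n)
  X <- outer(a, v) + matrix(rep(5, n * p), n, p)
  md <- grid_metadata(4, 5)
  list(ds = spectral_dataset(w, X, md), a = a, v = v)
}

test_that("PCA recovers rank-1 structure exactly", {
  r1 <- make_rank1_dataset()
  fit <- fit_pca(r1$ds, q = 1)
  expect_lt(abs(fit$model$explained_fraction[1] - 1), 1e-9)
  expect_gt(abs(cor(fit$scores$scores[, 1], r1$a)), 1 - 1e-9)
  # loadings orthonormal
  L <- fit$model$loadings
  expect_equal(tcrossprod(L), diag(nrow(L)), tolerance = 1e-8)
})

test_that("PCA splits variance between planted orthogonal components", {
  set.seed(2)
  p <- 80
  v1 <- rep(c(1, -1), p / 2) / sqrt(p)
  v2 <- rep(c(1, 1, -1, -1), p / 4) / sqrt(p)
  expect_lt(abs(sum(v1 * v2)), 1e-12)
  n <- 500
  X <- outer(rnorm(n, sd = 2), v1) + outer(rnorm(n, sd = 1), v2)
  md <- grid_metadata(20, 25)
  ds <- spectral_dataset(default_wavenumbers(n = p), X, md)
  fit <- fit_pca(ds, q = 2)
  expect_lt(abs(fit$model$explained_fraction[1] - 0.8), 0.02)
  expect_lt(abs(fit$model$explained_fraction[2] - 0.2), 0.02)
  # score columns uncorrelated
  expect_lt(abs(cor(fit$scores$scores[, 1], fit$scores$scores[, 2])), 1e-6)
})

test_that("explained fractions account for the reconstruction residual", {
  set.seed(3)
  n <- 40; p <- 30
  X <- matrix(rnorm(n * p), n, p)
  ds <- spectral_dataset(default_wavenumbers(n = p), X, grid_metadata(5, 8))
  q <- 6
  fit <- fit_pca(ds, q = q)
  Xc <- sweep(X, 2, colMeans(X))
  recon <- fit$scores$scores %*% fit$model$loadings
  resid_var <- sum((Xc - recon)^2) / (n - 1)
  total_var <- sum(Xc^2) / (n - 1)
  expect_equal(resid_var,
               (1 - sum(fit$model$explained_fraction)) * total_var,
               tolerance = 1e-8)
  expect_error(fit_pca(ds, q = min(n, p) + 1), "exceeds")
})

test_that("component orientation flips toward the reference band idempotently", {
  r1 <- make_rank1_dataset(p = 100)
  fit <- fit_pca(r1$ds, q = 1)
  win <- c(840, 860)
  sel <- fit$model$wavenumbers >= win[1] & fit$model$wavenumbers <= win[2]
  o1 <- orient_component(fit, 1, win)
  expect_gte(mean(o1$model$loadings[1, sel]), 0)
  # forcing a negative loading flips both loading and scores
  flipped <- fit
  flipped$model$loadings[1, ] <- -o1$model$loadings[1, ]
  flipped$scores$scores[, 1] <- -o1$scores$scores[, 1]
  o2 <- orient_component(flipped, 1, win)
  expect_equal(o2$model$loadings, o1$model$loadings)
  expect_equal(o2$scores$scores, o1$scores$scores)
  # idempotent
  expect_equal(orient_component(o1, 1, win), o1)
  expect_error(orient_component(fit, 1, c(10, 20)), "window")
})

test_that("score scaling follows the global and per-map conventions", {
  expect_equal(scale_scores(c(-2, 0, 2)), c(0, 0.5, 1))
  ids <- c("a", "a", "b", "b")
  expect_equal(scale_scores(c(0, 1, 10, 11), "per_map", ids), c(0, 1, 0, 1))
  expect_equal(scale_scores(c(0, 1, 10, 11), "global"), c(0, 1 / 11, 10 / 11, 1))
  expect_warning(out <- scale_scores(c(3, 3, 3)), "constant")
  expect_equal(out, c(0, 0, 0))
})

test_that("discretization uses half-open uniform bins with a closed top", {
  expect_equal(discretize_scores(c(0, 0.24, 0.25, 0.5, 0.99, 1), 4),
               c(0L, 0L, 1L, 2L, 3L, 3L))
  expect_equal(discretize_scores(0.5, 2), 1L)
  set.seed(4)
  x <- runif(200)
  lv <- discretize_scores(x, 8)
  expect_gte(min(lv), 0)
  expect_lte(max(lv), 7)
  expect_error(discretize_scores(c(0.5, 1.2), 4), "\\[0, 1\\]")
})

test_that("gray maps assemble by grid coordinate and reject broken grids", {
  md <- grid_metadata(2, 2)
  gm <- build_gray_map(c(0, 0.4, 0.6, 1), md, n_levels = 2)
  expect_equal(gm$levels, matrix(c(0L, 0L, 1L, 1L), 2, 2, byrow = TRUE))
  # constant field -> constant map
  comps <- make_component_spectra(default_wavenumbers(n = 150))
  f <- sample_abundance_field(8, 8, 2, 0, 0.5, seed = 1)
  ds <- synthesize_map(f, comps, baseline_amplitude = 0, noise_sd = 0,
                       spike_rate = 0, seed = 1)
  md8 <- ds$metadata
  suppressWarnings(gm8 <- build_gray_map(rep(0, 64), md8, 8))
  expect_true(all(gm8$levels == gm8$levels[1, 1]))
  bad <- md[-4, ]
  expect_error(build_gray_map(c(0, 0.4, 0.6), bad, 2), "missing cell \\(1, 1\\)")
})

test_that("PC1 score maps recover the planted abundance field", {
  comps <- make_component_spectra(default_wavenumbers(n = 300))
  field <- sample_abundance_field(10, 10, 2, 0.2, 0.5, seed = 5)
  ds <- synthesize_map(field, comps, baseline_amplitude = 3e-3,
                       noise_sd = 1e-4, spike_rate = 0, seed = 5)
  pp <- preprocess_dataset(ds)
  fit <- orient_component(fit_pca(pp, q = 2))
  scaled <- scale_scores(fit$scores$scores[, 1])
  g <- as.vector(t(field$grid))
  expect_gt(abs(cor(scaled, g)), 0.95)
  # orientation makes the relationship positive
  expect_gt(cor(scaled, g), 0.95)
})

test_that("a constant intensity offset changes no gray map", {
  comps <- make_component_spectra(default_wavenumbers(n = 200))
  field <- sample_abundance_field(6, 6, 1.5, 0.15, 0.5, seed = 6)
  ds <- synthesize_map(field, comps, noise_sd = 1e-4, spike_rate = 0, seed = 6)
  shifted <- spectral_dataset(ds$wavenumbers, ds$intensities + 0.37, ds$metadata)
  maps1 <- gray_maps_from_scores(fit_pca(ds, 2))
  maps2 <- gray_maps_from_scores(fit_pca(shifted, 2))
  expect_equal(maps1[["map1"]]$levels, maps2[["map1"]]$levels)
})

test_that("RGB export scales three channels and degenerates gracefully", {
  r1 <- make_rank1_dataset(n = 20, p = 60)
  # rank-1 data: only PC1 has variance, so q = 3 is not achievable
  expect_error(fit_pca(r1$ds, q = 3), "rank")
  set.seed(7)
  noisy <- r1$ds
  noisy$intensities <- noisy$intensities + matrix(rnorm(20 * 60, sd = 1e-4), 20, 60)
  fit <- fit_pca(noisy, q = 3)
  arr <- build_rgb_map(fit, "m1")
  expect_equal(dim(arr), c(4, 5, 3))
  expect_true(all(arr >= 0 & arr <= 1))
  fit2 <- fit_pca(r1$ds, q = 1)
  expect_error(build_rgb_map(fit2, "m1"), "3 components")
})
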