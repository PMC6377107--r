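test_that("cosmic-ray removal repairs isolated and adjacent spikes", {
  y <- rep(1, 100)
  y[40] <- 100
  res <- remove_cosmic_rays(y)
  expect_equal(sum(res$spike_mask), 1)
  expect_equal(res$spectrum[40], 1, tolerance = 0.01)
  # two adjacent spikes inside one window are both flagged
  y2 <- rep(1, 100)
  y2[50:51] <- c(80, 120)
  res2 <- remove_cosmic_rays(y2)
  expect_true(all(res2$spike_mask[50:51]))
  expect_equal(sum(res2$spike_mask), 2)
  expect_equal(res2$spectrum, rep(1, 100), tolerance = 1e-12)
  # a smooth peak is untouched
  w <- seq_len(300)
  smooth <- 5 * exp(-0.5 * ((w - 150) / 30)^2) + 0.01 * w
  res3 <- remove_cosmic_rays(smooth)
  expect_identical(res3$spectrum, smooth)
  expect_false(any(res3$spike_mask))
  expect_error(remove_cosmic_rays(1:4), "shorter")
})

test_that("Savitzky-Golay smoothing reproduces polynomials and damps noise", {
  x <- seq(-1, 1, length.out = 101)
  cubic <- 2 + x - 3 * x^2 + 0.5 * x^3
  expect_equal(smooth_spectrum(cubic, 11, 3), cubic, tolerance = 1e-9)
  expect_equal(smooth_spectrum(rep(2, 50), 11, 3), rep(2, 50), tolerance = 1e-12)
  set.seed(42)
  noise <- rnorm(500)
  expect_lt(var(smooth_spectrum(noise, 11, 3)), var(noise))
  expect_error(smooth_spectrum(1:5, 11, 3), "exceeds")
})

test_that("matrix smoothing operator equals signal::sgolayfilt", {
  set.seed(1)
  y <- cumsum(rnorm(207))
  S <- ramantex:::sgolay_operator(207, 11, 3)
  expect_equal(as.numeric(S %*% y),
               as.numeric(signal::sgolayfilt(y, p = 3, n = 11)),
               tolerance = 1e-10)
})

test_that("ALS baseline hugs peakless signals and preserves planted peaks", {
  ramp <- seq(0, 10, length.out = 400)
  z <- als_baseline(ramp)
  expect_lt(max(abs(ramp - z)), 0.01 * diff(range(ramp)))
  # ramp + tall Gaussian (height 10x ramp span, FWHM 10 channels): the
  # corrected signal keeps the peak, the off-peak residual is small
  x <- seq_len(400)
  sigma <- 10 / (2 * sqrt(2 * log(2)))
  peak <- 100 * exp(-0.5 * ((x - 200) / sigma)^2)
  y <- ramp + peak
  corrected <- y - als_baseline(y)
  expect_equal(max(corrected), 100, tolerance = 0.1)
  off <- abs(x - 200) > 40
  expect_lt(max(abs(corrected[off])), 0.02 * 100)
  expect_error(als_baseline(c(1, NA, 3)), "finite")
})

test_that("banded ALS agrees with a dense reference solver", {
  set.seed(5)
  for (lambda_log10 in c(2, 4, 6)) {
    y <- cumsum(rnorm(150)) + 30 * exp(-0.5 * ((seq_len(150) - 60) / 5)^2)
    ours <- als_baseline(y, als_lambda_log10 = lambda_log10)
    ref <- oracle_als(y, 10^lambda_log10, 0.05)
    expect_equal(ours, ref$baseline, tolerance = 1e-8)
  }
})

test_that("very large lambda drives the ALS baseline to a weighted line", {
  set.seed(8)
  y <- cumsum(rnorm(200)) + seq(0, 5, length.out = 200)
  z <- als_baseline(y, als_lambda_log10 = 12)
  # independent check: asymmetric weighted straight-line fit using the
  # converged weights of the dense reference
  ref <- oracle_als(y, 1e12, 0.05)
  x <- seq_along(y)
  line <- stats::lm(y ~ x, weights = ref$weights)
  expect_lt(max(abs(z - stats::fitted(line))), 1e-3 * diff(range(y)))
})

test_that("volume normalization yields unit integrals and scale invariance", {
  w <- default_wavenumbers(n = 120)
  y <- exp(-0.5 * ((w - 900) / 50)^2) + 0.1
  n1 <- normalize_volume(y, w)
  expect_lt(abs(pracma::trapz(w, n1) - 1), 1e-9)
  expect_equal(normalize_volume(n1, w), n1, tolerance = 1e-12)
  expect_equal(normalize_volume(5 * y, w), n1, tolerance = 1e-12)
  expect_error(normalize_volume(-y, w), "nonpositive")
})

test_that("the full chain recovers planted mixtures and unit areas", {
  comps <- make_component_spectra(default_wavenumbers(n = 300))
  field <- sample_abundance_field(6, 6, 1.5, 0.15, 0.5, seed = 2)
  ds <- synthesize_map(field, comps, baseline_amplitude = 5e-3, noise_sd = 0,
                       spike_rate = 0, seed = 2)
  pp <- preprocess_dataset(ds)
  w <- pp$wavenumbers
  g <- as.vector(t(field$grid))
  for (i in seq_len(nrow(pp$intensities))) {
    expect_lt(abs(pracma::trapz(w, pp$intensities[i, ]) - 1), 1e-9)
    planted <- g[i] * comps$glycogen$intensities +
      (1 - g[i]) * comps$matrix$intensities
    expect_gt(cor(pp$intensities[i, ], planted), 0.99)
  }
})

test_that("preprocessing handles empty datasets and logs spikes per map", {
  empty <- spectral_dataset(default_wavenumbers(n = 50),
                            matrix(0, 0, 50),
                            grid_metadata(1, 1)[0, ])
  out <- preprocess_dataset(empty)
  expect_equal(nrow(out$intensities), 0)
  expect_length(attr(out, "spike_counts"), 0)

  # clean and spiked maps share every non-spike random draw under one seed,
  # so successful spike repair makes their processed spectra nearly coincide
  comps <- make_component_spectra(default_wavenumbers(n = 200))
  field <- sample_abundance_field(3, 3, 1.5, 0.1, 0.5, seed = 4)
  clean <- synthesize_map(field, comps, noise_sd = 2e-4, spike_rate = 0, seed = 4)
  spiked <- synthesize_map(field, comps, noise_sd = 2e-4, spike_rate = 2, seed = 4)
  expect_gt(max(abs(clean$intensities - spiked$intensities)), 0.01)
  pp_clean <- preprocess_dataset(clean)
  pp_spiked <- preprocess_dataset(spiked)
  expect_named(attr(pp_spiked, "spike_counts"), "map1")
  expect_gt(attr(pp_spiked, "spike_counts")[["map1"]], 0)
  expect_lt(max(abs(pp_clean$intensities - pp_spiked$intensities)),
            0.05 * max(pp_clean$intensities))
})

test_that("the un-normalized chain annihilates peakless spectra idempotently", {
  # a straight line is all baseline: spike removal and smoothing leave it
  # unchanged and ALS absorbs it entirely, so the corrected signal is zero
  # and stays zero on a second pass
  w <- default_wavenumbers(n = 200)
  y <- 2 + 0.004 * (w - 400)
  chain <- function(v) {
    v <- remove_cosmic_rays(v)$spectrum
    v <- smooth_spectrum(v)
    v - als_baseline(v)
  }
  once <- chain(y)
  expect_lt(max(abs(once)), 1e-6 * diff(range(y)))
  expect_lt(max(abs(chain(once + 1))), 1e-6)  # shifted to keep it peakless
})

test_that("baseline subtraction does not create new spike flags", {
  # the baseline is smooth, so removing it cannot push residuals from the
  # running median over the spike threshold: flag counts per spectrum never
  # grow across the subtraction step
  comps <- make_component_spectra(default_wavenumbers(n = 250))
  field <- sample_abundance_field(4, 4, 1.5, 0.1, 0.5, seed = 6)
  ds <- synthesize_map(field, comps, noise_sd = 3e-4, spike_rate = 1, seed = 6)
  for (i in seq_len(nrow(ds$intensities))) {
    y <- smooth_spectrum(remove_cosmic_rays(ds$intensities[i, ])$spectrum)
    before <- sum(remove_cosmic_rays(y)$spike_mask)
    after <- sum(remove_cosmic_rays(y - als_baseline(y))$spike_mask)
    expect_lte(after, before)
  }
})
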