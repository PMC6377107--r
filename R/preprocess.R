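#' Preprocessing configuration
#'
#' Parameters for the four-step spectral processing chain applied by
#' [preprocess_dataset()]: cosmic-ray spike removal, Savitzky-Golay smoothing,
#' asymmetric least squares (ALS) baseline subtraction, volume normalization.
#'
#' @param spike_k_mad Spike detection threshold, in multiples of the MAD of
#'   running-median residuals.
#' @param spike_window Odd running-median window (channels).
#' @param smooth_window Odd Savitzky-Golay window (channels).
#' @param smooth_polyorder Savitzky-Golay polynomial order
#'   (`< smooth_window`).
#' @param als_lambda_log10 ALS second-derivative smoothness on the log10
#'   scale; the penalty used is `10^als_lambda_log10` (default 4, i.e.
#'   lambda = 10^4). Set `als_lambda_scale = "linear"` to use the value as
#'   given.
#' @param als_lambda_scale `"log10"` (default) or `"linear"`.
#' @param als_p ALS asymmetry in (0, 1): weight on points above the baseline.
#' @param als_max_iter,als_tol ALS iteration controls.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(spike_k_mad = 8, spike_window = 5,
                              smooth_window = 11, smooth_polyorder = 3,
                              als_lambda_log10 = 4,
                              als_lambda_scale = c("log10", "linear"),
                              als_p = 0.05, als_max_iter = 20,
                              als_tol = 1e-6) {
  als_lambda_scale <- match.arg(als_lambda_scale)
  if (spike_k_mad <= 0) stopf("`spike_k_mad` must be positive")
  if (!is_count(spike_window, 3) || spike_window %% 2 == 0) {
    stopf("`spike_window` must be an odd integer >= 3")
  }
  if (!is_count(smooth_window, 3) || smooth_window %% 2 == 0) {
    stopf("`smooth_window` must be an odd integer >= 3")
  }
  if (!is_count(smooth_polyorder, 0) || smooth_polyorder >= smooth_window) {
    stopf("`smooth_polyorder` must be a nonnegative integer < smooth_window")
  }
  if (als_p <= 0 || als_p >= 1) stopf("`als_p` must lie in (0, 1)")
  if (als_tol <= 0) stopf("`als_tol` must be positive")
  structure(list(
    spike_k_mad = spike_k_mad, spike_window = as.integer(spike_window),
    smooth_window = as.integer(smooth_window),
    smooth_polyorder = as.integer(smooth_polyorder),
    als_lambda_log10 = als_lambda_log10, als_lambda_scale = als_lambda_scale,
    als_p = als_p, als_max_iter = as.integer(als_max_iter), als_tol = als_tol
  ), class = "preprocess_config")
}

#' @noRd
als_lambda_value <- function(config) {
  if (config$als_lambda_scale == "linear") config$als_lambda_log10
  else 10^config$als_lambda_log10
}

#' Detect and repair cosmic-ray spikes in one spectrum
#'
#' Channels whose residual from a running median (window `spike_window`)
#' exceeds `spike_k_mad` times the MAD of all residuals are flagged as
#' cosmic-ray spikes and replaced by linear interpolation between the nearest
#' non-spike neighbours. Only positive excursions are flagged (cosmic rays add
#' counts). The MAD is floored by the first-difference robust noise estimate
#' `mad(diff(y)) / sqrt(2)` so that smooth noise-free spectra are never
#' flagged wholesale.
#'
#' @param spectrum Numeric vector.
#' @param spike_k_mad,spike_window See [preprocess_config()].
#' @return List with `spectrum` (repaired) and `spike_mask` (logical).
#' @export
remove_cosmic_rays <- function(spectrum, spike_k_mad = 8, spike_window = 5) {
  y <- as.numeric(spectrum)
  n <- length(y)
  if (n <= spike_window) stopf("spectrum shorter than the spike window")
  resid <- y - stats::runmed(y, spike_window, endrule = "median")
  # robust noise scale: MAD of the running-median residuals, floored by the
  # first-difference noise estimate so smooth noise-free peaks (where the
  # residual MAD degenerates to zero) are not flagged; both terms are
  # invariant under subtraction of a smooth baseline
  scale <- max(stats::mad(resid), stats::mad(diff(y)) / sqrt(2))
  mask <- resid > spike_k_mad * scale & resid > 0
  if (all(mask)) stopf("every channel flagged as a spike; input unusable")
  if (any(mask)) {
    keep <- which(!mask)
    y[mask] <- stats::approx(keep, y[keep], xout = which(mask), rule = 2)$y
  }
  list(spectrum = y, spike_mask = mask)
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial smoothing; reproduces polynomials up to
#' `smooth_polyorder` exactly and preserves the spectrum length.
#'
#' @param spectrum Numeric vector.
#' @param smooth_window,smooth_polyorder See [preprocess_config()].
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_spectrum <- function(spectrum, smooth_window = 11, smooth_polyorder = 3) {
  y <- as.numeric(spectrum)
  if (smooth_window > length(y)) stopf("smoothing window exceeds spectrum length")
  if (smooth_polyorder >= smooth_window) stopf("polynomial order must be < window")
  as.numeric(signal::sgolayfilt(y, p = smooth_polyorder, n = smooth_window))
}

#' Sparse smoothing operator equivalent to signal::sgolayfilt for length p,
#' so a whole spectra matrix can be smoothed with one multiplication.
#' @noRd
sgolay_operator <- function(p_len, smooth_window, smooth_polyorder) {
  FM <- signal::sgolay(p = smooth_polyorder, n = smooth_window)
  FM <- unclass(FM)
  half <- (smooth_window - 1L) %/% 2L
  S <- matrix(0, p_len, p_len)
  center <- FM[half + 1L, ]
  for (i in seq_len(p_len)) {
    if (i <= half) {
      S[i, 1:smooth_window] <- FM[i, ]
    } else if (i > p_len - half) {
      S[i, (p_len - smooth_window + 1L):p_len] <- FM[smooth_window - (p_len - i), ]
    } else {
      S[i, (i - half):(i + half)] <- center
    }
  }
  S
}

#' Estimate an ALS baseline for one spectrum
#'
#' Iteratively reweighted Whittaker smoothing with asymmetric weights:
#' minimises `sum w_i (y_i - z_i)^2 + lambda * sum (diff(z, 2))^2` where
#' `w_i = als_p` when `y_i > z_i` (point treated as peak) and `1 - als_p`
#' otherwise, so the smooth curve `z` hugs the lower envelope of the
#' spectrum — the fluorescence background of a Raman measurement.
#'
#' @param spectrum Finite numeric vector (length >= 3).
#' @param als_lambda_log10,als_lambda_scale,als_p,als_max_iter,als_tol See
#'   [preprocess_config()].
#' @return The estimated baseline (same length as `spectrum`).
#' @export
als_baseline <- function(spectrum, als_lambda_log10 = 4,
                         als_lambda_scale = c("log10", "linear"),
                         als_p = 0.05, als_max_iter = 20, als_tol = 1e-6) {
  als_lambda_scale <- match.arg(als_lambda_scale)
  y <- as.numeric(spectrum)
  if (any(!is.finite(y))) stopf("spectrum contains non-finite values")
  if (als_p <= 0 || als_p >= 1) stopf("`als_p` must lie in (0, 1)")
  lambda <- if (als_lambda_scale == "linear") als_lambda_log10 else 10^als_lambda_log10
  als_baseline_cpp(y, lambda, als_p, as.integer(als_max_iter), als_tol)
}

#' Volume-normalize a spectrum
#'
#' Divides a spectrum by its trapezoidal integral over the wavenumber axis so
#' spectra are comparable in shape regardless of absolute signal level; the
#' output integrates to 1.
#'
#' @param spectrum Numeric vector.
#' @param wavenumbers Matching strictly increasing axis.
#' @return Normalized spectrum with unit trapezoidal integral.
#' @export
normalize_volume <- function(spectrum, wavenumbers) {
  y <- as.numeric(spectrum)
  w <- as.numeric(wavenumbers)
  if (length(y) != length(w)) stopf("spectrum and axis lengths differ")
  area_pos <- pracma::trapz(w, pmax(y, 0))
  area <- pracma::trapz(w, y)
  if (!is.finite(area) || area_pos <= 0 || area <= 0) {
    stopf("spectrum has nonpositive integrated intensity; cannot volume-normalize")
  }
  y / area
}

#' Apply the full preprocessing chain to a dataset
#'
#' Runs, per spectrum and in this order: cosmic-ray spike removal,
#' Savitzky-Golay smoothing, ALS baseline subtraction, volume normalization.
#' Metadata pass through unchanged. Negative intensities left by baseline
#' subtraction are retained (clipping would bias the downstream PCA); only the
#' normalization guard inspects the positive part.
#'
#' @param ds A [spectral_dataset()].
#' @param config A [preprocess_config()].
#' @return A preprocessed [spectral_dataset()]; per-map spike counts are
#'   attached as attribute `"spike_counts"` (named integer vector).
#' @export
preprocess_dataset <- function(ds, config = preprocess_config()) {
  validate_spectral_dataset(ds)
  if (!inherits(config, "preprocess_config")) config <- do.call(preprocess_config, config)
  X <- ds$intensities
  n <- nrow(X)
  if (n == 0L) {
    out <- ds
    attr(out, "spike_counts") <- integer(0)
    return(out)
  }
  w <- ds$wavenumbers
  p <- ncol(X)
  row_label <- function(i) {
    sprintf("spectrum %d (map '%s', cell (%d, %d))", i, ds$metadata$map_id[i],
            ds$metadata$grid_row[i], ds$metadata$grid_col[i])
  }
  # 1. cosmic-ray removal (per spectrum)
  spikes <- integer(n)
  i <- 0L
  tryCatch(
    for (i in seq_len(n)) {
      res <- remove_cosmic_rays(X[i, ], config$spike_k_mad, config$spike_window)
      X[i, ] <- res$spectrum
      spikes[i] <- sum(res$spike_mask)
    },
    error = function(e) stopf("%s: %s", row_label(i), conditionMessage(e))
  )
  # 2. Savitzky-Golay smoothing (one sparse operator for the whole matrix)
  if (config$smooth_window > p) stopf("smoothing window exceeds spectrum length")
  S <- sgolay_operator(p, config$smooth_window, config$smooth_polyorder)
  X <- tcrossprod(X, S)
  # 3. ALS baseline subtraction
  Z <- als_baseline_mat_cpp(X, als_lambda_value(config), config$als_p,
                            config$als_max_iter, config$als_tol)
  X <- X - Z
  # 4. volume normalization (vectorized composite-trapezoid weights)
  tw <- c(diff(w)[1] / 2, (w[-(1:2)] - w[seq_len(p - 2)]) / 2,
          diff(w)[p - 1] / 2)
  areas <- as.vector(X %*% tw)
  areas_pos <- as.vector(pmax(X, 0) %*% tw)
  bad <- which(!is.finite(areas) | areas <= 0 | areas_pos <= 0)
  if (length(bad)) {
    stopf("%s: nonpositive integrated intensity; cannot volume-normalize",
          row_label(bad[1L]))
  }
  X <- X / areas
  out <- spectral_dataset(w, X, ds$metadata, validate = FALSE)
  per_map <- tapply(spikes, ds$metadata$map_id, sum)
  attr(out, "spike_counts") <- setNames(as.integer(per_map), names(per_map))
  out
}
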