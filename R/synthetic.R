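#' Default wavenumber axis for synthetic spectra
#'
#' @param from,to Axis span in cm^-1.
#' @param n Number of points.
#' @return Strictly increasing numeric vector.
#' @export
default_wavenumbers <- function(from = 400, to = 1800, n = 700) {
  if (!is_count(n, 2)) stopf("`n` must be an integer >= 2")
  seq(from, to, length.out = n)
}

#' Default peak tables for the two synthetic tissue components
#'
#' The glycogen-like component places its dominant bands near 490, 850 and
#' 1050 cm^-1 (the bands that discriminate glycogen in tumour Raman spectra);
#' the matrix-like component carries generic protein/lipid bands
#' (phenylalanine ring breathing near 1004, CH2 deformation near 1450,
#' amide I near 1660 cm^-1).
#'
#' @return Named list of data frames with columns `center`, `width`, `height`.
#' @export
default_peak_spec <- function() {
  list(
    glycogen = data.frame(
      center = c(490, 850, 1050, 1340),
      width  = c(18, 12, 14, 22),
      height = c(1.0, 0.95, 0.85, 0.30)
    ),
    matrix = data.frame(
      center = c(622, 1004, 1260, 1450, 1660),
      width  = c(12, 8, 28, 20, 24),
      height = c(0.25, 0.70, 0.45, 0.80, 1.0)
    )
  )
}

#' Build unit-area component spectra from Gaussian peak tables
#'
#' Each component is a sum of Gaussian peaks on the shared axis, normalized to
#' unit trapezoidal area so that mixtures of components are on a common
#' intensity scale.
#'
#' @param wavenumbers Strictly increasing axis (cm^-1).
#' @param peak_spec Named list of data frames with columns `center`, `width`
#'   (Gaussian sigma, cm^-1, positive) and `height`; one entry per component.
#' @return Named list of `component_spectrum` objects (fields `wavenumbers`,
#'   `intensities`, `label`).
#' @export
make_component_spectra <- function(wavenumbers = default_wavenumbers(),
                                   peak_spec = default_peak_spec()) {
  w <- as.numeric(wavenumbers)
  if (length(w) < 2L) stopf("wavenumber axis must have at least 2 points")
  if (any(diff(w) <= 0)) stopf("wavenumbers must be strictly increasing")
  if (!is.list(peak_spec) || is.null(names(peak_spec)) || any(names(peak_spec) == "")) {
    stopf("`peak_spec` must be a named list of peak tables")
  }
  lapply(setNames(names(peak_spec), names(peak_spec)), function(lab) {
    pk <- peak_spec[[lab]]
    if (!all(c("center", "width", "height") %in% names(pk)) || nrow(pk) < 1L) {
      stopf("peak table for '%s' needs columns center, width, height", lab)
    }
    if (any(pk$width <= 0)) stopf("peak widths must be positive (component '%s')", lab)
    if (any(pk$height < 0)) stopf("peak heights must be nonnegative (component '%s')", lab)
    y <- rep(0, length(w))
    for (i in seq_len(nrow(pk))) {
      y <- y + pk$height[i] * exp(-0.5 * ((w - pk$center[i]) / pk$width[i])^2)
    }
    area <- pracma::trapz(w, y)
    if (area <= 0) stopf("component '%s' has zero area", lab)
    structure(list(wavenumbers = w, intensities = y / area, label = lab),
              class = "component_spectrum")
  })
}

#' Sample a spatially correlated abundance field
#'
#' Gaussian white noise smoothed with a separable Gaussian kernel of scale
#' `correlation_length` (pixels), rescaled to the requested mean and standard
#' deviation (`heterogeneity`), then clipped to `[0, 1]`. The field stands in
#' for the spatial distribution of relative glycogen abundance over a map;
#' `heterogeneity` is the tunable spatial-variability dial the dose effect
#' acts on.
#'
#' @param rows,cols Grid dimensions (>= 2).
#' @param correlation_length Kernel sigma in pixels (>= 0; 0 = white noise).
#' @param heterogeneity Target field standard deviation before clipping (>= 0;
#'   0 yields a constant field at `mean`).
#' @param mean Target field mean (typically in `[0, 1]`).
#' @param seed Integer seed; identical seeds give identical fields.
#' @return An `abundance_field`: list with `grid` (rows x cols matrix in
#'   `[0, 1]`), `correlation_length`, `heterogeneity`.
#' @export
sample_abundance_field <- function(rows, cols, correlation_length = 1.5,
                                   heterogeneity = 0.1, mean = 0.5,
                                   seed = NULL) {
  if (!is_count(rows, 2) || !is_count(cols, 2)) stopf("`rows` and `cols` must be integers >= 2")
  if (!is.numeric(heterogeneity) || heterogeneity < 0) stopf("`heterogeneity` must be >= 0")
  if (!is.numeric(correlation_length) || correlation_length < 0) {
    stopf("`correlation_length` must be >= 0")
  }
  grid <- with_seed(seed, {
    if (heterogeneity == 0) {
      matrix(mean, rows, cols)
    } else {
      # pad so kernel support does not wrap or starve at the borders
      half <- max(1L, ceiling(3 * correlation_length))
      z <- matrix(rnorm((rows + 2L * half) * (cols + 2L * half)),
                  rows + 2L * half, cols + 2L * half)
      if (correlation_length > 0) {
        k <- exp(-0.5 * ((-half):half / correlation_length)^2)
        k <- k / sum(k)
        # separable convolution: rows then columns
        z <- apply(z, 2, function(col) stats::filter(col, k, sides = 2))
        z <- t(apply(z, 1, function(row) stats::filter(row, k, sides = 2)))
      }
      core <- z[half + seq_len(rows), half + seq_len(cols), drop = FALSE]
      s <- stats::sd(as.vector(core))
      if (s == 0) {
        matrix(mean, rows, cols)
      } else {
        g <- (core - base::mean(core)) / s * heterogeneity + mean
        pmin(pmax(g, 0), 1)
      }
    }
  })
  structure(list(grid = grid, correlation_length = correlation_length,
                 heterogeneity = heterogeneity),
            class = "abundance_field")
}

#' Synthesize one Raman map from an abundance field
#'
#' Per pixel with abundance `g`, the spectrum is the two-component mixture
#' `g * S_glycogen + (1 - g) * S_matrix`, plus a smooth additive quadratic
#' baseline (emulating fluorescence background), i.i.d. Gaussian channel
#' noise, and Poisson-placed single-channel positive spikes (emulating cosmic
#' rays; spike height >= 20x the noise scale so the spike-removal stage has a
#' well-separated target).
#'
#' @param field An [sample_abundance_field()] result (values used as `g`).
#' @param components List with elements `glycogen` and `matrix` from
#'   [make_component_spectra()], on one shared axis.
#' @param baseline_amplitude Scale of the additive quadratic baseline (same
#'   units as the unit-area component intensities; 0 disables).
#' @param noise_sd Gaussian channel noise standard deviation (0 disables).
#' @param spike_rate Expected number of cosmic-ray spikes per spectrum.
#' @param seed Integer seed.
#' @param map_id,mouse_id,dose_gy,pixel_size_um Metadata carried on each row.
#' @return A [spectral_dataset()] block of `rows*cols` spectra.
#' @export
synthesize_map <- function(field, components, baseline_amplitude = 5e-3,
                           noise_sd = 5e-4, spike_rate = 0.05, seed = NULL,
                           map_id = "map1", mouse_id = "mouse1", dose_gy = 0,
                           pixel_size_um = 15) {
  if (!inherits(field, "abundance_field")) stopf("`field` must be an abundance_field")
  if (!all(c("glycogen", "matrix") %in% names(components))) {
    stopf("`components` must contain 'glycogen' and 'matrix' spectra")
  }
  w <- components$glycogen$wavenumbers
  if (!isTRUE(all.equal(w, components$matrix$wavenumbers))) {
    stopf("component spectra are on different wavenumber axes")
  }
  if (noise_sd < 0 || spike_rate < 0) stopf("`noise_sd` and `spike_rate` must be >= 0")
  g <- as.vector(t(field$grid))           # row-major: row 0 first
  npx <- length(g)
  p <- length(w)
  sg <- components$glycogen$intensities
  sm <- components$matrix$intensities
  X <- with_seed(seed, {
    X <- outer(g, sg) + outer(1 - g, sm)
    if (baseline_amplitude > 0) {
      u <- (w - w[1]) / (w[p] - w[1])
      # gently decaying quadratic background, random per-pixel coefficients
      a <- matrix(runif(3 * npx, 0.2, 1), npx, 3)
      X <- X + baseline_amplitude *
        (a[, 1] + a[, 2] * (1 - u[col(X)]) + a[, 3] * (1 - u[col(X)])^2) / 3
    }
    if (noise_sd > 0) X <- X + matrix(rnorm(npx * p, sd = noise_sd), npx, p)
    if (spike_rate > 0) {
      nspikes <- rpois(npx, spike_rate)
      ref <- if (noise_sd > 0) noise_sd else 0.05 * max(abs(X))
      for (i in which(nspikes > 0)) {
        ch <- sample.int(p, nspikes[i])
        X[i, ch] <- X[i, ch] + (20 + stats::rexp(nspikes[i], 1 / 10)) * ref
      }
    }
    X
  })
  nr <- nrow(field$grid); nc <- ncol(field$grid)
  md <- data.frame(
    map_id = map_id, mouse_id = mouse_id, dose_gy = dose_gy,
    grid_row = rep(0:(nr - 1L), each = nc),
    grid_col = rep(0:(nc - 1L), times = nr),
    stringsAsFactors = FALSE
  )
  spectral_dataset(w, X, md)
}

#' Describe a multi-mouse Raman mapping study design
#'
#' Defaults emulate a three-arm murine irradiation study: doses 0, 5 and
#' 15 Gy, four mice per dose, five to eight maps per mouse on a mixture of
#' 8x8 and 14x14 grids. The dose effect is planted in the abundance field's
#' spatial heterogeneity (its standard deviation), not its mean, with a small
#' multiplicative mouse-level jitter.
#'
#' @param doses_gy Dose levels (Gy).
#' @param mice_per_dose Mice in each arm.
#' @param maps_per_mouse Length-2 integer range; each mouse's map count is
#'   drawn uniformly from it.
#' @param grid_shapes List of `c(rows, cols)` shapes sampled per map.
#' @param grid_probs Sampling probabilities for `grid_shapes`.
#' @param effect Named numeric: heterogeneity (field sd) by dose; names must
#'   cover `doses_gy`.
#' @param mouse_sd Standard deviation of the lognormal mouse-level
#'   multiplicative jitter on heterogeneity.
#' @param mean_abundance,correlation_length Field parameters passed through.
#' @param baseline_amplitude,noise_sd,spike_rate Per-map nuisance parameters.
#' @param wavenumbers Shared axis.
#' @param seed Integer seed for the whole study.
#' @return A `study_design` list.
#' @export
study_design <- function(doses_gy = c(0, 5, 15),
                         mice_per_dose = 4,
                         maps_per_mouse = c(5, 8),
                         grid_shapes = list(c(8, 8), c(14, 14)),
                         grid_probs = c(0.5, 0.5),
                         effect = c("0" = 0.05, "5" = 0.065, "15" = 0.065),
                         mouse_sd = 0.05,
                         mean_abundance = 0.5,
                         correlation_length = 1.5,
                         baseline_amplitude = 5e-3,
                         noise_sd = 5e-4,
                         spike_rate = 0.05,
                         wavenumbers = default_wavenumbers(),
                         seed = 1L) {
  if (!is_count(mice_per_dose)) stopf("`mice_per_dose` must be a positive integer")
  # normalize shapes that may arrive as YAML lists
  doses_gy <- as.numeric(unlist(doses_gy))
  maps_per_mouse <- as.integer(unlist(maps_per_mouse))
  grid_shapes <- lapply(grid_shapes, function(s) as.integer(unlist(s)))
  grid_probs <- as.numeric(unlist(grid_probs))
  effect <- unlist(effect)
  wavenumbers <- as.numeric(unlist(wavenumbers))
  if (length(maps_per_mouse) == 1L) maps_per_mouse <- rep(maps_per_mouse, 2L)
  if (length(maps_per_mouse) != 2L || maps_per_mouse[1] > maps_per_mouse[2] ||
      !is_count(maps_per_mouse[1])) {
    stopf("`maps_per_mouse` must be a nondecreasing integer range c(lo, hi)")
  }
  missing_dose <- setdiff(as.character(doses_gy), names(effect))
  if (length(missing_dose)) {
    stopf("`effect` has no entry for dose(s): %s", paste(missing_dose, collapse = ", "))
  }
  if (length(grid_probs) != length(grid_shapes)) stopf("`grid_probs` length mismatch")
  structure(list(
    doses_gy = doses_gy, mice_per_dose = mice_per_dose,
    maps_per_mouse = maps_per_mouse, grid_shapes = grid_shapes,
    grid_probs = grid_probs, effect = effect, mouse_sd = mouse_sd,
    mean_abundance = mean_abundance, correlation_length = correlation_length,
    baseline_amplitude = baseline_amplitude, noise_sd = noise_sd,
    spike_rate = spike_rate, wavenumbers = wavenumbers, seed = seed
  ), class = "study_design")
}

#' Simulate a complete multi-mouse Raman mapping study
#'
#' Draws each map's heterogeneity from `design$effect[dose] * mouse jitter`,
#' samples an abundance field per map, and synthesizes all spectra onto one
#' shared axis. Fully deterministic given the design (including its seed).
#'
#' @param design A [study_design()].
#' @return A [spectral_dataset()]; its `metadata` identifies dose, mouse, map
#'   and grid cell for every spectrum. The per-map design table is attached as
#'   attribute `"map_table"`.
#' @export
synthesize_study <- function(design = study_design()) {
  if (!inherits(design, "study_design")) design <- do.call(study_design, design)
  comps <- make_component_spectra(design$wavenumbers)
  n_mice <- length(design$doses_gy) * design$mice_per_dose
  plan <- with_seed(design$seed, {
    rows <- list()
    mouse_idx <- 0L
    for (dose in design$doses_gy) {
      for (m in seq_len(design$mice_per_dose)) {
        mouse_idx <- mouse_idx + 1L
        mouse_id <- sprintf("mouse%02d", mouse_idx)
        jitter <- exp(rnorm(1, 0, design$mouse_sd))
        map_counts <- seq(design$maps_per_mouse[1], design$maps_per_mouse[2])
        n_maps <- map_counts[sample.int(length(map_counts), 1L)]
        for (k in seq_len(n_maps)) {
          shape <- design$grid_shapes[[
            sample.int(length(design$grid_shapes), 1L, prob = design$grid_probs)]]
          rows[[length(rows) + 1L]] <- data.frame(
            mouse_id = mouse_id, dose_gy = dose,
            rows = shape[1], cols = shape[2],
            heterogeneity = design$effect[[as.character(dose)]] * jitter,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    do.call(rbind, rows)
  })
  plan$map_id <- sprintf("map%03d", seq_len(nrow(plan)))
  seeds <- derive_seeds(design$seed, 2L * nrow(plan))
  blocks <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    field <- sample_abundance_field(
      plan$rows[i], plan$cols[i],
      correlation_length = design$correlation_length,
      heterogeneity = plan$heterogeneity[i],
      mean = design$mean_abundance,
      seed = seeds[2L * i - 1L]
    )
    blocks[[i]] <- synthesize_map(
      field, comps,
      baseline_amplitude = design$baseline_amplitude,
      noise_sd = design$noise_sd, spike_rate = design$spike_rate,
      seed = seeds[2L * i],
      map_id = plan$map_id[i], mouse_id = plan$mouse_id[i],
      dose_gy = plan$dose_gy[i],
      pixel_size_um = if (plan$rows[i] >= 14) 20 else 15
    )
  }
  ds <- bind_spectral(blocks)
  attr(ds, "map_table") <- plan
  ds
}
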