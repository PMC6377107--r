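#' Fit a principal component model to a spectral dataset
#'
#' Mean-centers the spectra and computes the leading `q` principal components
#' via an eigendecomposition of the sample covariance. Loadings are returned
#' as orthonormal rows; scores are the centered data projected onto them.
#' `explained_fraction[k]` is the variance of score `k` over the total
#' variance of the data.
#'
#' @param ds A preprocessed [spectral_dataset()] with `n >= 2` spectra.
#' @param q Number of components (`<= min(n - 1, p)` achievable rank).
#' @return List with `model` (class `pca_model`: `loadings` q x p,
#'   `mean_spectrum`, `explained_fraction`, `wavenumbers`) and `scores`
#'   (class `score_matrix`: `scores` n x q, `metadata`).
#' @export
fit_pca <- function(ds, q = 3) {
  validate_spectral_dataset(ds)
  X <- ds$intensities
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stopf("PCA needs at least 2 spectra")
  if (!is_count(q)) stopf("`q` must be a positive integer")
  if (q > min(n, p)) stopf("`q` = %d exceeds min(n, p) = %d", q, min(n, p))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  CV <- crossprod(Xc) / (n - 1)
  eg <- eigen(CV, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  total <- sum(ev)
  rank_eff <- sum(ev > max(ev[1], .Machine$double.eps) * 1e-12)
  if (q > rank_eff) {
    stopf("`q` = %d exceeds the achievable rank %d of the centered data", q, rank_eff)
  }
  V <- eg$vectors[, seq_len(q), drop = FALSE]
  # deterministic sign: largest-magnitude loading entry is positive
  for (k in seq_len(q)) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  scores <- Xc %*% V
  model <- structure(list(
    loadings = t(V), mean_spectrum = mu,
    explained_fraction = if (total > 0) ev[seq_len(q)] / total else rep(0, q),
    wavenumbers = ds$wavenumbers
  ), class = "pca_model")
  sm <- structure(list(scores = scores, metadata = ds$metadata),
                  class = "score_matrix")
  list(model = model, scores = sm)
}

#' Fix a principal component's sign against a reference band
#'
#' The sign of a principal component is arbitrary; this orients a component
#' so that a positive score means a stronger signal in a reference wavenumber
#' window (default 840-860 cm^-1, inside the 850 cm^-1 glycogen band, so
#' "high PC1 score" reads as "high glycogen"). If the mean loading over the
#' window is negative, the loading row and its scores are negated.
#' Idempotent.
#'
#' @param fit The list returned by [fit_pca()].
#' @param component 1-based component index.
#' @param reference_window Length-2 wavenumber interval (cm^-1).
#' @return `fit` with the component (and its scores) possibly negated.
#' @export
orient_component <- function(fit, component = 1L,
                             reference_window = c(840, 860)) {
  model <- fit$model
  w <- model$wavenumbers
  if (length(reference_window) != 2L || reference_window[1] >= reference_window[2]) {
    stopf("`reference_window` must be an increasing length-2 interval")
  }
  sel <- w >= reference_window[1] & w <= reference_window[2]
  if (!any(sel)) {
    stopf("reference window [%g, %g] contains no axis points",
          reference_window[1], reference_window[2])
  }
  if (!is_count(component) || component > nrow(model$loadings)) {
    stopf("`component` out of range")
  }
  if (mean(model$loadings[component, sel]) < 0) {
    fit$model$loadings[component, ] <- -model$loadings[component, ]
    fit$scores$scores[, component] <- -fit$scores$scores[, component]
  }
  fit
}

#' Min-max scale PC scores to [0, 1]
#'
#' `mode = "global"` uses one minimum and maximum over all rows (gray tones
#' comparable across maps, the default); `mode = "per_map"` rescales within
#' each `map_id`. Constant input (zero range) maps to 0 with a warning.
#'
#' @param scores Numeric vector of scores for one component.
#' @param mode `"global"` or `"per_map"`.
#' @param map_id Required for `mode = "per_map"`: map identifier per score.
#' @return Numeric vector in `[0, 1]`.
#' @export
scale_scores <- function(scores, mode = c("global", "per_map"), map_id = NULL) {
  mode <- match.arg(mode)
  x <- as.numeric(scores)
  if (length(x) == 0L) return(numeric(0))
  rescale <- function(v, label) {
    rng <- range(v)
    if (rng[1] == rng[2]) {
      warning(sprintf("constant scores%s; scaled to 0", label), call. = FALSE)
      rep(0, length(v))
    } else {
      (v - rng[1]) / (rng[2] - rng[1])
    }
  }
  if (mode == "global") {
    rescale(x, "")
  } else {
    if (is.null(map_id) || length(map_id) != length(x)) {
      stopf("`map_id` must accompany per_map scaling")
    }
    out <- numeric(length(x))
    for (m in unique(map_id)) {
      i <- map_id == m
      out[i] <- rescale(x[i], sprintf(" in map '%s'", m))
    }
    out
  }
}

#' Discretize [0, 1] scores into integer gray levels
#'
#' Uniform bins `[k/N_g, (k+1)/N_g)` for `k < N_g - 1`; the last bin is closed
#' at 1, so outputs lie in `0 .. n_levels - 1`.
#'
#' @param scaled_scores Numeric values in `[0, 1]`.
#' @param n_levels Number of gray levels `N_g >= 2`.
#' @return Integer vector of levels.
#' @export
discretize_scores <- function(scaled_scores, n_levels = 8) {
  x <- as.numeric(scaled_scores)
  if (!is_count(n_levels, 2)) stopf("`n_levels` must be an integer >= 2")
  if (length(x) && (any(!is.finite(x)) || any(x < 0) || any(x > 1))) {
    stopf("scaled scores must lie in [0, 1]")
  }
  as.integer(pmin(floor(x * n_levels), n_levels - 1L))
}

#' Assemble a gray-level map from scaled scores
#'
#' Places discretized scores on the map's grid by `(grid_row, grid_col)`
#' (0-based, row 0 at the top). The metadata must cover a complete rectangle.
#'
#' @param scaled_scores Scores in `[0, 1]`, one per metadata row.
#' @param metadata Data frame with `map_id`, `mouse_id`, `dose_gy`,
#'   `grid_row`, `grid_col` for a single map.
#' @param n_levels Gray-level count `N_g`.
#' @param pixel_size_um Pixel size carried as metadata.
#' @return A `gray_map`: list with `levels` (rows x cols integer matrix),
#'   `n_levels`, `map_id`, `mouse_id`, `dose_gy`, `pixel_size_um`.
#' @export
build_gray_map <- function(scaled_scores, metadata, n_levels = 8,
                           pixel_size_um = NA_real_) {
  md <- as.data.frame(metadata)
  if (length(unique(md$map_id)) != 1L) stopf("metadata must describe a single map")
  m <- md$map_id[1L]
  nr <- max(md$grid_row) + 1L
  nc <- max(md$grid_col) + 1L
  key <- paste(md$grid_row, md$grid_col)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stopf("map '%s': duplicated cell (%s)", m, gsub(" ", ", ", d))
  }
  want <- as.vector(outer(0:(nr - 1L), 0:(nc - 1L), paste))
  missing_cell <- setdiff(want, key)
  if (length(missing_cell) || min(md$grid_row) != 0L || min(md$grid_col) != 0L) {
    stopf("map '%s': grid incomplete, missing cell (%s)",
          m, gsub(" ", ", ", missing_cell[1L]))
  }
  lv <- discretize_scores(scaled_scores, n_levels)
  levels <- matrix(NA_integer_, nr, nc)
  levels[cbind(md$grid_row + 1L, md$grid_col + 1L)] <- lv
  structure(list(levels = levels, n_levels = as.integer(n_levels),
                 map_id = m, mouse_id = md$mouse_id[1L],
                 dose_gy = md$dose_gy[1L], pixel_size_um = pixel_size_um),
            class = "gray_map")
}

#' @export
print.gray_map <- function(x, ...) {
  cat(sprintf("<gray_map> '%s' %dx%d, %d levels (mouse %s, %g Gy)\n",
              x$map_id, nrow(x$levels), ncol(x$levels), x$n_levels,
              x$mouse_id, x$dose_gy))
  invisible(x)
}

#' Build all gray-level maps from a fitted score matrix
#'
#' Convenience wrapper: orients PC1 toward the glycogen band, min-max scales
#' its scores ([scale_scores()]), discretizes, and assembles one
#' [build_gray_map()] per `map_id`.
#'
#' @param fit Result of [fit_pca()] (oriented internally).
#' @param n_levels Gray levels `N_g`.
#' @param scale_mode `"global"` (default) or `"per_map"`.
#' @param component Component to image (default 1).
#' @return Named list of `gray_map` objects, ordered by `map_id`.
#' @export
gray_maps_from_scores <- function(fit, n_levels = 8,
                                  scale_mode = c("global", "per_map"),
                                  component = 1L) {
  scale_mode <- match.arg(scale_mode)
  fit <- orient_component(fit, component)
  md <- fit$scores$metadata
  sc <- fit$scores$scores[, component]
  scaled <- scale_scores(sc, scale_mode, map_id = md$map_id)
  ids <- sort(unique(md$map_id))
  maps <- lapply(ids, function(m) {
    i <- md$map_id == m
    build_gray_map(scaled[i], md[i, , drop = FALSE], n_levels = n_levels)
  })
  setNames(maps, ids)
}

#' Compose an RGB image from the first three PC scores
#'
#' Scales PC1, PC2, PC3 scores each to `[0, 1]` with one global min-max per
#' channel and arranges them on the map grid as red, green and blue planes.
#' Export-only: no texture is computed on colour images. A zero-variance
#' channel maps to 0.
#'
#' @param fit Result of [fit_pca()] with `q >= 3`.
#' @param map_id Which map to render.
#' @return `rows x cols x 3` numeric array in `[0, 1]`.
#' @export
build_rgb_map <- function(fit, map_id) {
  sc <- fit$scores$scores
  if (ncol(sc) < 3L) stopf("RGB export needs at least 3 components (q >= 3)")
  md <- fit$scores$metadata
  chans <- lapply(1:3, function(k) {
    rng <- range(sc[, k])
    if (rng[1] == rng[2]) rep(0, nrow(sc))
    else (sc[, k] - rng[1]) / (rng[2] - rng[1])
  })
  i <- md$map_id == map_id
  if (!any(i)) stopf("unknown map_id '%s'", map_id)
  sub <- md[i, , drop = FALSE]
  nr <- max(sub$grid_row) + 1L
  nc <- max(sub$grid_col) + 1L
  arr <- array(NA_real_, c(nr, nc, 3))
  for (k in 1:3) {
    plane <- matrix(NA_real_, nr, nc)
    plane[cbind(sub$grid_row + 1L, sub$grid_col + 1L)] <- chans[[k]][i]
    arr[, , k] <- plane
  }
  if (any(is.na(arr))) stopf("map '%s': grid incomplete for RGB export", map_id)
  arr
}
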