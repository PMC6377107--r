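#' Offset vector for a GLCM angle
#'
#' Angles follow the standard co-occurrence convention on an image whose row
#' 0 is at the top: 0 degrees looks right, 90 degrees up, 45 and 135 the two
#' diagonals. Returned as a `(row, col)` displacement at distance `d`.
#' @noRd
glcm_offset <- function(angle_deg, d) {
  switch(as.character(angle_deg),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stopf("`angle_deg` must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix of a gray map
#'
#' Counts ordered pixel pairs `(I(k, l), I(k + dr, l + dc))` over all
#' in-bounds positions for the offset `(dr, dc)` given by `distance` and
#' `angle_deg`, optionally adding the reverse pair (symmetric counting, the
#' convention used when opposite directions are averaged). The matrix is
#' normalized so all elements sum to 1.
#'
#' @param map A [build_gray_map()] object, or an integer matrix of levels in
#'   `0 .. n_levels - 1` (then `n_levels` must be supplied).
#' @param distance Pixel distance `d >= 1`.
#' @param angle_deg One of 0, 45, 90, 135.
#' @param symmetric Count each pair in both directions (default `TRUE`).
#' @param n_levels Required when `map` is a bare matrix.
#' @return A `glcm`: list with `counts` (integer `N_g x N_g`), `probs`
#'   (normalized), `n_levels`, `distance`, `angle_deg`, `symmetric`.
#' @export
compute_glcm <- function(map, distance = 1L, angle_deg = 0,
                         symmetric = TRUE, n_levels = NULL) {
  if (inherits(map, "gray_map")) {
    levels <- map$levels
    n_levels <- map$n_levels
  } else {
    levels <- map
    if (is.null(n_levels)) stopf("`n_levels` is required for a bare level matrix")
  }
  if (!is.matrix(levels)) stopf("`map` must be a matrix of gray levels")
  if (!is_count(distance)) stopf("`distance` must be a positive integer")
  if (any(levels < 0) || any(levels > n_levels - 1L)) {
    stopf("levels must lie in 0 .. n_levels - 1")
  }
  off <- glcm_offset(angle_deg, as.integer(distance))
  nr <- nrow(levels); nc <- ncol(levels)
  rows <- seq_len(nr); cols <- seq_len(nc)
  r2 <- rows + off[1]; c2 <- cols + off[2]
  rok <- rows[r2 >= 1L & r2 <= nr]; cok <- cols[c2 >= 1L & c2 <= nc]
  if (length(rok) == 0L || length(cok) == 0L) {
    stopf("map %dx%d admits no pixel pair at distance %d, angle %d",
          nr, nc, distance, angle_deg)
  }
  a <- levels[rok, cok, drop = FALSE]
  b <- levels[rok + off[1], cok + off[2], drop = FALSE]
  idx <- as.vector(a) * n_levels + as.vector(b) + 1L
  counts <- matrix(tabulate(idx, nbins = n_levels^2), n_levels, n_levels,
                   byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  structure(list(counts = counts, probs = counts / sum(counts),
                 n_levels = as.integer(n_levels),
                 distance = as.integer(distance),
                 angle_deg = angle_deg, symmetric = symmetric),
            class = "glcm")
}

#' Haralick texture features of one GLCM
#'
#' Computes, from the normalized co-occurrence probabilities `m(i, j)` with
#' 1-based level indices:
#' \describe{
#'   \item{homogeneity `H`}{angular second moment `sum m(i,j)^2`; near 1 when
#'     few gray-tone pairs dominate.}
#'   \item{contrast `Con`}{`sum_k k^2 P(|i-j| = k)`; 0 for a constant image,
#'     growing as neighbouring tones diverge.}
#'   \item{correlation `Cor`}{`(sum ij m(i,j) - mu_x mu_y) / (sigma_x
#'     sigma_y)` with the marginal means and standard deviations of `m`;
#'     confined to `[-1, 1]`.}
#'   \item{entropy `E`}{`-sum m log m` (natural log by default; `0 log 0 = 0`).}
#'   \item{local homogeneity `LH`}{inverse difference moment
#'     `sum m(i,j) / (1 + (i-j)^2)`.}
#' }
#' A constant image has zero marginal spread; its correlation is reported as
#' 0 with `degenerate_correlation = TRUE` rather than dividing by zero.
#'
#' @param glcm A [compute_glcm()] result (normalized).
#' @param log_base Base for the entropy logarithm (default `exp(1)`).
#' @return Named list: `H`, `Con`, `Cor`, `E`, `LH`,
#'   `degenerate_correlation`.
#' @export
haralick_features <- function(glcm, log_base = exp(1)) {
  if (!inherits(glcm, "glcm")) stopf("`glcm` must be a glcm object")
  m <- glcm$probs
  if (abs(sum(m) - 1) > 1e-8) stopf("GLCM is not normalized (sum = %g)", sum(m))
  ng <- glcm$n_levels
  i <- row(m)  # 1-based level indices
  j <- col(m)
  H <- sum(m^2)
  Con <- sum((i - j)^2 * m)
  mu_x <- sum(i * m)
  mu_y <- sum(j * m)
  sd_x <- sqrt(sum((i - mu_x)^2 * m))
  sd_y <- sqrt(sum((j - mu_y)^2 * m))
  degenerate <- sd_x * sd_y <= .Machine$double.eps
  Cor <- if (degenerate) 0 else (sum(i * j * m) - mu_x * mu_y) / (sd_x * sd_y)
  pos <- m > 0
  E <- -sum(m[pos] * log(m[pos], base = log_base))
  LH <- sum(m / (1 + (i - j)^2))
  list(H = H, Con = Con, Cor = Cor, E = E, LH = LH,
       degenerate_correlation = degenerate)
}

#' Angle-averaged Haralick features for one map
#'
#' Computes the GLCM and the five Haralick features separately at each angle
#' (default 0, 45, 90, 135 degrees; distance 1) and averages each feature
#' arithmetically across angles, removing directional dependency.
#'
#' @param map A [build_gray_map()] object.
#' @param distance Pixel distance (default 1).
#' @param angles Angles in degrees.
#' @param symmetric Symmetric pair counting (default `TRUE`).
#' @param log_base Entropy log base.
#' @return One-row data frame (a feature record): `map_id`, `mouse_id`,
#'   `dose_gy`, `H`, `Con`, `Cor`, `E`, `LH`, `degenerate_correlation`,
#'   `n_levels`, `distance`.
#' @export
angle_averaged_features <- function(map, distance = 1L,
                                    angles = c(0, 45, 90, 135),
                                    symmetric = TRUE, log_base = exp(1)) {
  if (!inherits(map, "gray_map")) stopf("`map` must be a gray_map")
  per_angle <- lapply(angles, function(a) {
    g <- tryCatch(
      compute_glcm(map, distance = distance, angle_deg = a, symmetric = symmetric),
      error = function(e) stopf("map '%s', angle %g: %s", map$map_id, a,
                                conditionMessage(e))
    )
    haralick_features(g, log_base = log_base)
  })
  avg <- function(name) mean(vapply(per_angle, `[[`, numeric(1), name))
  data.frame(
    map_id = map$map_id, mouse_id = map$mouse_id, dose_gy = map$dose_gy,
    H = avg("H"), Con = avg("Con"), Cor = avg("Cor"), E = avg("E"),
    LH = avg("LH"),
    degenerate_correlation = any(vapply(per_angle, `[[`, logical(1),
                                        "degenerate_correlation")),
    n_levels = map$n_levels, distance = as.integer(distance),
    stringsAsFactors = FALSE
  )
}

#' Haralick feature table for a collection of maps
#'
#' One feature record per map, ordered by `map_id`. Per-map failures (e.g. a
#' map too small for the offset) are collected as warnings and the run
#' continues.
#'
#' @param maps List of `gray_map` objects.
#' @inheritParams angle_averaged_features
#' @return Data frame, one row per successfully processed map.
#' @export
features_for_dataset <- function(maps, distance = 1L,
                                 angles = c(0, 45, 90, 135),
                                 symmetric = TRUE, log_base = exp(1)) {
  if (length(maps) == 0L) stopf("`maps` is empty")
  rows <- list()
  for (map in maps) {
    rec <- tryCatch(
      angle_averaged_features(map, distance, angles, symmetric, log_base),
      error = function(e) {
        warning(conditionMessage(e), call. = FALSE)
        NULL
      }
    )
    if (!is.null(rec)) rows[[length(rows) + 1L]] <- rec
  }
  if (length(rows) == 0L) stopf("no map yielded features")
  out <- do.call(rbind, rows)
  out <- out[order(out$map_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
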