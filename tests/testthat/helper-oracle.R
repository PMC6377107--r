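# Independent oracles, kept deliberately naive: exhaustive loops and direct
# formula transcription, never calls into the implementation under test.

# GLCM by brute-force enumeration of every ordered pixel pair.
oracle_glcm <- function(levels, n_levels, d, angle_deg, symmetric = TRUE) {
  off <- switch(as.character(angle_deg),
                "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0), "135" = c(-d, -d))
  counts <- matrix(0L, n_levels, n_levels)
  nr <- nrow(levels); nc <- ncol(levels)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        i <- levels[r, c] + 1L; j <- levels[r2, c2] + 1L
        counts[i, j] <- counts[i, j] + 1L
        if (symmetric) counts[j, i] <- counts[j, i] + 1L
      }
    }
  }
  counts
}

# Direct evaluation of the five texture features from a normalized GLCM.
oracle_features <- function(probs) {
  ng <- nrow(probs)
  H <- 0; Con <- 0; E <- 0; LH <- 0
  mu_x <- 0; mu_y <- 0
  for (i in 1:ng) for (j in 1:ng) {
    m <- probs[i, j]
    H <- H + m^2
    Con <- Con + (i - j)^2 * m
    LH <- LH + m / (1 + (i - j)^2)
    if (m > 0) E <- E - m * log(m)
    mu_x <- mu_x + i * m
    mu_y <- mu_y + j * m
  }
  sx2 <- 0; sy2 <- 0; cross <- 0
  for (i in 1:ng) for (j in 1:ng) {
    m <- probs[i, j]
    sx2 <- sx2 + (i - mu_x)^2 * m
    sy2 <- sy2 + (j - mu_y)^2 * m
    cross <- cross + i * j * m
  }
  Cor <- if (sx2 * sy2 == 0) 0 else (cross - mu_x * mu_y) / sqrt(sx2 * sy2)
  list(H = H, Con = Con, Cor = Cor, E = E, LH = LH,
       degenerate = sx2 * sy2 == 0)
}

# Dense-matrix ALS reference (base solve(), no banded shortcuts).
oracle_als <- function(y, lambda, p, max_iter = 20, tol = 1e-6) {
  n <- length(y)
  D <- diff(diag(n), differences = 2)
  P <- lambda * crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(max_iter)) {
    z <- solve(diag(w) + P, w * y)
    wn <- ifelse(y > z, p, 1 - p)
    if (it > 1 && max(abs(wn - w)) < tol) {
      w <- wn
      break
    }
    w <- wn
  }
  list(baseline = as.numeric(z), weights = w)
}

# Random gray maps for property suites.
random_gray_map <- function(seed, min_side = 2, max_side = 14,
                            levels_choices = c(2, 4, 8)) {
  set.seed(seed)
  nr <- sample(min_side:max_side, 1)
  nc <- sample(min_side:max_side, 1)
  ng <- sample(levels_choices, 1)
  structure(list(
    levels = matrix(sample(0:(ng - 1), nr * nc, replace = TRUE), nr, nc),
    n_levels = as.integer(ng), map_id = sprintf("rand%05d", seed),
    mouse_id = "m", dose_gy = 0, pixel_size_um = 15
  ), class = "gray_map")
}
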