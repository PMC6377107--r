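#' Write a spectral dataset as delimited text
#'
#' Header: the five metadata columns followed by the numeric wavenumbers.
#' Rows are ordered by `(map_id, grid_row, grid_col)` and numbers formatted
#' at fixed precision, so identical datasets produce byte-identical files.
#'
#' @param ds A [spectral_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectral_csv <- function(ds, path) {
  validate_spectral_dataset(ds)
  md <- ds$metadata
  header <- paste(c("map_id", "mouse_id", "dose_gy", "grid_row", "grid_col",
                    format_num(ds$wavenumbers)), collapse = ",")
  if (nrow(md) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  ord <- order(md$map_id, md$grid_row, md$grid_col)
  X <- ds$intensities[ord, , drop = FALSE]
  md <- md[ord, , drop = FALSE]
  body <- vapply(seq_len(nrow(md)), function(i) {
    paste(c(md$map_id[i], md$mouse_id[i], format_num(md$dose_gy[i]),
            md$grid_row[i], md$grid_col[i], format_num(X[i, ])),
          collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a spectral dataset from delimited text
#'
#' Expects the dialect written by [write_spectral_csv()]: metadata columns
#' `map_id`, `mouse_id`, `dose_gy`, `grid_row`, `grid_col`, then one column
#' per wavenumber with the numeric wavenumber as its header. Validates axis
#' monotonicity and per-map grid completeness.
#'
#' @param path File path.
#' @return A validated [spectral_dataset()].
#' @export
read_spectral_csv <- function(path) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("map_id", "mouse_id", "dose_gy", "grid_row", "grid_col")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stopf("'%s': missing metadata column(s): %s", path, paste(miss, collapse = ", "))
  }
  wn_cols <- setdiff(names(raw), need)
  w <- suppressWarnings(as.numeric(wn_cols))
  if (length(w) == 0L || any(is.na(w))) {
    stopf("'%s': intensity column headers must be numeric wavenumbers", path)
  }
  if (any(diff(w) <= 0)) {
    bad <- which(diff(w) <= 0)[1L]
    stopf("'%s': wavenumber headers not strictly increasing at column %d (%g >= %g)",
          path, bad, w[bad], w[bad + 1L])
  }
  X <- as.matrix(raw[, wn_cols, drop = FALSE])
  storage.mode(X) <- "double"
  md <- raw[, need, drop = FALSE]
  md$map_id <- as.character(md$map_id)
  md$mouse_id <- as.character(md$mouse_id)
  md$grid_row <- as.integer(md$grid_row)
  md$grid_col <- as.integer(md$grid_col)
  spectral_dataset(w, X, md)
}

#' Write a gray map as a plain-text PGM (P2) image
#'
#' Maximum gray value is `n_levels - 1`, so the file carries the map's
#' quantization exactly.
#'
#' @param map A [build_gray_map()] object.
#' @param path Output path (conventionally `.pgm`).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(map, path) {
  if (!inherits(map, "gray_map")) stopf("`map` must be a gray_map")
  lv <- map$levels
  lines <- c("P2",
             sprintf("# %s mouse=%s dose_gy=%s", map$map_id, map$mouse_id,
                     format_num(map$dose_gy)),
             sprintf("%d %d", ncol(lv), nrow(lv)),
             sprintf("%d", map$n_levels - 1L),
             apply(lv, 1L, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text PGM (P2) gray image
#'
#' @param path PGM file path.
#' @return List with `levels` (integer matrix) and `maxval`.
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (lines[1] != "P2") stopf("'%s' is not a plain (P2) PGM file", path)
  tokens <- as.integer(unlist(strsplit(paste(lines[-1], collapse = " "), "\\s+")))
  tokens <- tokens[!is.na(tokens)]
  nc <- tokens[1]; nr <- tokens[2]; maxval <- tokens[3]
  px <- tokens[-(1:3)]
  if (length(px) != nr * nc) stopf("'%s': expected %d pixels, found %d",
                                   path, nr * nc, length(px))
  list(levels = matrix(px, nr, nc, byrow = TRUE), maxval = maxval)
}

#' Write an RGB array as a plain-text PPM (P3) image
#'
#' @param rgb `rows x cols x 3` array with values in `[0, 1]`.
#' @param path Output path (conventionally `.ppm`).
#' @param maxval Integer maximum channel value (default 255).
#' @return `path`, invisibly.
#' @export
write_ppm <- function(rgb, path, maxval = 255L) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) stopf("`rgb` must be rows x cols x 3")
  if (any(rgb < 0) || any(rgb > 1)) stopf("`rgb` values must lie in [0, 1]")
  q <- round(rgb * maxval)
  nr <- dim(rgb)[1]; nc <- dim(rgb)[2]
  rows <- vapply(seq_len(nr), function(i) {
    paste(as.vector(t(cbind(q[i, , 1], q[i, , 2], q[i, , 3]))), collapse = " ")
  }, character(1))
  writeLines(c("P3", sprintf("%d %d", nc, nr), sprintf("%d", maxval), rows), path)
  invisible(path)
}

#' Default full-run configuration
#'
#' One document tying together the study design, preprocessing parameters and
#' texture/comparison settings consumed by [run_pipeline()]. Serializable to
#' and from YAML.
#'
#' @param seed Master seed for the run.
#' @param design A [study_design()] (or list of its arguments).
#' @param preprocess A [preprocess_config()] (or list of its arguments).
#' @param n_levels Gray levels for score discretization.
#' @param scale_mode `"global"` or `"per_map"` score scaling.
#' @param distance,angles GLCM geometry.
#' @param log_base Entropy log base (`"e"` or `"2"`).
#' @param correction Multiple-testing correction for the dose tests.
#' @param cluster Clustering treatment for the dose tests.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, design = list(), preprocess = list(),
                       n_levels = 8L, scale_mode = "global", distance = 1L,
                       angles = c(0, 45, 90, 135), log_base = "e",
                       correction = "none", cluster = "none") {
  if (!log_base %in% c("e", "2")) stopf("`log_base` must be 'e' or '2'")
  structure(list(
    seed = as.integer(seed),
    design = if (inherits(design, "study_design")) unclass(design) else design,
    preprocess = if (inherits(preprocess, "preprocess_config")) unclass(preprocess) else preprocess,
    n_levels = as.integer(n_levels), scale_mode = scale_mode,
    distance = as.integer(distance), angles = angles, log_base = log_base,
    correction = correction, cluster = cluster
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown top-level keys are rejected to catch misspelled parameters.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(doc), known)
  if (length(unknown)) {
    stopf("'%s': unknown configuration key(s): %s", path,
          paste(unknown, collapse = ", "))
  }
  do.call(run_config, doc)
}

#' Write a run configuration to YAML
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
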