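#' Construct a spectral dataset
#'
#' The central data container: an `n x p` intensity matrix on a shared
#' wavenumber axis, with one row of metadata per spectrum locating it in a
#' rectangular Raman map (`map_id`, `grid_row`, `grid_col`, 0-based, row 0 at
#' the top) and recording its provenance (`mouse_id`, `dose_gy`).
#'
#' @param wavenumbers Strictly increasing numeric vector (cm^-1), length `p`.
#' @param intensities Numeric `n x p` matrix; no missing values.
#' @param metadata Data frame with columns `map_id`, `mouse_id`, `dose_gy`,
#'   `grid_row`, `grid_col`; `n` rows. Each map's cells must fill a complete
#'   rectangle with no duplicates.
#' @param validate Set `FALSE` to skip integrity checks (internal use).
#'
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(wavenumbers, intensities, metadata, validate = TRUE) {
  wavenumbers <- as.numeric(wavenumbers)
  if (is.null(dim(intensities))) {
    intensities <- matrix(as.numeric(intensities), nrow = length(intensities) > 0,
                          ncol = length(wavenumbers))
  }
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  dimnames(intensities) <- NULL
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  rownames(metadata) <- NULL
  ds <- structure(
    list(wavenumbers = wavenumbers, intensities = intensities, metadata = metadata),
    class = "spectral_dataset"
  )
  if (validate) validate_spectral_dataset(ds)
  ds
}

#' Validate a spectral dataset's integrity
#'
#' Checks axis monotonicity, absence of missing values, metadata completeness,
#' uniqueness of `(map_id, grid_row, grid_col)` and that every map's grid
#' coordinates fill a full rectangle.
#'
#' @param ds A [spectral_dataset()].
#' @return `ds`, invisibly, if valid; otherwise an error naming the defect.
#' @export
validate_spectral_dataset <- function(ds) {
  w <- ds$wavenumbers
  x <- ds$intensities
  md <- ds$metadata
  if (length(w) < 1L) stopf("wavenumber axis is empty")
  if (any(!is.finite(w))) stopf("wavenumber axis contains non-finite values")
  if (any(diff(w) <= 0)) {
    bad <- which(diff(w) <= 0)[1L]
    stopf("wavenumbers must be strictly increasing (violated at position %d: %g >= %g)",
          bad, w[bad], w[bad + 1L])
  }
  if (ncol(x) != length(w)) {
    stopf("intensity matrix has %d columns but axis has %d points", ncol(x), length(w))
  }
  if (nrow(x) != nrow(md)) {
    stopf("intensity matrix has %d rows but metadata has %d", nrow(x), nrow(md))
  }
  if (nrow(x) > 0 && any(!is.finite(x))) stopf("intensities contain missing or non-finite values")
  need <- c("map_id", "mouse_id", "dose_gy", "grid_row", "grid_col")
  miss <- setdiff(need, names(md))
  if (length(miss)) stopf("metadata is missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(md) == 0L) return(invisible(ds))
  key <- paste(md$map_id, md$grid_row, md$grid_col, sep = "\r")
  if (anyDuplicated(key)) {
    d <- md[duplicated(key), , drop = FALSE][1L, ]
    stopf("duplicated grid cell: map '%s', cell (%d, %d)",
          d$map_id, d$grid_row, d$grid_col)
  }
  for (m in unique(md$map_id)) {
    sub <- md[md$map_id == m, , drop = FALSE]
    nr <- max(sub$grid_row) + 1L
    nc <- max(sub$grid_col) + 1L
    if (min(sub$grid_row) != 0L || min(sub$grid_col) != 0L || nrow(sub) != nr * nc) {
      have <- paste(sub$grid_row, sub$grid_col)
      want <- as.vector(outer(0:(nr - 1L), 0:(nc - 1L), paste))
      missing_cell <- setdiff(want, have)[1L]
      stopf("map '%s' does not fill a complete %dx%d rectangle (e.g. missing cell (%s))",
            m, nr, nc, gsub(" ", ", ", missing_cell))
    }
  }
  invisible(ds)
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d spectra x %d wavenumbers (%g-%g cm^-1)\n",
              nrow(x$intensities), length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  if (nrow(x$metadata) > 0) {
    cat(sprintf("  maps: %d | mice: %d | doses (Gy): %s\n",
                length(unique(x$metadata$map_id)),
                length(unique(x$metadata$mouse_id)),
                paste(sort(unique(x$metadata$dose_gy)), collapse = ", ")))
  }
  invisible(x)
}

#' Bind spectral datasets sharing one wavenumber axis
#' @param ... `spectral_dataset` objects on identical axes.
#' @return A single combined [spectral_dataset()].
#' @export
bind_spectral <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) &&
      !inherits(parts[[1L]], "spectral_dataset")) {
    parts <- parts[[1L]]
  }
  stopifnot(length(parts) >= 1L)
  w <- parts[[1L]]$wavenumbers
  for (p in parts) {
    if (!isTRUE(all.equal(p$wavenumbers, w))) stopf("wavenumber axes differ; cannot bind")
  }
  spectral_dataset(
    w,
    do.call(rbind, lapply(parts, `[[`, "intensities")),
    do.call(rbind, lapply(parts, `[[`, "metadata"))
  )
}
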