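# Shared fixtures built in code.

make_gray_map <- function(levels, n_levels, map_id = "m1", mouse_id = "mouse1",
                          dose_gy = 0) {
  structure(list(levels = levels, n_levels = as.integer(n_levels),
                 map_id = map_id, mouse_id = mouse_id, dose_gy = dose_gy,
                 pixel_size_um = 15), class = "gray_map")
}

# A small, fast study design used where the full default would be overkill.
small_design <- function(seed, effect = c("0" = 0.05, "5" = 0.065, "15" = 0.065),
                         axis_n = 150, maps_per_mouse = c(2, 2),
                         mice_per_dose = 2, grid = list(c(8, 8))) {
  study_design(
    mice_per_dose = mice_per_dose, maps_per_mouse = maps_per_mouse,
    grid_shapes = grid, grid_probs = rep(1 / length(grid), length(grid)),
    effect = effect, wavenumbers = default_wavenumbers(n = axis_n), seed = seed
  )
}

# Metadata for one complete rectangular map.
grid_metadata <- function(nr, nc, map_id = "m1", mouse_id = "mouse1", dose_gy = 0) {
  data.frame(
    map_id = map_id, mouse_id = mouse_id, dose_gy = dose_gy,
    grid_row = rep(0:(nr - 1), each = nc),
    grid_col = rep(0:(nc - 1), times = nr),
    stringsAsFactors = FALSE
  )
}
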