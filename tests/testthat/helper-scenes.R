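# Small scene configurations and hand-built scenes for fast tests.

tiny_config <- function(seed = 1, n = 6, ...) {
  scene_config(n_trees_per_class = n, image_size = 100,
               canopy_radius_range = c(3, 4), seed = seed, ...)
}

# noise-free configuration: every canopy pixel equals its class mean
flat_config <- function(seed = 1, n = 4, ...) {
  tiny_config(seed = seed, n = n, class_color_sd = 0,
              texture_grain = c(0, 0, 0, 0), shadow_fraction = 0, ...)
}

# hand-built one/two-tree scene with explicitly chosen pixel values
manual_scene <- function(canopy_values, levels = NULL) {
  # canopy_values: named list tree_id -> matrix with columns row,col,R,G,B
  sz <- 16
  raster <- array(0.5, dim = c(sz, sz, 3),
                  dimnames = list(NULL, NULL, c("R", "G", "B")))
  canopies <- list()
  for (id in names(canopy_values)) {
    m <- canopy_values[[id]]
    for (i in seq_len(nrow(m))) {
      raster[m[i, "row"], m[i, "col"], 1] <- m[i, "R"]
      raster[m[i, "row"], m[i, "col"], 2] <- m[i, "G"]
      raster[m[i, "row"], m[i, "col"], 3] <- m[i, "B"]
    }
    canopies[[id]] <- m[, c("row", "col"), drop = FALSE]
  }
  if (is.null(levels)) levels <- rep(1L, length(canopies))
  truth <- data.frame(tree_id = names(canopies),
                      L_h = 100, L_d = 0, DR = 0, level = levels)
  structure(list(raster = raster, canopies = canopies, truth = truth),
            class = "scene")
}
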