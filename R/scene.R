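# Synthetic UAV scene generator.
#
# Emulates the statistical structure the downstream analysis assumes: four
# damage classes whose canopy colour progresses green -> yellow -> red ->
# grey, class-dependent local texture (pixel-level noise driving GLCM
# contrast), within-class variability, shadow pixels, background, and an
# optional five-band multispectral stack whose NIR reflectance declines
# with damage. It does not attempt radiative-transfer realism.

#' Configuration of a synthetic scene
#'
#' @param n_trees_per_class Trees per damage class (default 210, i.e. 840
#'   trees over the four classes).
#' @param classes Ordered integer damage levels, subset of 1..4.
#' @param image_size Side length of the square raster, pixels.
#' @param canopy_radius_range Min/max canopy semi-axis, pixels.
#' @param class_color_means 4x3 matrix of per-class mean (R, G, B)
#'   reflectance encoding the green/yellow/red/grey colour progression.
#' @param class_color_sd Per-channel standard deviation of the per-tree
#'   base colour around its class mean (within-class variability).
#' @param texture_grain Per-class standard deviation of per-pixel noise;
#'   larger grain raises local variance and GLCM contrast.
#' @param texture_grain_jitter Standard deviation of the per-tree
#'   lognormal factor multiplying the class grain. Individual crowns vary
#'   widely in fine-scale texture, so neighbouring classes overlap in
#'   texture far more than in colour — texture is an auxiliary signal,
#'   not a primary one.
#' @param ms_enabled Also emit the five multispectral planes
#'   (b, g, r, RE, NIR)?
#' @param background_reflectance Mean (R, G, B) of non-canopy pixels.
#' @param shadow_fraction Fraction of each canopy's pixels darkened
#'   (multiplied by 0.5), emulating intra-crown shadow.
#' @param seed Integer seed; identical seeds give bit-identical scenes.
#' @return A `scene_config` list, validated.
#' @export
scene_config <- function(n_trees_per_class = 210,
                         classes = 1:4,
                         image_size = 420,
                         canopy_radius_range = c(4, 6),
                         class_color_means = default_class_colors(),
                         class_color_sd = 0.07,
                         texture_grain = c(0.02, 0.04, 0.06, 0.09),
                         texture_grain_jitter = 0.35,
                         ms_enabled = FALSE,
                         background_reflectance = c(0.08, 0.06, 0.05),
                         shadow_fraction = 0.15,
                         seed = 1L) {
  stopifnot(n_trees_per_class >= 1, length(classes) >= 1,
            all(classes %in% 1:4), !anyDuplicated(classes),
            image_size >= 16, length(canopy_radius_range) == 2,
            canopy_radius_range[1] >= 2,
            diff(canopy_radius_range) >= 0,
            is.matrix(class_color_means), ncol(class_color_means) == 3,
            nrow(class_color_means) == 4,
            all(class_color_means >= 0 & class_color_means <= 1),
            class_color_sd >= 0, length(texture_grain) == 4,
            all(texture_grain >= 0), texture_grain_jitter >= 0,
            length(background_reflectance) == 3,
            all(background_reflectance >= 0 & background_reflectance <= 1),
            shadow_fraction >= 0, shadow_fraction < 1)
  used <- class_color_means[classes, , drop = FALSE]
  if (length(classes) > 1 && min(stats::dist(used)) == 0)
    stop("class_color_means must be pairwise distinct across classes")
  structure(list(
    n_trees_per_class = as.integer(n_trees_per_class),
    classes = as.integer(classes), image_size = as.integer(image_size),
    canopy_radius_range = canopy_radius_range,
    class_color_means = class_color_means,
    class_color_sd = class_color_sd, texture_grain = texture_grain,
    texture_grain_jitter = texture_grain_jitter,
    ms_enabled = isTRUE(ms_enabled),
    background_reflectance = background_reflectance,
    shadow_fraction = shadow_fraction, seed = as.integer(seed)),
    class = "scene_config")
}

#' Default class colour model
#'
#' Per-class mean (R, G, B) reflectances: healthy green, mild yellow-green,
#' moderate red-brown, severe grey. Generator defaults, not field
#' measurements.
#'
#' @return 4x3 numeric matrix, rows = damage levels 1..4.
#' @export
default_class_colors <- function() {
  m <- rbind(Healthy  = c(0.20, 0.45, 0.18),
             Mild     = c(0.45, 0.48, 0.20),
             Moderate = c(0.55, 0.35, 0.18),
             Severe   = c(0.40, 0.40, 0.40))
  colnames(m) <- c("R", "G", "B")
  m
}

# Multispectral emulation: class-mean reflectance of the five bands.
# NIR declines monotonically with damage (loss of leaf internal
# scattering); red-edge declines more gently; visible bands track the
# RGB colour model loosely.
.ms_class_means <- function() {
  m <- rbind(Healthy  = c(b = 0.05, g = 0.12, r = 0.06, RE = 0.32, NIR = 0.45),
             Mild     = c(b = 0.06, g = 0.13, r = 0.10, RE = 0.29, NIR = 0.38),
             Moderate = c(b = 0.07, g = 0.11, r = 0.15, RE = 0.26, NIR = 0.30),
             Severe   = c(b = 0.09, g = 0.10, r = 0.11, RE = 0.23, NIR = 0.22))
  m
}

# survey draw shared by generate_survey / generate_scene; assumes the RNG
# is already seeded. DR targets are kept 0.5% clear of the band edges so
# integer needle-count rounding cannot move a tree across a boundary.
.draw_survey <- function(config) {
  bands <- level_bands()
  margin <- 0.5
  per <- config$n_trees_per_class
  recs <- lapply(config$classes, function(cl) {
    lo <- if (cl == 1) 0 else bands[cl, "lower"] + margin
    hi <- bands[cl, "upper"] - if (cl == 4) 0 else margin
    if (hi <= lo) stop("empty leaf-loss band for class ", cl)
    target <- stats::runif(per, lo, hi)
    total <- sample(200:400, per, replace = TRUE)
    L_d <- round(target / 100 * total)
    data.frame(L_h = total - L_d, L_d = L_d, class = cl)
  })
  recs <- do.call(rbind, recs)
  ids <- sprintf("tree_%04d", seq_len(nrow(recs)))
  out <- survey_records(ids, recs$L_h, recs$L_d)
  if (!all(out$level == recs$class))  # margin makes this unreachable
    stop("internal error: rounding moved a tree across a level boundary")
  out
}

#' Generate a synthetic field survey
#'
#' Draws healthy/damaged needle counts for every tree so that its
#' leaf-loss rate falls strictly inside its class band.
#'
#' @param config A [scene_config()].
#' @return Survey `data.frame` (see [survey_records()]).
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  .draw_survey(config)
}

#' Generate a labelled synthetic scene
#'
#' Renders every tree as a filled ellipse with jittered radii on a
#' non-overlapping grid; canopy pixels get the tree's base colour (class
#' mean plus within-class jitter) plus per-pixel noise at the class's
#' texture grain; a fixed fraction of canopy pixels is darkened as shadow.
#'
#' @param config A [scene_config()].
#' @return A `scene`: list with `raster` (rows x cols x channels array,
#'   channels `R,G,B` and optionally `b,g,r,RE,NIR`), `canopies` (named
#'   list of n x 2 pixel index matrices, columns row/col, 1-based), and
#'   `truth` (the survey table with `level`).
#' @examples
#' sc <- generate_scene(scene_config(n_trees_per_class = 3,
#'                                   image_size = 64, seed = 1))
#' range(sc$raster)
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  truth <- .draw_survey(config)
  n_trees <- nrow(truth)
  sz <- config$image_size
  rmax <- config$canopy_radius_range[2]
  cell <- ceiling(2 * rmax + 2)
  per_side <- sz %/% cell
  if (per_side^2 < n_trees)
    stop("scene layout error: image_size ", sz, " holds at most ",
         per_side^2, " non-overlapping canopies, need ", n_trees)

  channels <- c("R", "G", "B")
  if (config$ms_enabled) channels <- c(channels, c("b", "g", "r", "RE", "NIR"))
  nch <- length(channels)
  raster <- array(0, dim = c(sz, sz, nch),
                  dimnames = list(NULL, NULL, channels))

  # background: mean reflectance plus mild speckle
  bg <- c(config$background_reflectance,
          if (config$ms_enabled) c(0.06, 0.07, 0.08, 0.10, 0.12))
  for (k in seq_len(nch))
    raster[, , k] <- pmin(pmax(
      bg[k] + stats::rnorm(sz * sz, 0, 0.01), 0), 1)

  # shuffled grid cells, one canopy per cell => masks disjoint by design
  cells <- sample.int(per_side^2, n_trees)
  ms_means <- .ms_class_means()
  canopies <- vector("list", n_trees)
  names(canopies) <- truth$tree_id

  for (t in seq_len(n_trees)) {
    cl <- truth$level[t]
    cell_r <- (cells[t] - 1) %/% per_side
    cell_c <- (cells[t] - 1) %% per_side
    mask <- NULL
    for (try in 1:20) {
      cr <- cell_r * cell + cell / 2 + stats::runif(1, -1, 1)
      cc <- cell_c * cell + cell / 2 + stats::runif(1, -1, 1)
      ry <- stats::runif(1, config$canopy_radius_range[1],
                         config$canopy_radius_range[2])
      rx <- stats::runif(1, config$canopy_radius_range[1],
                         config$canopy_radius_range[2])
      rows <- max(1, floor(cr - ry)):min(sz, ceiling(cr + ry))
      cols <- max(1, floor(cc - rx)):min(sz, ceiling(cc + rx))
      gr <- expand.grid(row = rows, col = cols)
      inside <- ((gr$row - cr) / ry)^2 + ((gr$col - cc) / rx)^2 <= 1
      if (sum(inside) >= 9) {
        mask <- as.matrix(gr[inside, c("row", "col")])
        break
      }
    }
    if (is.null(mask))
      stop("scene layout error: could not place canopy for ",
           truth$tree_id[t])
    dimnames(mask) <- list(NULL, c("row", "col"))
    canopies[[t]] <- mask

    npix <- nrow(mask)
    flat <- (mask[, "col"] - 1L) * sz + mask[, "row"]
    base_rgb <- pmin(pmax(config$class_color_means[cl, ] +
                            stats::rnorm(3, 0, config$class_color_sd), 0), 1)
    grain <- config$texture_grain[cl] *
      exp(stats::rnorm(1, 0, config$texture_grain_jitter))
    shade <- rep(1, npix)
    n_shadow <- floor(config$shadow_fraction * npix)
    if (n_shadow > 0) shade[sample.int(npix, n_shadow)] <- 0.5
    for (k in 1:3) {
      v <- base_rgb[k] + stats::rnorm(npix, 0, grain)
      raster[, , k][flat] <- pmin(pmax(v * shade, 0), 1)
    }
    if (config$ms_enabled) {
      base_ms <- pmin(pmax(ms_means[cl, ] +
                             stats::rnorm(5, 0, config$class_color_sd / 2),
                           0.01), 1)
      for (k in 1:5) {
        v <- base_ms[k] + stats::rnorm(npix, 0, grain)
        raster[, , k + 3][flat] <- pmin(pmax(v * shade, 0.001), 1)
      }
    }
  }

  structure(list(raster = raster, canopies = canopies, truth = truth,
                 config = config), class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  d <- dim(x$raster)
  cat(sprintf("<scene> %dx%d px, %d channel(s), %d trees\n",
              d[1], d[2], d[3], length(x$canopies)))
  print(table(level_name(x$truth$level)))
  invisible(x)
}

#' Persist / load a scene
#'
#' Writes the raster as a multi-page 32-bit float TIFF (one page per
#' channel), canopy masks as a GeoJSON FeatureCollection (one MultiPolygon
#' of unit pixel squares per tree, coordinates (col, row), 0-based,
#' half-open pixel extents) and the survey as CSV.
#'
#' @param scene A scene.
#' @param dir Output directory (created if needed).
#' @return `write_scene` returns `dir` invisibly; `read_scene` the scene
#'   (without the generating config).
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  channels <- dimnames(scene$raster)[[3]]
  pages <- lapply(seq_along(channels), function(k) scene$raster[, , k])
  tiff::writeTIFF(pages, file.path(dir, "raster.tif"),
                  bits.per.sample = 32L)
  writeLines(paste(channels, collapse = ","),
             file.path(dir, "channels.txt"))
  feats <- lapply(names(scene$canopies), function(id) {
    m <- scene$canopies[[id]]
    rings <- lapply(seq_len(nrow(m)), function(i) {
      r0 <- m[i, "row"] - 1; c0 <- m[i, "col"] - 1  # 0-based corner
      list(list(c(c0, r0), c(c0 + 1, r0), c(c0 + 1, r0 + 1),
                c(c0, r0 + 1), c(c0, r0)))
    })
    lev <- scene$truth$level[scene$truth$tree_id == id]
    list(type = "Feature",
         properties = list(tree_id = id, level = lev),
         geometry = list(type = "MultiPolygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file.path(dir, "canopies.geojson"),
                       auto_unbox = TRUE, digits = NA)
  write_survey(scene$truth, file.path(dir, "survey.csv"))
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  pages <- tiff::readTIFF(file.path(dir, "raster.tif"), all = TRUE)
  channels <- strsplit(readLines(file.path(dir, "channels.txt")), ",")[[1]]
  sz <- dim(pages[[1]])
  raster <- array(0, dim = c(sz[1], sz[2], length(channels)),
                  dimnames = list(NULL, NULL, channels))
  for (k in seq_along(pages)) raster[, , k] <- pages[[k]]
  gj <- jsonlite::read_json(file.path(dir, "canopies.geojson"))
  canopies <- list()
  for (f in gj$features) {
    px <- t(vapply(f$geometry$coordinates, function(ring) {
      corner <- ring[[1]][[1]]  # (col, row), 0-based min corner
      c(row = corner[[2]] + 1L, col = corner[[1]] + 1L)
    }, c(row = 0, col = 0)))
    canopies[[f$properties$tree_id]] <- px
  }
  truth <- read_survey(file.path(dir, "survey.csv"))
  structure(list(raster = raster, canopies = canopies, truth = truth),
            class = "scene")
}
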