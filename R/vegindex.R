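# Vegetation-index registry.
#
# RGB indices are functions of the camera channels R, G, B; multispectral
# indices use the five band reflectances b, g, r, RE, NIR (blue, green, red,
# red-edge, near-infrared). All reflectances are in [0, 1]. Ratio indices
# guard against denominators of exactly zero by adding eps = 1e-9 there;
# reflectances are noisy non-negative floats and a hard per-pixel failure
# would be unusable.

.den_eps <- 1e-9

.safe_div <- function(num, den) num / (den + .den_eps * (den == 0))

# name = registry key; set = feature namespace; source = "printed" for
# formulas with a normative printed definition, "literature" for indices
# that are named in the study's feature catalogue but defined from the
# standard literature form; channels = bands the formula reads.
.index_defs <- list(
  # --- RGB channel features and indices ---
  R     = list(set = "RGB_VI", source = "printed", channels = "R",
               fun = function(ch) ch$R),
  G     = list(set = "RGB_VI", source = "printed", channels = "G",
               fun = function(ch) ch$G),
  B     = list(set = "RGB_VI", source = "printed", channels = "B",
               fun = function(ch) ch$B),
  CIVE  = list(set = "RGB_VI", source = "printed", channels = c("R", "G", "B"),
               fun = function(ch) 0.441 * ch$R - 0.881 * ch$G +
                 0.3856 * ch$B + 18.78745),
  ExR   = list(set = "RGB_VI", source = "printed", channels = c("R", "G"),
               fun = function(ch) 1.4 * ch$R - ch$G),
  ExG   = list(set = "RGB_VI", source = "printed", channels = c("R", "G", "B"),
               fun = function(ch) 2 * ch$G - ch$R - ch$B),
  GBRI  = list(set = "RGB_VI", source = "printed", channels = c("G", "B"),
               fun = function(ch) .safe_div(ch$G, ch$B)),
  RBRI  = list(set = "RGB_VI", source = "printed", channels = c("R", "B"),
               fun = function(ch) .safe_div(ch$R, ch$B)),
  RGRI  = list(set = "RGB_VI", source = "printed", channels = c("R", "G"),
               fun = function(ch) .safe_div(ch$R, ch$G)),
  GCC   = list(set = "RGB_VI", source = "printed", channels = c("R", "G", "B"),
               fun = function(ch) .safe_div(ch$G, ch$R + ch$G + ch$B)),
  VDVI  = list(set = "RGB_VI", source = "printed", channels = c("R", "G", "B"),
               fun = function(ch) .safe_div(ch$G - ch$B - ch$R,
                                            ch$G + ch$B + ch$R)),
  GLA   = list(set = "RGB_VI", source = "printed", channels = c("R", "G", "B"),
               fun = function(ch) .safe_div(2 * ch$G - ch$R - ch$B,
                                            2 * ch$G + ch$R + ch$B)),
  GB    = list(set = "RGB_VI", source = "printed", channels = c("G", "B"),
               fun = function(ch) ch$G - ch$B),
  VARI  = list(set = "RGB_VI", source = "literature",
               channels = c("R", "G", "B"),
               fun = function(ch) .safe_div(ch$G - ch$R,
                                            ch$G + ch$R - ch$B)),
  GRVI  = list(set = "RGB_VI", source = "literature", channels = c("R", "G"),
               fun = function(ch) .safe_div(ch$G - ch$R, ch$G + ch$R)),
  NGRVI = list(set = "RGB_VI", source = "literature", channels = c("R", "G"),
               fun = function(ch) .safe_div(ch$G^2 - ch$R^2,
                                            ch$G^2 + ch$R^2)),
  PPR   = list(set = "RGB_VI", source = "literature", channels = c("G", "B"),
               fun = function(ch) .safe_div(ch$G - ch$B, ch$G + ch$B)),
  WI    = list(set = "RGB_VI", source = "literature",
               channels = c("R", "G", "B"),
               fun = function(ch) .safe_div(ch$G - ch$B, ch$R - ch$G)),
  ExGR  = list(set = "RGB_VI", source = "literature",
               channels = c("R", "G", "B"),
               fun = function(ch) (2 * ch$G - ch$R - ch$B) -
                 (1.4 * ch$R - ch$G)),
  RGBVI = list(set = "RGB_VI", source = "literature",
               channels = c("R", "G", "B"),
               fun = function(ch) .safe_div(ch$G^2 - ch$B * ch$R,
                                            ch$G^2 + ch$B * ch$R)),

  # --- Multispectral indices (b, g, r, RE, NIR reflectance bands) ---
  `2NLI`   = list(set = "MS_VI", source = "printed",
                  channels = c("NIR", "g"),
                  fun = function(ch) .safe_div(ch$NIR^2 - ch$g,
                                               ch$NIR^2 + ch$g)),
  GDVI     = list(set = "MS_VI", source = "printed",
                  channels = c("NIR", "g"),
                  fun = function(ch) ch$NIR - ch$g),
  GMNLI    = list(set = "MS_VI", source = "printed",
                  channels = c("NIR", "g"),
                  fun = function(ch) .safe_div(1.5 * (sqrt(ch$NIR) - ch$g),
                                               sqrt(ch$NIR) + ch$g + 0.5)),
  NDVIreg  = list(set = "MS_VI", source = "printed",
                  channels = c("NIR", "RE"),
                  fun = function(ch) .safe_div(ch$NIR - ch$RE,
                                               ch$NIR + ch$RE)),
  SI1reg   = list(set = "MS_VI", source = "printed",
                  channels = c("g", "RE"),
                  fun = function(ch) sqrt(ch$g * ch$RE)),
  `SI1reg*` = list(set = "MS_VI", source = "printed",
                   channels = c("r", "RE"),
                   fun = function(ch) sqrt(ch$r * ch$RE)),
  TCARI    = list(set = "MS_VI", source = "printed",
                  channels = c("r", "g", "RE"),
                  fun = function(ch) 3 * ((ch$RE - ch$r) -
                    0.2 * (ch$RE - ch$g) * .safe_div(ch$RE, ch$r))),
  MTVI2    = list(set = "MS_VI", source = "printed",
                  channels = c("NIR", "g", "r"),
                  fun = function(ch) {
                    disc <- (2 * ch$NIR + 1)^2 -
                      (6 * ch$NIR - 5 * sqrt(ch$r)) - 0.5
                    .safe_div(1.5 * (1.2 * (ch$NIR - ch$g) -
                                       2.5 * (ch$r - ch$g)),
                              sqrt(pmax(disc, 0)))
                  }),
  `Int2reg*` = list(set = "MS_VI", source = "printed",
                    channels = c("g", "r", "RE"),
                    fun = function(ch) (ch$g + ch$r + ch$RE) / 2),
  NDSIreg  = list(set = "MS_VI", source = "printed",
                  channels = c("RE", "NIR"),
                  fun = function(ch) .safe_div(ch$RE - ch$NIR,
                                               ch$RE + ch$NIR)),
  RECI     = list(set = "MS_VI", source = "printed",
                  channels = c("NIR", "RE"),
                  fun = function(ch) .safe_div(ch$NIR, ch$RE) - 1),
  SCCI     = list(set = "MS_VI", source = "printed",
                  channels = c("NIR", "r"),
                  fun = function(ch) {
                    if (any(ch$NIR <= 0) || any(ch$r <= 0))
                      stop("SCCI needs strictly positive NIR and r")
                    .safe_div(100 * (log(ch$NIR) - log(ch$r)),
                              .safe_div(ch$NIR - ch$r, ch$NIR + ch$r))
                  }),
  SI2reg   = list(set = "MS_VI", source = "printed",
                  channels = c("g", "RE", "NIR"),
                  fun = function(ch) sqrt(ch$g^2 + ch$RE^2 + ch$NIR^2)),
  NDVI     = list(set = "MS_VI", source = "literature",
                  channels = c("NIR", "r"),
                  fun = function(ch) .safe_div(ch$NIR - ch$r,
                                               ch$NIR + ch$r)),
  GNDVI    = list(set = "MS_VI", source = "literature",
                  channels = c("NIR", "g"),
                  fun = function(ch) .safe_div(ch$NIR - ch$g,
                                               ch$NIR + ch$g))
)

#' Registry of vegetation indices
#'
#' Lists every registered vegetation index with its feature namespace
#' (`RGB_VI` or `MS_VI`), the channels its formula reads, and whether the
#' formula has a normative printed definition or is taken from the standard
#' literature form.
#'
#' @param set Optional filter, `"RGB_VI"` or `"MS_VI"`.
#' @return A `data.frame` with columns `name`, `set`, `source`, `channels`.
#' @examples
#' head(index_registry("RGB_VI"))
#' @export
index_registry <- function(set = NULL) {
  out <- data.frame(
    name = names(.index_defs),
    set = vapply(.index_defs, `[[`, "", "set"),
    source = vapply(.index_defs, `[[`, "", "source"),
    channels = vapply(.index_defs, function(d)
      paste(d$channels, collapse = ","), ""),
    row.names = NULL
  )
  if (!is.null(set)) out <- out[out$set == set, , drop = FALSE]
  out
}

.get_index <- function(name) {
  def <- .index_defs[[name]]
  if (is.null(def)) stop("unknown vegetation index: ", name)
  def
}

.compute_index <- function(name, ch) {
  def <- .get_index(name)
  missing <- setdiff(def$channels, names(ch))
  if (length(missing))
    stop("index ", name, " needs channel(s) ",
         paste(missing, collapse = ", "))
  def$fun(ch)
}

#' Evaluate a vegetation index at reflectance values
#'
#' `rgb_index` evaluates an RGB-channel index; `ms_index` a multispectral
#' one. Channel arguments are vectorised, so whole rasters can be passed
#' as flat vectors.
#'
#' @param name Registered index name (see [index_registry()]).
#' @param R,G,B RGB channel reflectances in \[0, 1\].
#' @param b,g,r,RE,NIR Multispectral band reflectances in \[0, 1\].
#' @return Index value(s).
#' @examples
#' rgb_index("CIVE", R = 0, G = 0, B = 0)  # the additive constant
#' ms_index("NDVIreg", NIR = 0.5, RE = 0.25)
#' @export
rgb_index <- function(name, R, G, B) {
  def <- .get_index(name)
  if (def$set != "RGB_VI") stop(name, " is not an RGB index")
  ch <- list()
  if (!missing(R)) ch$R <- R
  if (!missing(G)) ch$G <- G
  if (!missing(B)) ch$B <- B
  .compute_index(name, ch)
}

#' @rdname rgb_index
#' @export
ms_index <- function(name, b, g, r, RE, NIR) {
  def <- .get_index(name)
  if (def$set != "MS_VI") stop(name, " is not a multispectral index")
  ch <- list()
  if (!missing(b)) ch$b <- b
  if (!missing(g)) ch$g <- g
  if (!missing(r)) ch$r <- r
  if (!missing(RE)) ch$RE <- RE
  if (!missing(NIR)) ch$NIR <- NIR
  .compute_index(name, ch)
}

#' Per-canopy means of vegetation indices
#'
#' Computes each index per pixel over every canopy mask and averages it
#' tree-by-tree, mirroring zonal statistics over digitised crown polygons.
#'
#' @param scene A [generate_scene()] scene (or any list with elements
#'   `raster` and `canopies`).
#' @param index_set Character vector of registered index names; default is
#'   every RGB index, plus every multispectral index when the scene carries
#'   the five band planes.
#' @return A [feature_table()] with one row per tree and namespaced
#'   feature columns (`RGB_VI:...`, `MS_VI:...`).
#' @export
extract_canopy_means <- function(scene, index_set = NULL) {
  channels <- dimnames(scene$raster)[[3]]
  if (is.null(index_set)) {
    reg <- index_registry()
    keep <- vapply(reg$name, function(nm)
      all(.get_index(nm)$channels %in% channels), TRUE)
    index_set <- reg$name[keep]
  }
  if (anyDuplicated(index_set)) stop("duplicate index names requested")
  ids <- names(scene$canopies)
  npix <- vapply(scene$canopies, nrow, 0L)
  if (any(npix == 0))
    stop("empty canopy mask for tree(s): ",
         paste(ids[npix == 0], collapse = ", "))

  # flatten all mask pixels once, then compute each index in one shot
  px <- do.call(rbind, scene$canopies)
  tree_of <- rep(seq_along(ids), npix)
  nr <- dim(scene$raster)[1]
  flat <- (px[, 2] - 1L) * nr + px[, 1]
  ch <- lapply(seq_along(channels), function(k)
    scene$raster[, , k][flat])
  names(ch) <- channels

  vals <- matrix(NA_real_, length(ids), length(index_set),
                 dimnames = list(ids, NULL))
  namespaced <- character(length(index_set))
  for (j in seq_along(index_set)) {
    def <- .get_index(index_set[j])
    missing_ch <- setdiff(def$channels, channels)
    if (length(missing_ch))
      stop("index ", index_set[j], " not computable: scene lacks ",
           paste(missing_ch, collapse = ", "))
    pix_val <- .compute_index(index_set[j], ch)
    vals[, j] <- rowsum(pix_val, tree_of)[, 1] / npix
    namespaced[j] <- paste0(def$set, ":", index_set[j])
  }
  colnames(vals) <- namespaced
  feature_table(vals, tree_id = ids)
}
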