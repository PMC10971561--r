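# GLCM texture features over the first principal component of the RGB
# channels. The single-patch functions here are the pure-R reference; the
# sliding-window raster path is compiled (src/texture.cpp) as raster
# texture tools in this field usually are.

#' First principal component of the RGB channels
#'
#' Projects every pixel's (R, G, B) vector onto the leading eigenvector of
#' the 3x3 channel covariance, the usual dimensionality reduction before
#' GLCM texture extraction. The eigenvector sign is fixed so the loading on
#' G is non-negative; the projection is linearly rescaled to \[0, 1\].
#'
#' @param raster rows x cols x >=3 array; the first three channels (or the
#'   channels named `R`, `G`, `B`) are used.
#' @return rows x cols matrix in \[0, 1\].
#' @export
pca_first_component <- function(raster) {
  channels <- dimnames(raster)[[3]]
  idx <- if (!is.null(channels) && all(c("R", "G", "B") %in% channels))
    match(c("R", "G", "B"), channels) else 1:3
  X <- cbind(as.vector(raster[, , idx[1]]),
             as.vector(raster[, , idx[2]]),
             as.vector(raster[, , idx[3]]))
  if (nrow(unique(X)) < 2)
    stop("degenerate covariance: raster has < 2 distinct pixel vectors")
  cv <- stats::cov(X)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[1] <= 1e-12 * max(1, sum(diag(cv))))
    stop("degenerate covariance: no direction of variance")
  v <- eg$vectors[, 1]
  if (v[2] < 0 || (v[2] == 0 && sum(v) < 0)) v <- -v
  proj <- X %*% v
  rng <- range(proj)
  out <- if (diff(rng) > 0) (proj - rng[1]) / diff(rng) else proj * 0
  matrix(out, nrow = dim(raster)[1])
}

#' Quantise a \[0, 1\] raster to grey levels
#'
#' Linear binning of the global \[0, 1\] range into `levels` bins,
#' independent of any mask, so co-occurrence statistics are comparable
#' across scenes.
#'
#' @param x Numeric matrix in \[0, 1\].
#' @param levels Number of grey levels N.
#' @return Integer matrix with values in 0..N-1.
#' @export
quantise_grey <- function(x, levels = 32) {
  stopifnot(levels >= 2)
  q <- floor(pmin(pmax(x, 0), 1) * levels)
  q[q == levels] <- levels - 1L
  storage.mode(q) <- "integer"
  q
}

#' Grey-level co-occurrence matrix of a patch
#'
#' Counts co-occurring grey-level pairs at a spatial offset, optionally
#' symmetrised (pairs counted in both directions), normalised to sum 1.
#'
#' @param patch Integer matrix of grey levels in 0..levels-1.
#' @param levels Number of grey levels N (>= 2).
#' @param offset Integer `(d_row, d_col)` displacement.
#' @param symmetric Count each pair in both directions?
#' @return An object of class `glcm`: list with `P` (N x N probability
#'   matrix, rows = level i of the reference pixel), `levels`, `offset`,
#'   `symmetric`.
#' @examples
#' g <- glcm(rbind(c(0, 1), c(0, 1)), levels = 2, offset = c(0, 1))
#' g$P  # P[1,2] = P[2,1] = 0.5
#' @export
glcm <- function(patch, levels, offset = c(0, 1), symmetric = TRUE) {
  stopifnot(levels >= 2, length(offset) == 2)
  patch <- as.matrix(patch)
  if (any(patch < 0) || any(patch >= levels))
    stop("patch values must lie in 0..levels-1")
  dr <- offset[1]; dc <- offset[2]
  nr <- nrow(patch); nc <- ncol(patch)
  rows <- seq_len(nr - abs(dr)); cols <- seq_len(nc - abs(dc))
  if (!length(rows) || !length(cols))
    stop("no valid pixel pairs: patch smaller than offset span")
  r1 <- if (dr >= 0) rows else rows + abs(dr)
  c1 <- if (dc >= 0) cols else cols + abs(dc)
  a <- patch[r1, c1, drop = FALSE]
  b <- patch[r1 + dr, c1 + dc, drop = FALSE]
  counts <- matrix(tabulate(as.vector(a) * levels + as.vector(b) + 1L,
                            nbins = levels * levels),
                   levels, levels, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  structure(list(P = counts / sum(counts), levels = levels,
                 offset = offset, symmetric = symmetric), class = "glcm")
}

#' The eight GLCM texture statistics
#'
#' Standard Haralick-style statistics over the co-occurrence probabilities
#' `P[i, j]` (0-based levels i, j):
#' mean `= sum(i P)`, var `= sum((i-mean)^2 P)`,
#' hom `= sum(P / (1+(i-j)^2))`, con `= sum((i-j)^2 P)`,
#' dis `= sum(|i-j| P)`, ent `= -sum(P log P)` (0 log 0 := 0),
#' sm `= sum(P^2)`, corr `= sum((i-mu_i)(j-mu_j) P) / (sigma_i sigma_j)`
#' (defined as 1 when a marginal is degenerate).
#'
#' `paper_literal = TRUE` switches mean, dis, ent and sm to the variant
#' forms that carry a leading `i` factor inside the sum
#' (`sum(i P |i-j|)`, `sum(i P (-log P))`, `sum(i P^2)`); these are kept
#' for comparison only and are not the defaults.
#'
#' @param m A [glcm()].
#' @param paper_literal Use the variant literal forms for mean/dis/ent/sm?
#' @return Named numeric vector
#'   `mean, var, hom, con, dis, ent, sm, corr`.
#' @export
texture_stats <- function(m, paper_literal = FALSE) {
  stopifnot(inherits(m, "glcm"))
  P <- m$P
  N <- m$levels
  i <- matrix(0:(N - 1), N, N)        # row index (reference pixel level)
  j <- t(i)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  var_i <- sum((i - mu_i)^2 * P); var_j <- sum((j - mu_j)^2 * P)
  nzP <- P[P > 0]
  ent <- -sum(nzP * log(nzP))
  corr <- if (var_i <= 0 || var_j <= 0) 1 else
    sum((i - mu_i) * (j - mu_j) * P) / sqrt(var_i * var_j)
  if (paper_literal) {
    nz <- P > 0
    c(mean = mu_i, var = var_i,
      hom = sum(P / (1 + (i - j)^2)), con = sum((i - j)^2 * P),
      dis = sum(i * P * abs(i - j)),
      ent = -sum((i * P * log(P))[nz]),
      sm = sum(i * P^2), corr = corr)
  } else {
    c(mean = mu_i, var = var_i,
      hom = sum(P / (1 + (i - j)^2)), con = sum((i - j)^2 * P),
      dis = sum(abs(i - j) * P), ent = ent, sm = sum(P^2), corr = corr)
  }
}

#' Default co-occurrence offsets
#'
#' The four standard 1-pixel displacements (0, 1), (1, 0), (1, 1),
#' (1, -1), averaged for approximate rotation invariance.
#'
#' @return 4 x 2 integer matrix.
#' @export
default_offsets <- function() {
  matrix(c(0L, 1L, 1L, 0L, 1L, 1L, 1L, -1L), ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("d_row", "d_col")))
}

.texture_names <- c("mean", "var", "hom", "con", "dis", "ent", "sm", "corr")

#' Sliding-window texture rasters
#'
#' Computes the eight GLCM statistics in a sliding window around every
#' pixel of a single-channel \[0, 1\] raster (normally the PCA first
#' component), averaging over the co-occurrence offsets. Edges are handled
#' by reflective padding.
#'
#' @param pc1 rows x cols matrix in \[0, 1\].
#' @param levels Grey levels for quantisation (default 32).
#' @param window Odd window side length in pixels (default 7).
#' @param offsets Integer matrix of `(d_row, d_col)` offsets.
#' @param symmetric Symmetrise each GLCM?
#' @param paper_literal See [texture_stats()].
#' @return Named list of eight rows x cols matrices.
#' @export
texture_rasters <- function(pc1, levels = 32, window = 7,
                            offsets = default_offsets(), symmetric = TRUE,
                            paper_literal = FALSE) {
  stopifnot(window %% 2 == 1, window >= 3, levels >= 2)
  offsets <- matrix(as.integer(offsets), ncol = 2)
  if (any(abs(offsets) >= window))
    stop("window smaller than offset span")
  q <- quantise_grey(pc1, levels)
  out <- texture_rasters_cpp(q, as.integer(levels), as.integer(window),
                             offsets, isTRUE(symmetric),
                             isTRUE(paper_literal))
  names(out) <- .texture_names
  out
}

#' Per-canopy GLCM texture features
#'
#' PCA first component of the scene's RGB channels, sliding-window texture
#' rasters, then per-canopy means — one `RGB_TF:` feature column per
#' statistic.
#'
#' @param scene A [generate_scene()] scene.
#' @inheritParams texture_rasters
#' @return A [feature_table()] with the eight `RGB_TF:*` columns.
#' @export
canopy_texture_features <- function(scene, levels = 32, window = 7,
                                    offsets = default_offsets(),
                                    symmetric = TRUE,
                                    paper_literal = FALSE) {
  pc1 <- pca_first_component(scene$raster)
  tex <- texture_rasters(pc1, levels, window, offsets, symmetric,
                         paper_literal)
  ids <- names(scene$canopies)
  npix <- vapply(scene$canopies, nrow, 0L)
  if (any(npix == 0))
    stop("empty canopy mask for tree(s): ",
         paste(ids[npix == 0], collapse = ", "))
  px <- do.call(rbind, scene$canopies)
  tree_of <- rep(seq_along(ids), npix)
  nr <- nrow(pc1)
  flat <- (px[, 2] - 1L) * nr + px[, 1]
  vals <- vapply(tex, function(m) rowsum(m[flat], tree_of)[, 1] / npix,
                 numeric(length(ids)))
  colnames(vals) <- paste0("RGB_TF:", .texture_names)
  feature_table(vals, tree_id = ids)
}
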