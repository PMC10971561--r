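test_that("PCA first component recovers structure of simple rasters", {
  # greyscale raster (R=G=B): PC1 is that greyscale up to affine rescale
  set.seed(1)
  grey <- matrix(runif(64), 8, 8)
  ras <- array(rep(grey, 3), c(8, 8, 3),
               dimnames = list(NULL, NULL, c("R", "G", "B")))
  pc1 <- pca_first_component(ras)
  rng <- range(grey)
  expect_equal(pc1, (grey - rng[1]) / diff(rng), tolerance = 1e-10)

  # PC1 variance is at least each single channel's variance
  set.seed(2)
  ras2 <- array(runif(8 * 8 * 3), c(8, 8, 3),
                dimnames = list(NULL, NULL, c("R", "G", "B")))
  X <- apply(ras2, 3, as.vector)
  v <- eigen(cov(X), symmetric = TRUE)$values[1]
  expect_true(all(v >= apply(X, 2, var) - 1e-12))

  # two-colour image separates into exactly two PC1 values, 0 and 1
  ras3 <- array(0, c(4, 4, 3), dimnames = list(NULL, NULL, c("R", "G", "B")))
  ras3[, 1:2, ] <- rep(c(0.1, 0.6, 0.2), each = 8)
  ras3[, 3:4, ] <- rep(c(0.5, 0.2, 0.4), each = 8)
  pc3 <- pca_first_component(ras3)
  expect_setequal(unique(as.vector(pc3)), c(0, 1))

  ras4 <- array(0.3, c(4, 4, 3), dimnames = list(NULL, NULL, c("R", "G", "B")))
  expect_error(pca_first_component(ras4), "degenerate")
})

test_that("single-patch GLCMs count co-occurrences correctly", {
  # constant patch: one nonzero cell of mass 1
  g <- glcm(matrix(3L, 4, 4), levels = 8, offset = c(0, 1))
  expect_equal(sum(g$P), 1)
  expect_equal(g$P[4, 4], 1)
  expect_equal(sum(g$P > 0), 1)

  # enumerated 2x2 example
  g2 <- glcm(rbind(c(0L, 1L), c(0L, 1L)), levels = 2, offset = c(0, 1),
             symmetric = TRUE)
  expect_equal(g2$P, matrix(c(0, 0.5, 0.5, 0), 2, 2))

  # any patch normalises to total mass 1; symmetric P equals t(P)
  set.seed(3)
  for (i in 1:5) {
    patch <- matrix(sample(0:5, 36, replace = TRUE), 6, 6)
    g3 <- glcm(patch, levels = 6, offset = c(1, 1))
    expect_equal(sum(g3$P), 1, tolerance = 1e-9)
    expect_equal(g3$P, t(g3$P))
  }

  expect_error(glcm(matrix(0L, 1, 1), levels = 2, offset = c(0, 1)),
               "no valid pixel pairs")
})

test_that("texture statistics have their closed-form values on degenerate GLCMs", {
  st <- texture_stats(glcm(matrix(2L, 3, 3), levels = 4))
  expect_equal(st[["con"]], 0)
  expect_equal(st[["dis"]], 0)
  expect_equal(st[["ent"]], 0)
  expect_equal(st[["sm"]], 1)
  expect_equal(st[["hom"]], 1)
  expect_equal(st[["corr"]], 1)  # degenerate marginals

  # two-cell GLCM P01 = P10 = 0.5
  st2 <- texture_stats(glcm(rbind(c(0L, 1L), c(0L, 1L)), levels = 2))
  expect_equal(st2[["con"]], 1)
  expect_equal(st2[["dis"]], 1)
  expect_equal(st2[["sm"]], 0.5)
  expect_equal(st2[["ent"]], log(2))
  expect_equal(st2[["mean"]], 0.5)
  expect_equal(st2[["corr"]], -1)
})

test_that("GLCM and statistics match the naive double-loop oracle on random patches", {
  set.seed(42)
  for (rep in 1:200) {
    levels <- sample(2:8, 1)
    patch <- matrix(sample(0:(levels - 1), 64, replace = TRUE), 8, 8)
    offset <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))[[sample(4, 1)]]
    symmetric <- sample(c(TRUE, FALSE), 1)
    g <- glcm(patch, levels, offset, symmetric)
    expect_equal(g$P, naive_glcm(patch, levels, offset, symmetric),
                 tolerance = 1e-12)
    expect_equal(texture_stats(g), naive_texture_stats(g$P),
                 tolerance = 1e-10)
  }
})

test_that("variant literal texture forms differ only in their leading index factor", {
  g <- glcm(rbind(c(0L, 1L, 2L), c(2L, 0L, 1L)), levels = 3)
  std <- texture_stats(g)
  lit <- texture_stats(g, paper_literal = TRUE)
  P <- g$P
  i <- matrix(0:2, 3, 3)
  j <- t(i)
  expect_equal(lit[["dis"]], sum(i * P * abs(i - j)))
  expect_equal(lit[["ent"]], -sum((i * P * log(P))[P > 0]))
  expect_equal(lit[["sm"]], sum(i * P^2))
  expect_equal(lit[["mean"]], std[["mean"]])
  expect_equal(lit[["con"]], std[["con"]])
})

test_that("sliding-window rasters agree with the pure-R path window by window", {
  set.seed(7)
  img <- matrix(runif(20 * 20), 20, 20)
  levels <- 8; window <- 5; half <- window %/% 2
  offs <- default_offsets()
  tex <- texture_rasters(img, levels = levels, window = window,
                         offsets = offs)
  q <- quantise_grey(img, levels)
  # interior pixels: reconstruct each window and use glcm()/texture_stats()
  for (px in list(c(5, 5), c(10, 14), c(17, 3))) {
    win <- q[(px[1] - half):(px[1] + half), (px[2] - half):(px[2] + half)]
    ref <- rowMeans(vapply(seq_len(nrow(offs)), function(o)
      texture_stats(glcm(win, levels, offs[o, ])), numeric(8)))
    got <- vapply(tex, function(m) m[px[1], px[2]], 0)
    expect_equal(got, ref, tolerance = 1e-10)
  }
  expect_error(texture_rasters(img, window = 3,
                               offsets = matrix(c(0L, 5L), 1)),
               "offset span")
})

test_that("interior canopy texture is grain-controlled: zero when noise-free, ordered by class grain", {
  erode <- function(mask, depth) {
    key <- paste(mask[, 1], mask[, 2])
    keep <- vapply(seq_len(nrow(mask)), function(i) {
      nb <- expand.grid(r = mask[i, 1] + (-depth:depth),
                       c = mask[i, 2] + (-depth:depth))
      all(paste(nb$r, nb$c) %in% key)
    }, TRUE)
    mask[keep, , drop = FALSE]
  }
  interior_con <- function(sc) {
    pc1 <- pca_first_component(sc$raster)
    tex <- texture_rasters(pc1)
    nr <- nrow(pc1)
    con <- vapply(names(sc$canopies), function(id) {
      m <- erode(sc$canopies[[id]], 3)  # window half-width
      if (nrow(m) == 0) return(NA_real_)
      mean(tex$con[(m[, 2] - 1) * nr + m[, 1]])
    }, 0)
    tapply(con, sc$truth$level, mean, na.rm = TRUE)
  }

  # zero-noise scene: interior windows hold a single grey level => con = 0
  sc0 <- generate_scene(scene_config(n_trees_per_class = 4,
                                     image_size = 120,
                                     canopy_radius_range = c(4, 6),
                                     class_color_sd = 0,
                                     texture_grain = c(0, 0, 0, 0),
                                     shadow_fraction = 0, seed = 8))
  expect_equal(as.vector(interior_con(sc0)), rep(0, 4))

  # grainier class => strictly larger mean interior contrast, over seeds
  cons <- vapply(1:10, function(seed)
    interior_con(generate_scene(scene_config(n_trees_per_class = 8,
                                             image_size = 140,
                                             canopy_radius_range = c(4, 6),
                                             seed = seed))),
    numeric(4))
  expect_true(all(diff(rowMeans(cons)) > 0))
})

test_that("reattaching shuffled canopy ids yields identical texture values", {
  sc <- generate_scene(tiny_config(seed = 8, n = 3))
  tf <- canopy_texture_features(sc)
  sc2 <- sc
  sc2$canopies <- sc2$canopies[rev(seq_along(sc2$canopies))]
  tf2 <- canopy_texture_features(sc2)
  expect_equal(tf2$values[rownames(tf$values), ], tf$values)
})
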