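# Golden tests of every registered index formula against an independent
# re-derivation written out here in plain arithmetic.

# three fixed reflectance points with all denominators away from zero
.pts <- list(
  list(R = 0.20, G = 0.45, B = 0.18, b = 0.05, g = 0.12, r = 0.06,
       RE = 0.32, NIR = 0.45),
  list(R = 0.55, G = 0.35, B = 0.18, b = 0.07, g = 0.11, r = 0.15,
       RE = 0.26, NIR = 0.30),
  list(R = 0.40, G = 0.41, B = 0.39, b = 0.09, g = 0.10, r = 0.11,
       RE = 0.23, NIR = 0.22))

# independent formula transcription (plain arithmetic, no registry code)
.oracle <- list(
  R = quote(R), G = quote(G), B = quote(B),
  CIVE = quote(0.441 * R - 0.881 * G + 0.3856 * B + 18.78745),
  ExR = quote(1.4 * R - G),
  ExG = quote(2 * G - R - B),
  GBRI = quote(G / B),
  RBRI = quote(R / B),
  RGRI = quote(R / G),
  GCC = quote(G / (R + G + B)),
  VDVI = quote((G - B - R) / (G + B + R)),
  GLA = quote((2 * G - R - B) / (2 * G + R + B)),
  GB = quote(G - B),
  VARI = quote((G - R) / (G + R - B)),
  GRVI = quote((G - R) / (G + R)),
  NGRVI = quote((G^2 - R^2) / (G^2 + R^2)),
  PPR = quote((G - B) / (G + B)),
  WI = quote((G - B) / (R - G)),
  ExGR = quote((2 * G - R - B) - (1.4 * R - G)),
  RGBVI = quote((G^2 - B * R) / (G^2 + B * R)),
  `2NLI` = quote((NIR^2 - g) / (NIR^2 + g)),
  GDVI = quote(NIR - g),
  GMNLI = quote(1.5 * (NIR^0.5 - g) / (NIR^0.5 + g + 0.5)),
  NDVIreg = quote((NIR - RE) / (NIR + RE)),
  SI1reg = quote((g * RE)^0.5),
  `SI1reg*` = quote((r * RE)^0.5),
  TCARI = quote(3 * ((RE - r) - 0.2 * (RE - g) * (RE / r))),
  MTVI2 = quote(1.5 * (1.2 * (NIR - g) - 2.5 * (r - g)) /
                  sqrt((2 * NIR + 1)^2 - (6 * NIR - 5 * r^0.5) - 0.5)),
  `Int2reg*` = quote((g + r + RE) / 2),
  NDSIreg = quote((RE - NIR) / (RE + NIR)),
  RECI = quote((NIR / RE) - 1),
  SCCI = quote(100 * (log(NIR) - log(r)) / ((NIR - r) / (NIR + r))),
  SI2reg = quote(sqrt(g^2 + RE^2 + NIR^2)),
  NDVI = quote((NIR - r) / (NIR + r)),
  GNDVI = quote((NIR - g) / (NIR + g)))

test_that("every registered index matches its hand-transcribed formula", {
  reg <- index_registry()
  expect_setequal(reg$name, names(.oracle))
  for (nm in reg$name) {
    fun <- if (reg$set[reg$name == nm] == "RGB_VI") {
      function(p) rgb_index(nm, R = p$R, G = p$G, B = p$B)
    } else {
      function(p) ms_index(nm, b = p$b, g = p$g, r = p$r, RE = p$RE,
                           NIR = p$NIR)
    }
    for (p in .pts)
      expect_equal(fun(p), eval(.oracle[[nm]], p), tolerance = 1e-9,
                   label = nm, expected.label = paste("oracle", nm))
  }
})

test_that("printed edge values and simple identities hold", {
  expect_equal(rgb_index("CIVE", R = 0, G = 0, B = 0), 18.78745)
  expect_equal(rgb_index("ExG", R = 0.37, G = 0.37, B = 0.37), 0)
  expect_equal(rgb_index("RGRI", R = 0.3, G = 0.3), 1)
  expect_equal(rgb_index("VDVI", R = 0.1, G = 0.4, B = 0.1), 1 / 3,
               tolerance = 1e-9)
  expect_equal(ms_index("NDVIreg", NIR = 0.4, RE = 0.4), 0)
  expect_equal(ms_index("GDVI", NIR = 0.5, g = 0.2), 0.3)
  expect_equal(ms_index("SI1reg", g = 0.04, RE = 0.25), 0.1)
  expect_equal(ms_index("RECI", NIR = 0.3, RE = 0.3), 0)
})

test_that("unknown names and namespace mixups are rejected", {
  expect_error(rgb_index("NOPE", R = 1, G = 1, B = 1), "unknown")
  expect_error(rgb_index("NDVIreg", R = 1, G = 1, B = 1), "not an RGB")
  expect_error(ms_index("ExG", g = 0.1), "not a multispectral")
  expect_error(ms_index("SCCI", NIR = 0, r = 0.2), "positive")
})

test_that("zero denominators fall back to the eps-padded ratio", {
  expect_equal(rgb_index("RGRI", R = 0.3, G = 0), 0.3 / 1e-9)
  expect_equal(rgb_index("GCC", R = 0, G = 0, B = 0), 0)
  # fallback only engages at exactly zero
  expect_equal(rgb_index("GBRI", G = 0.4, B = 0.2), 2)
})

test_that("canopy means equal per-pixel index values averaged per tree", {
  px1 <- cbind(row = c(3, 3, 4), col = c(3, 4, 3),
               R = 0.2, G = 0.5, B = 0.1)
  px2 <- cbind(row = c(9, 9), col = c(9, 10),
               R = c(0.3, 0.5), G = c(0.4, 0.6), B = c(0.2, 0.2))
  sc <- manual_scene(list(t1 = px1, t2 = px2))
  ft <- extract_canopy_means(sc, c("ExG", "RGRI"))
  # constant canopy: mean equals the pixel formula value
  expect_equal(unname(ft$values["t1", "RGB_VI:ExG"]),
               2 * 0.5 - 0.2 - 0.1)
  # two-pixel canopy: arithmetic mean of per-pixel values
  expect_equal(unname(ft$values["t2", "RGB_VI:ExG"]),
               mean(c(2 * 0.4 - 0.3 - 0.2, 2 * 0.6 - 0.5 - 0.2)))
  expect_equal(unname(ft$values["t2", "RGB_VI:RGRI"]),
               mean(c(0.3 / 0.4, 0.5 / 0.6)))

  # permuting mask order leaves values identical up to row order
  sc2 <- sc
  sc2$canopies <- rev(sc2$canopies)
  ft2 <- extract_canopy_means(sc2, c("ExG", "RGRI"))
  expect_equal(ft2$values[rownames(ft$values), ], ft$values)

  sc3 <- sc
  sc3$canopies$t1 <- sc3$canopies$t1[0, , drop = FALSE]
  expect_error(extract_canopy_means(sc3, "ExG"), "t1")
})

test_that("min-max normalisation scales, stores bounds, and replays", {
  ft <- feature_table(cbind(`RGB_VI:a` = c(2, 4, 6),
                            `RGB_VI:b` = c(5, 5, 5)))
  nf <- normalise_features(ft)
  expect_equal(unname(nf$values[, "RGB_VI:a"]), c(0, 0.5, 1))
  expect_equal(unname(nf$values[, "RGB_VI:b"]), c(0, 0, 0))
  expect_true(all(nf$values >= 0 & nf$values <= 1))
  expect_error(normalise_features(nf), "already")
  # replay with stored bounds reproduces the result exactly
  again <- normalise_features(ft, bounds = nf$bounds)
  expect_identical(again$values, nf$values)
  # held-out data outside the bounds scales by the stored range
  held <- feature_table(cbind(`RGB_VI:a` = 8, `RGB_VI:b` = 5))
  expect_equal(unname(normalise_features(held, nf$bounds)$values[1, 1]),
               1.5)
})

test_that("zero-noise class colours order RGRI canopy means as the colour model implies", {
  sc <- generate_scene(flat_config(seed = 4))
  ft <- extract_canopy_means(sc, "RGRI")
  m <- tapply(ft$values[, 1], sc$truth$level, mean)
  expect_equal(length(unique(round(m, 10))), 4)  # pairwise distinct
  expect_true(all(m["1"] < m[c("2", "3", "4")]))  # healthy lowest R/G
  expect_lt(m["2"], m["3"])  # damage reddening up to moderate
})
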