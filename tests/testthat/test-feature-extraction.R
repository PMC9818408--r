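test_that("grayscale uses BT.601 luma weights", {
  white <- array(255, c(2, 2, 3))
  expect_true(all(grayscale(white) == 255))
  red <- array(0, c(1, 1, 3)); red[1, 1, 1] <- 255
  expect_equal(as.numeric(grayscale(red)), 0.299 * 255)
  gray <- array(123, c(3, 3, 3))
  expect_true(all(grayscale(gray) == 123))
})

test_that("compiled convolution matches a naive double-loop oracle", {
  set.seed(9)
  x <- matrix(rnorm(16 * 16), 16, 16)
  k <- gabor_kernel(45, fast_gabor)
  expect_equal(swequant:::conv2_reflect(x, k), conv2_naive(x, k),
               tolerance = 1e-10)
  k2 <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  expect_equal(swequant:::conv2_reflect(x, k2), conv2_naive(x, k2),
               tolerance = 1e-10)
})

test_that("Gabor features are orientation sensitive with zero variance on constants", {
  flat <- matrix(42, 20, 20)
  gf <- gabor_features(flat, fast_gabor)
  expect_equal(unname(gf[grep("_var$", names(gf))]), rep(0, 4))

  stripes <- matrix(rep(c(0, 255), each = 2, length.out = 16 * 16), 16, 16)
  gs <- gabor_features(stripes, fast_gabor)  # horizontal stripes (vary by row)
  expect_false(isTRUE(all.equal(gs[["gabor_kernel2_var"]],
                                gs[["gabor_kernel4_var"]])))
})

test_that("rotating the image by 90 degrees swaps the 90- and 180-degree responses", {
  set.seed(10)
  x <- matrix(rnorm(24 * 24), 24, 24)
  xr <- t(x[nrow(x):1, ])  # 90-degree rotation
  g <- gabor_features(x, fast_gabor)
  gr <- gabor_features(xr, fast_gabor)
  # kernel2 = 90 deg, kernel4 = 180 deg; variances swap up to boundary effects
  expect_equal(gr[["gabor_kernel2_var"]], g[["gabor_kernel4_var"]],
               tolerance = 0.05)
  expect_equal(gr[["gabor_kernel4_var"]], g[["gabor_kernel2_var"]],
               tolerance = 0.05)
})

test_that("horizontal segmentation covers all rows without overlap", {
  s100 <- segment_horizontal(100, 10)
  expect_true(all(lengths(s100) == 10))
  s105 <- segment_horizontal(105, 10)
  expect_equal(lengths(s105), c(rep(11L, 5), rep(10L, 5)))
  expect_equal(sort(unlist(s105)), 1:105)
  expect_equal(sum(duplicated(unlist(s105))), 0)
  expect_equal(s105[[1]][1], 1L)
  expect_equal(rev(s105[[10]])[1], 105L)
  expect_error(segment_horizontal(5, 10), "height")
})

test_that("region features carry the 28 canonical values", {
  lut <- swe_lut(64)
  set.seed(12)
  v <- matrix(runif(20 * 15, 0.5, 10), 20, 15)
  rgb <- velocity_to_rgb(v, lut)
  f <- region_features(rgb, lut = lut, gabor = fast_gabor)
  expect_length(f, 28)
  expect_identical(names(f), swequant:::region_feature_names())

  # uniform gray region: degenerate statistics over pixels and channels
  fg <- region_features(array(100, c(8, 8, 3)), lut = lut, gabor = fast_gabor)
  expect_equal(fg[["mean"]], fg[["median"]])
  expect_equal(fg[["sd"]], 0)

  # uniform low-velocity color: every valid pixel in the low band
  ru <- velocity_to_rgb(matrix(2, 8, 8), lut)
  fu <- region_features(ru, lut = lut, gabor = fast_gabor)
  expect_equal(fu[["red_layer_value_sum"]], fu[["red_layer_value_mean"]] * 64)
  expect_equal(fu[["blue_pixels"]], 64)

  # hand-computed 2x2 red-channel arithmetic
  r2 <- array(0L, c(2, 2, 3))
  r2[, , 1] <- matrix(c(10L, 20L, 30L, 40L), 2, 2)
  f2 <- region_features(r2, lut = lut, gabor = fast_gabor)
  expect_equal(f2[["red_layer_value_sum"]], 100)
  expect_equal(f2[["red_layer_value_mean"]], 25)
  expect_equal(f2[["gray_value"]], sum(0.299 * c(10, 20, 30, 40)))
})

test_that("dummy encoding yields 13 + 2 reference-coded indicators", {
  acts <- default_activities()$activity
  d0 <- encode_dummies(acts[1], "s1")
  expect_length(d0, 15)
  expect_true(all(d0 == 0))
  d1 <- encode_dummies(acts[5], "s3")
  expect_equal(sum(d1[grep("^activity_", names(d1))]), 1)
  expect_equal(unname(d1[paste0("activity_", acts[5])]), 1)
  expect_equal(unname(d1["session_s3"]), 1)
  expect_error(encode_dummies("zumba", "s1"), "unknown activity")
  expect_error(encode_dummies(acts[1], "s9"), "unknown session")
})

test_that("the feature table has 308 image features and 323 feature columns", {
  cfg <- tiny_config(n_pain = 2, n_control = 2, image_height = 40,
                     image_width = 30, seed = 21)
  ds <- simulate_dataset(cfg)
  ft <- build_feature_table(ds, gabor = fast_gabor)
  cols <- feature_cols(ft)
  expect_length(cols, 323)
  expect_equal(sum(!grepl("^activity_|^session_", cols)), 308)
  expect_equal(sum(grepl("_hsegment_", cols)), 280)
  expect_true("blue_pixels_hsegment_10/10" %in% cols)
  expect_equal(nrow(ft), nrow(ds$manifest))
  expect_false(anyNA(ft[, cols]))
  expect_identical(ft$label, ds$manifest$group)
})

test_that("whole-image mean equals the row-weighted mean of segment means", {
  cfg <- tiny_config(n_pain = 2, n_control = 2, image_height = 45,
                     image_width = 30, seed = 22)
  ds <- simulate_dataset(cfg)
  ft <- build_feature_table(ds, gabor = fast_gabor)
  segs <- segment_horizontal(45, 10)
  wts <- lengths(segs) / 45
  seg_means <- as.matrix(ft[, sprintf("mean_hsegment_%d/10", 1:10)])
  expect_equal(as.numeric(seg_means %*% wts), ft$mean, tolerance = 1e-12)
})

test_that("feature extraction is deterministic across re-reads and duplicates", {
  cfg <- tiny_config(n_pain = 2, n_control = 2, image_height = 40,
                     image_width = 30, seed = 23)
  ds <- simulate_dataset(cfg)
  man <- ds$manifest[c(1, 1, 5), ]
  ft <- build_feature_table(man, lut = ds$lut, gabor = fast_gabor,
                            activity_levels = cfg$activities$activity)
  cols <- feature_cols(ft)
  expect_equal(as.numeric(ft[1, cols]), as.numeric(ft[2, cols]))
})

test_that("unreadable images are skipped and reported", {
  cfg <- tiny_config(n_pain = 2, n_control = 2, image_height = 40,
                     image_width = 30, seed = 24)
  ds <- simulate_dataset(cfg)
  man <- ds$manifest[1:5, ]
  man$path[3] <- file.path(ds$dir, "missing.png")
  expect_warning(
    ft <- build_feature_table(man, lut = ds$lut, gabor = fast_gabor,
                              activity_levels = cfg$activities$activity),
    "skipping")
  expect_equal(nrow(ft), 4)
  expect_equal(attr(ft, "skipped"), man$path[3])
})

test_that("feature tables round-trip through CSV with verbatim names", {
  cfg <- tiny_config(n_pain = 2, n_control = 2, image_height = 40,
                     image_width = 30, seed = 25)
  ds <- simulate_dataset(cfg)
  ft <- build_feature_table(ds$manifest[1:4, ], lut = ds$lut,
                            gabor = fast_gabor,
                            activity_levels = cfg$activities$activity)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  ft2 <- read_feature_table(path)
  expect_identical(feature_cols(ft2), feature_cols(ft))
  expect_equal(as.matrix(ft2[, feature_cols(ft2)]),
               as.matrix(ft[, feature_cols(ft)]), tolerance = 1e-12,
               ignore_attr = TRUE)
})
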