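make_stack <- function(n, h = 12, w = 10, mean = 100, sd = 20, seed = 1) {
  set.seed(seed)
  array(pmin(pmax(rnorm(h * w * 3 * n, mean, sd), 0), 255), c(h, w, 3, n))
}

test_that("summary image of a single all-pass image is the image itself", {
  img <- make_stack(1, seed = 41)
  si <- summary_image(img, group = "pain")
  expect_equal(si$mean, img[, , , 1])
  expect_true(all(si$count == 1))
})

test_that("summary means equal an exhaustive per-pixel loop oracle", {
  rgb <- make_stack(20, h = 6, w = 5, seed = 42)
  set.seed(43)
  quality <- array(runif(6 * 5 * 20), c(6, 5, 20))
  si <- summary_image(rgb, quality, threshold = 0.5)
  for (i in 1:6) for (j in 1:5) {
    keep <- quality[i, j, ] >= 0.5
    expect_equal(si$count[i, j], sum(keep))
    for (ch in 1:3) {
      expected <- if (any(keep)) mean(rgb[i, j, ch, keep]) else NA_real_
      expect_equal(si$mean[i, j, ch], expected)
    }
  }
  # two-image arithmetic
  two <- array(c(rep(100, 4 * 3 * 3), rep(200, 4 * 3 * 3)), c(4, 3, 3, 2))
  expect_true(all(summary_image(two)$mean == 150))
})

test_that("Hotelling's T2 is zero for identical samples and invariant to affine maps", {
  set.seed(44)
  a <- matrix(rnorm(60, 100, 10), 20, 3)
  h0 <- hotelling_t2(a, a)
  expect_equal(h0$t2, 0)
  expect_equal(h0$p_value, 1)

  b <- matrix(rnorm(45, 110, 10), 15, 3)
  h1 <- hotelling_t2(a, b)
  A <- matrix(c(2, 0.5, 0, 0, 1, -1, 0.3, 0, 3), 3, 3)
  shift <- c(5, -2, 7)
  h2 <- hotelling_t2(a %*% A + rep(shift, each = 20),
                     b %*% A + rep(shift, each = 15))
  expect_equal(h2$t2, h1$t2, tolerance = 1e-8)
  expect_equal(h2$p_value, h1$p_value, tolerance = 1e-8)
})

test_that("with one dimension the T2 p-value equals the two-sample t-test", {
  set.seed(45)
  a <- rnorm(20, 0, 1)
  b <- rnorm(18, 0.8, 1)
  h <- hotelling_t2(a, b)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(h$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(h$t2, unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("degenerate covariance is ridge-regularized and flagged, small n undefined", {
  a <- cbind(rnorm(10), 5, 7)
  b <- cbind(rnorm(10, 2), 5, 7)
  h <- hotelling_t2(a, b)
  expect_true(h$regularized)
  expect_true(is.finite(h$t2))
  expect_gte(h$t2, 0)

  h2 <- hotelling_t2(a[1:3, ], b)
  expect_true(h2$undefined)
  expect_true(is.na(h2$p_value))
})

test_that("the vectorized T2 map matches the per-pixel scalar test", {
  rgb_a <- make_stack(9, h = 5, w = 4, seed = 46)
  rgb_b <- make_stack(8, h = 5, w = 4, mean = 120, seed = 47)
  set.seed(48)
  qa <- array(runif(5 * 4 * 9, 0.3, 1), c(5, 4, 9))
  qb <- array(runif(5 * 4 * 8, 0.3, 1), c(5, 4, 8))
  tm <- t2_map(rgb_a, rgb_b, qa, qb, threshold = 0.5, min_n = 4)
  for (i in 1:5) for (j in 1:4) {
    keep_a <- qa[i, j, ] >= 0.5
    keep_b <- qb[i, j, ] >= 0.5
    ora <- hotelling_t2(t(rgb_a[i, j, , keep_a]), t(rgb_b[i, j, , keep_b]),
                        min_n = 4)
    if (ora$undefined) {
      expect_equal(tm$category[i, j], "undefined")
    } else {
      expect_equal(tm$t2[i, j], ora$t2, tolerance = 1e-8)
      expect_equal(tm$p[i, j], ora$p_value, tolerance = 1e-8)
    }
  }
})

test_that("map categories are nested and consistent with p-values", {
  rgb_a <- make_stack(12, seed = 49)
  rgb_b <- make_stack(12, mean = 115, seed = 50)
  tm <- t2_map(rgb_a, rgb_b)
  def <- tm$category != "undefined"
  expect_true(all(tm$p[def & tm$category == "p<0.01"] < 0.01))
  expect_true(all(tm$p[def & tm$category == "p<0.05"] >= 0.01 &
                    tm$p[def & tm$category == "p<0.05"] < 0.05))
  expect_true(all(tm$p[def & tm$category == "ns"] >= 0.05))
  expect_true(all(tm$n1 <= 12) && all(tm$n2 <= 12))
  # BH adjustment can only reduce the significant set
  tm_bh <- t2_map(rgb_a, rgb_b, p_adjust = "BH")
  sig <- function(x) sum(x$category %in% c("p<0.05", "p<0.01"))
  expect_lte(sig(tm_bh), sig(tm))
})

test_that("fully masked stacks give an all-undefined map", {
  rgb_a <- make_stack(6, seed = 51)
  rgb_b <- make_stack(6, seed = 52)
  qa <- array(0, c(12, 10, 6))
  qb <- array(0, c(12, 10, 6))
  tm <- t2_map(rgb_a, rgb_b, qa, qb)
  expect_true(all(tm$category == "undefined"))
  expect_true(all(is.na(tm$p)))
})

test_that("the T2 map rejects at the nominal rate under a Gaussian null", {
  set.seed(53)
  h <- 40; w <- 50
  rgb_a <- array(rnorm(h * w * 3 * 20, 128, 25), c(h, w, 3, 20))
  rgb_b <- array(rnorm(h * w * 3 * 20, 128, 25), c(h, w, 3, 20))
  tm <- t2_map(rgb_a, rgb_b)
  rate <- mean(tm$p < 0.05, na.rm = TRUE)
  bounds <- qbinom(c(0.005, 0.995), h * w, 0.05) / (h * w)
  expect_gte(rate, bounds[1])
  expect_lte(rate, bounds[2])
})

test_that("rendered maps round-trip exactly and use the documented palette", {
  rgb_a <- make_stack(10, seed = 54)
  rgb_b <- make_stack(10, mean = 105, seed = 55)  # weak shift: mixed categories
  tm <- t2_map(rgb_a, rgb_b)
  expect_true("ns" %in% tm$category)
  path <- withr::local_tempfile(fileext = ".png")
  render_map(tm, path)
  cats <- read_t2_categories(path)
  expect_identical(cats, tm$category)

  # ns pixels render gray
  img <- read_elastogram(path)
  ns <- which(tm$category == "ns", arr.ind = TRUE)[1, ]
  expect_equal(as.numeric(img[ns[1], ns[2], ]), c(128, 128, 128))

  # summary rendering of a uniform-velocity group is a uniform LUT color
  lut <- swe_lut(64)
  uni <- velocity_to_rgb(matrix(2, 8, 6), lut)
  stack <- array(rep(uni, 3), c(8, 6, 3, 3))
  si <- summary_image(stack)
  sp <- withr::local_tempfile(fileext = ".png")
  render_map(si, sp)
  back <- read_elastogram(sp)
  expect_equal(back, uni, ignore_attr = TRUE)
})
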