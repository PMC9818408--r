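#' Load a stack of elastograms (and quality maps) from a manifest
#'
#' @param manifest data.frame with columns `path` and optionally
#'   `quality_path`; typically a subset of a dataset manifest selecting one
#'   group/category.
#' @return list with `rgb` (H x W x 3 x N array, 0-255) and `quality`
#'   (H x W x N array, or `NULL` when no quality paths are present).
#' @export
load_stack <- function(manifest) {
  stopifnot(nrow(manifest) >= 1L, "path" %in% names(manifest))
  imgs <- lapply(manifest$path, read_elastogram)
  d <- dim(imgs[[1]])
  if (!all(vapply(imgs, function(i) identical(dim(i), d), logical(1)))) {
    stop("images in a stack must share dimensions")
  }
  rgb <- array(unlist(imgs), c(d, length(imgs)))
  quality <- NULL
  if ("quality_path" %in% names(manifest) &&
      all(nzchar(manifest$quality_path))) {
    qs <- lapply(manifest$quality_path, read_quality_map)
    quality <- array(unlist(qs), c(d[1], d[2], length(qs)))
  }
  list(rgb = rgb, quality = quality)
}

stack_mask <- function(quality, h, w, n, threshold) {
  if (is.null(quality)) {
    matrix(TRUE, h * w, n)
  } else {
    stopifnot(identical(dim(quality), c(h, w, n)))
    matrix(quality >= threshold, h * w, n)
  }
}

#' Pixelwise mean summary image of one group
#'
#' Arithmetic mean of the RGB values at every pixel over all images of a
#' group, restricted per pixel to the images in which that pixel passes the
#' quality threshold. Pixels that no image contributes to carry count 0 and
#' `NA` means.
#'
#' @param rgb H x W x 3 x N array of images (0-255), all same size.
#' @param quality optional H x W x N quality array in \[0, 1\].
#' @param threshold quality cut-off (default 0.5, the conventional 50%).
#' @param group,category optional labels carried into the result.
#' @return object of class `swe_summary_image`: list with `mean`
#'   (H x W x 3, real-valued), `count` (H x W), `group`, `category`.
#' @export
summary_image <- function(rgb, quality = NULL, threshold = 0.5,
                          group = NA_character_, category = NA_character_) {
  d <- dim(rgb)
  stopifnot(length(d) == 4L, d[3] == 3L)
  h <- d[1]; w <- d[2]; n <- d[4]
  m <- stack_mask(quality, h, w, n, threshold)
  count <- rowSums(m)
  mean_rgb <- array(NA_real_, c(h, w, 3L))
  for (ch in 1:3) {
    xc <- matrix(rgb[, , ch, ], h * w, n)
    s <- rowSums(xc * m)
    mc <- ifelse(count > 0, s / count, NA_real_)
    mean_rgb[, , ch] <- matrix(mc, h, w)
  }
  structure(list(mean = mean_rgb, count = matrix(count, h, w),
                 group = group, category = category, threshold = threshold),
            class = "swe_summary_image")
}

#' @export
#' @method print swe_summary_image
print.swe_summary_image <- function(x, ...) {
  cat(sprintf("Summary image (%s%s): %d x %d px, contributing images per pixel %d-%d\n",
              x$group, if (!is.na(x$category)) paste0(", ", x$category) else "",
              nrow(x$count), ncol(x$count), min(x$count), max(x$count)))
  invisible(x)
}

#' Two-sample Hotelling's T-squared test
#'
#' Multivariate generalization of the two-sample t-test comparing mean
#' vectors (here typically 3-dimensional RGB means):
#' `T2 = n1 n2 / (n1 + n2) * d' S^-1 d`, with `d` the mean difference and `S`
#' the pooled sample covariance. The p-value uses the exact F transform
#' `F = (n1 + n2 - p - 1) / (p (n1 + n2 - 2)) * T2` on
#' `(p, n1 + n2 - p - 1)` degrees of freedom. A singular pooled covariance
#' (for example a constant channel) is ridge-regularized by adding
#' `1e-6 * trace(S)/p` to the diagonal and flagged. With `p = 1` the test
#' reduces exactly to the equal-variance two-sample t-test.
#'
#' @param a,b numeric matrices (`n1 x p`, `n2 x p`) of observations; vectors
#'   are treated as single-column matrices.
#' @param min_n minimal per-group sample size; below it (or when
#'   `n1 + n2 - p - 1 <= 0`) the result is undefined (`NA`), not an error.
#' @return list with `t2`, `f`, `p_value`, `df` (length 2), `n1`, `n2`,
#'   `p_dim`, `regularized`, `undefined`.
#' @examples
#' a <- matrix(rnorm(60), 20, 3); hotelling_t2(a, a)$t2  # 0
#' @export
hotelling_t2 <- function(a, b, min_n = 5L) {
  if (is.vector(a)) a <- matrix(a, ncol = 1)
  if (is.vector(b)) b <- matrix(b, ncol = 1)
  stopifnot(ncol(a) == ncol(b))
  n1 <- nrow(a); n2 <- nrow(b); p <- ncol(a)
  df2 <- n1 + n2 - p - 1
  if (n1 < min_n || n2 < min_n || df2 <= 0) {
    return(list(t2 = NA_real_, f = NA_real_, p_value = NA_real_,
                df = c(p, df2), n1 = n1, n2 = n2, p_dim = p,
                regularized = FALSE, undefined = TRUE))
  }
  d <- colMeans(a) - colMeans(b)
  S <- ((n1 - 1) * stats::cov(a) + (n2 - 1) * stats::cov(b)) / (n1 + n2 - 2)
  regularized <- FALSE
  if (p == 1L) {
    if (S[1, 1] <= 0) { S[1, 1] <- S[1, 1] + 1e-6; regularized <- TRUE }
  } else if (rcond(S) < 1e-12) {
    S <- S + diag(1e-6 * sum(diag(S)) / p, p)
    regularized <- TRUE
  }
  t2 <- as.numeric(n1 * n2 / (n1 + n2) * t(d) %*% solve(S, d))
  f <- df2 / (p * (n1 + n2 - 2)) * t2
  list(t2 = t2, f = f,
       p_value = stats::pf(f, p, df2, lower.tail = FALSE),
       df = c(p, df2), n1 = n1, n2 = n2, p_dim = p,
       regularized = regularized, undefined = FALSE)
}

# per-pixel channel sums / cross-products of a masked stack
stack_moments <- function(rgb, m) {
  d <- dim(rgb)
  h <- d[1]; w <- d[2]; n <- d[4]
  xc <- lapply(1:3, function(ch) matrix(rgb[, , ch, ], h * w, n))
  count <- rowSums(m)
  sums <- lapply(xc, function(x) rowSums(x * m))
  means <- lapply(sums, function(s) ifelse(count > 0, s / count, NA_real_))
  cross <- vector("list", 6)  # 11,22,33,12,13,23 centered cross-products
  pairs <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  for (k in seq_along(pairs)) {
    i <- pairs[[k]][1]; j <- pairs[[k]][2]
    cross[[k]] <- rowSums(xc[[i]] * xc[[j]] * m) -
      count * means[[i]] * means[[j]]
  }
  list(count = count, means = means, cross = cross)
}

#' Pixelwise Hotelling's T-squared significance map
#'
#' Runs the two-sample Hotelling's T-squared test on the RGB 3-vectors at
#' every pixel, comparing the images of group A against group B, using at
#' each pixel only the images in which that pixel passes the quality
#' threshold. Pixels with fewer than `min_n` contributing images in either
#' group are marked `undefined`. Categories follow the conventional
#' three-level map: `ns` (p >= 0.05), `p<0.05`, `p<0.01` (nested: the
#' stricter category wins). No multiple-testing correction is applied by
#' default, matching the descriptive map character; `p_adjust = "BH"`
#' applies Benjamini-Hochberg across the defined pixels.
#'
#' @param rgb_a,rgb_b H x W x 3 x N arrays for the two groups.
#' @param quality_a,quality_b optional matching H x W x N quality arrays.
#' @param threshold quality cut-off (default 0.5).
#' @param min_n minimal per-group, per-pixel sample size (default 5, above
#'   the test's p + 1 lower bound).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @param alpha the two significance levels (default 0.05 and 0.01).
#' @return object of class `swe_t2map`: list with matrices `t2`, `p`,
#'   `category` (character: `"undefined"`, `"ns"`, `"p<0.05"`, `"p<0.01"`),
#'   `n1`, `n2`, `regularized`.
#' @export
t2_map <- function(rgb_a, rgb_b, quality_a = NULL, quality_b = NULL,
                   threshold = 0.5, min_n = 5L, p_adjust = c("none", "BH"),
                   alpha = c(0.05, 0.01)) {
  p_adjust <- match.arg(p_adjust)
  da <- dim(rgb_a); db <- dim(rgb_b)
  stopifnot(length(da) == 4L, length(db) == 4L,
            identical(da[1:3], db[1:3]), da[3] == 3L)
  h <- da[1]; w <- da[2]
  ma <- stack_mask(quality_a, h, w, da[4], threshold)
  mb <- stack_mask(quality_b, h, w, db[4], threshold)
  A <- stack_moments(rgb_a, ma)
  B <- stack_moments(rgb_b, mb)
  n1 <- A$count; n2 <- B$count
  df2 <- n1 + n2 - 3 - 1
  defined <- n1 >= min_n & n2 >= min_n & df2 > 0
  denom <- pmax(n1 + n2 - 2, 1)
  # pooled covariance entries (order 11,22,33,12,13,23)
  S <- lapply(1:6, function(k) (A$cross[[k]] + B$cross[[k]]) / denom)
  tr <- S[[1]] + S[[2]] + S[[3]]
  det3 <- function(S) {
    S[[1]] * (S[[2]] * S[[3]] - S[[6]]^2) -
      S[[4]] * (S[[4]] * S[[3]] - S[[6]] * S[[5]]) +
      S[[5]] * (S[[4]] * S[[6]] - S[[2]] * S[[5]])
  }
  dt <- det3(S)
  regularized <- defined & (!is.finite(dt) | abs(dt) < 1e-10 * pmax(tr / 3, 1e-12)^3)
  eps <- ifelse(regularized, 1e-6 * tr / 3 + 1e-12, 0)
  S[[1]] <- S[[1]] + eps; S[[2]] <- S[[2]] + eps; S[[3]] <- S[[3]] + eps
  dt <- det3(S)
  d1 <- A$means[[1]] - B$means[[1]]
  d2 <- A$means[[2]] - B$means[[2]]
  d3 <- A$means[[3]] - B$means[[3]]
  # S^-1 via cofactors; quadratic form d' S^-1 d
  c11 <- S[[2]] * S[[3]] - S[[6]]^2
  c22 <- S[[1]] * S[[3]] - S[[5]]^2
  c33 <- S[[1]] * S[[2]] - S[[4]]^2
  c12 <- S[[5]] * S[[6]] - S[[4]] * S[[3]]
  c13 <- S[[4]] * S[[6]] - S[[5]] * S[[2]]
  c23 <- S[[4]] * S[[5]] - S[[1]] * S[[6]]
  quad <- (d1^2 * c11 + d2^2 * c22 + d3^2 * c33 +
             2 * d1 * d2 * c12 + 2 * d1 * d3 * c13 + 2 * d2 * d3 * c23) / dt
  t2 <- n1 * n2 / pmax(n1 + n2, 1) * quad
  f <- df2 / (3 * denom) * t2
  pval <- stats::pf(f, 3, df2, lower.tail = FALSE)
  t2[!defined] <- NA_real_
  pval[!defined] <- NA_real_
  if (p_adjust == "BH") {
    pval[defined] <- stats::p.adjust(pval[defined], "BH")
  }
  cat_chr <- rep("undefined", h * w)
  cat_chr[defined & pval >= alpha[1]] <- "ns"
  cat_chr[defined & pval < alpha[1]] <- "p<0.05"
  cat_chr[defined & pval < alpha[2]] <- "p<0.01"
  structure(
    list(t2 = matrix(t2, h, w), p = matrix(pval, h, w),
         category = matrix(cat_chr, h, w),
         n1 = matrix(n1, h, w), n2 = matrix(n2, h, w),
         regularized = matrix(regularized, h, w),
         threshold = threshold, min_n = min_n, alpha = alpha,
         p_adjust = p_adjust),
    class = "swe_t2map")
}

#' @export
#' @method print swe_t2map
print.swe_t2map <- function(x, ...) {
  tab <- table(factor(x$category,
                      levels = c("undefined", "ns", "p<0.05", "p<0.01")))
  cat(sprintf("Hotelling's T2 map: %d x %d px (quality >= %.0f%%, min n = %d)\n",
              nrow(x$p), ncol(x$p), 100 * x$threshold, x$min_n))
  def <- sum(tab[-1])
  cat(sprintf("  undefined %d | ns %d | p<0.05 %d | p<0.01 %d (%.1f%% of defined pixels significant)\n",
              tab[[1]], tab[[2]], tab[[3]], tab[[4]],
              if (def > 0) 100 * (tab[[3]] + tab[[4]]) / def else 0))
  invisible(x)
}

t2_palette <- function() {
  rbind("undefined" = c(0, 0, 0),
        "ns" = c(128, 128, 128),
        "p<0.05" = c(0, 255, 0),
        "p<0.01" = c(255, 255, 0))
}

#' Render a summary image or T2 map to a PNG file
#'
#' Summary images are written with their mean RGB values (uncovered pixels
#' black); T2 maps use the three-category palette: gray = not significant,
#' green = p < 0.05, yellow = p < 0.01, black = undefined. The categorical
#' palette colors are exact, so categories are recoverable from the file.
#'
#' @param x an `swe_summary_image` or `swe_t2map`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
render_map <- function(x, path) {
  UseMethod("render_map")
}

#' @export
render_map.swe_summary_image <- function(x, path) {
  img <- x$mean
  img[is.na(img)] <- 0
  png::writePNG(img / 255, path)
  invisible(path)
}

#' @export
render_map.swe_t2map <- function(x, path) {
  pal <- t2_palette()
  idx <- match(x$category, rownames(pal))
  h <- nrow(x$category); w <- ncol(x$category)
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- matrix(pal[idx, ch], h, w)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Read categories back from a rendered T2 map PNG
#' @param path PNG path written by [render_map()].
#' @return character matrix of categories.
#' @export
read_t2_categories <- function(path) {
  img <- read_elastogram(path)
  pal <- t2_palette()
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- matrix(as.numeric(img), h * w, 3)
  idx <- apply(pal, 1, function(col) {
    rowSums(sweep(px, 2, col)^2) == 0
  })
  cat_chr <- rownames(pal)[max.col(idx, ties.method = "first")]
  cat_chr[rowSums(idx) == 0] <- NA_character_
  matrix(cat_chr, h, w)
}

#' Export a T2 map as a per-pixel CSV
#'
#' Columns: `row`, `col`, `t2`, `p`, `category`.
#'
#' @param x an `swe_t2map`.
#' @param path CSV path.
#' @export
write_t2_csv <- function(x, path) {
  h <- nrow(x$p); w <- ncol(x$p)
  df <- data.frame(row = rep(seq_len(h), w), col = rep(seq_len(w), each = h),
                   t2 = as.numeric(x$t2), p = as.numeric(x$p),
                   category = as.character(x$category))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
plot.swe_summary_image <- function(x, ...) {
  img <- x$mean
  img[is.na(img)] <- 0
  plot_raster(img / 255, main = sprintf("Summary image (%s)", x$group), ...)
}

#' @export
plot.swe_t2map <- function(x, ...) {
  pal <- t2_palette()
  idx <- match(x$category, rownames(pal))
  h <- nrow(x$category); w <- ncol(x$category)
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- matrix(pal[idx, ch], h, w)
  plot_raster(img / 255, main = "Hotelling's T2 map", ...)
}

plot_raster <- function(img, main = "", ...) {
  graphics::plot.new()
  graphics::plot.window(c(0, ncol(img)), c(0, nrow(img)), asp = 1)
  graphics::rasterImage(img, 0, 0, ncol(img), nrow(img), interpolate = FALSE)
  graphics::title(main = main)
  invisible(NULL)
}
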