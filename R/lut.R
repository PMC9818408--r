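#' Build a shear-wave velocity colormap lookup table
#'
#' Constructs the lookup table (LUT) that maps shear-wave velocity in
#' \[`v_min`, `v_max`\] m/s to an RGB color, as rendered on the elastogram.
#' The table is a piecewise-linear traversal of `colors` over an even velocity
#' grid. The default blue-to-green-to-red ramp follows the field's convention
#' of blue = soft (slow shear waves) and red = stiff (fast shear waves); the
#' exact scanner palette differs between vendors, so the color sequence is
#' configurable and the LUT can be exported/imported as CSV
#' (see [write_lut()]).
#'
#' @param n_entries integer >= 2, number of LUT entries (velocity resolution).
#' @param colors character vector of at least two R colors traversed linearly.
#' @param v_min,v_max velocity range of the color scale in m/s.
#' @return An object of class `swe_lut`: list with `velocity` (length
#'   `n_entries`, strictly increasing from `v_min` to `v_max`) and `rgb`
#'   (`n_entries` x 3 integer matrix, 0-255).
#' @examples
#' lut <- swe_lut(256)
#' range(lut$velocity)   # 0.5 10
#' @export
swe_lut <- function(n_entries = 256L,
                    colors = c("blue", "green", "red"),
                    v_min = 0.5, v_max = 10) {
  if (n_entries < 2) stop("n_entries must be >= 2")
  if (v_max <= v_min) stop("v_max must exceed v_min")
  ramp <- grDevices::colorRamp(colors)
  rgb <- round(ramp(seq(0, 1, length.out = n_entries)))
  storage.mode(rgb) <- "integer"
  colnames(rgb) <- c("R", "G", "B")
  if (anyDuplicated(rgb)) {
    stop("configured color sequence yields duplicate RGB entries; ",
         "LUT would not be invertible")
  }
  structure(
    list(velocity = seq(v_min, v_max, length.out = n_entries),
         rgb = rgb, v_min = v_min, v_max = v_max),
    class = "swe_lut"
  )
}

#' @export
#' @method print swe_lut
print.swe_lut <- function(x, ...) {
  cat(sprintf("Shear-wave velocity colormap LUT: %d entries, %.2f-%.2f m/s (step %.4f m/s)\n",
              length(x$velocity), x$v_min, x$v_max, lut_step(x)))
  invisible(x)
}

#' Velocity step between consecutive LUT entries (m/s)
#' @param lut an [swe_lut()] object.
#' @export
lut_step <- function(lut) {
  (lut$v_max - lut$v_min) / (length(lut$velocity) - 1)
}

#' Write / read a colormap LUT as CSV
#'
#' CSV columns: `velocity`, `R`, `G`, `B`.
#'
#' @param lut an [swe_lut()] object.
#' @param path file path.
#' @return `read_lut()` returns an `swe_lut`; `write_lut()` returns `path`
#'   invisibly.
#' @export
write_lut <- function(lut, path) {
  df <- data.frame(velocity = lut$velocity, lut$rgb)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("velocity", "R", "G", "B") %in% names(df)))
  rgb <- as.matrix(df[, c("R", "G", "B")])
  storage.mode(rgb) <- "integer"
  if (is.unsorted(df$velocity, strictly = TRUE)) {
    stop("LUT velocities must be strictly increasing")
  }
  if (anyDuplicated(rgb)) stop("duplicate RGB entries; LUT not invertible")
  structure(
    list(velocity = df$velocity, rgb = rgb,
         v_min = df$velocity[1], v_max = df$velocity[length(df$velocity)]),
    class = "swe_lut"
  )
}

#' Render velocities as RGB through a LUT
#'
#' Each velocity is assigned the color of the nearest LUT entry (the forward
#' rendering used by the scanner display and by the synthetic generator).
#'
#' @param v numeric vector/matrix of velocities in m/s, inside the LUT range.
#' @param lut an [swe_lut()] object.
#' @return integer array of dim `c(dim(v), 3)` (or `length(v)` x 3 for a
#'   vector), values 0-255.
#' @export
velocity_to_rgb <- function(v, lut) {
  if (any(v < lut$v_min - 1e-9 | v > lut$v_max + 1e-9, na.rm = TRUE)) {
    stop(sprintf("velocity outside LUT range [%g, %g]", lut$v_min, lut$v_max))
  }
  idx <- nearest_lut_index(v, lut)
  out <- lut$rgb[idx, , drop = FALSE]
  if (!is.null(dim(v))) {
    out <- array(out, c(dim(v), 3L))
  }
  out
}

nearest_lut_index <- function(v, lut) {
  step <- lut_step(lut)
  idx <- as.integer(round((as.numeric(v) - lut$v_min) / step)) + 1L
  pmin(pmax(idx, 1L), length(lut$velocity))
}

#' Invert an elastogram's colors to shear-wave velocity
#'
#' Performs the inverse mapping from RGB color to stiffness: each pixel is
#' assigned the velocity of the LUT entry nearest in Euclidean RGB distance.
#' Pixels nearer to black than to any LUT color (untracked shear-wave areas
#' are rendered black by the scanner), or whose nearest LUT distance exceeds
#' `tol`, are marked invalid.
#'
#' @param img numeric/integer array H x W x 3, values 0-255.
#' @param lut an [swe_lut()] object.
#' @param tol rejection tolerance: maximal Euclidean RGB distance (0-255
#'   scale) to the nearest LUT color for a pixel to be considered on the
#'   colormap. Compression of real screenshots perturbs colors, hence a
#'   nonzero default.
#' @return An object of class `velocity_field`: list with matrices `velocity`
#'   (m/s, `NA` where invalid) and `valid` (logical), plus `v_min`, `v_max`.
#' @export
rgb_to_velocity <- function(img, lut, tol = 30) {
  d <- dim(img)
  if (is.null(d) || length(d) != 3L || d[3] != 3L || d[1] * d[2] == 0L) {
    stop("img must be a non-empty H x W x 3 array")
  }
  px <- round(matrix(as.numeric(img), d[1] * d[2], 3L))  # 0-255 integer grid
  L <- lut$rgb
  # elastograms carry few distinct colors: search only the unique ones
  code <- px %*% c(65536, 256, 1)
  ucode <- unique(as.numeric(code))
  u <- cbind(ucode %/% 65536, (ucode %/% 256) %% 256, ucode %% 256)
  # squared distances unique-color x entry via |p|^2 + |l|^2 - 2 p.l
  cross <- u %*% t(L)
  d2 <- matrix(rowSums(u^2), nrow(u), nrow(L)) +
    matrix(rowSums(L^2), nrow(u), nrow(L), byrow = TRUE) - 2 * cross
  ubest <- max.col(-d2, ties.method = "first")
  udmin <- sqrt(pmax(d2[cbind(seq_len(nrow(u)), ubest)], 0))
  udblack <- sqrt(rowSums(u^2))
  uvalid <- !(udblack < udmin) & udmin <= tol
  uvel <- ifelse(uvalid, lut$velocity[ubest], NA_real_)
  idx <- match(as.numeric(code), ucode)
  valid <- uvalid[idx]
  vel <- uvel[idx]
  structure(
    list(velocity = matrix(vel, d[1], d[2]),
         valid = matrix(valid, d[1], d[2]),
         v_min = lut$v_min, v_max = lut$v_max),
    class = "velocity_field"
  )
}

#' @export
#' @method print velocity_field
print.velocity_field <- function(x, ...) {
  cat(sprintf("velocity_field: %d x %d pixels, %d valid (%.1f%%), range [%0.2f, %0.2f] m/s\n",
              nrow(x$velocity), ncol(x$velocity), sum(x$valid),
              100 * mean(x$valid),
              suppressWarnings(min(x$velocity, na.rm = TRUE)),
              suppressWarnings(max(x$velocity, na.rm = TRUE))))
  invisible(x)
}

#' Classify shear-wave velocities into stiffness bands
#'
#' Three bands: low (0.5-3.67 m/s), medium (3.67-6.84 m/s) and high
#' (6.84-10 m/s). The printed band endpoints overlap, so a deterministic
#' boundary convention is required: intervals are half-open and
#' lower-inclusive — \[0.5, 3.67), \[3.67, 6.84), \[6.84, 10\] — with the high
#' band closed at the scale maximum. The boundaries are configurable.
#'
#' @param v numeric vector of velocities in m/s; must lie in
#'   \[`v_min`, `v_max`\].
#' @param boundaries two increasing interior cut points (m/s).
#' @param v_min,v_max velocity scale limits (m/s).
#' @return factor with levels `low`, `medium`, `high`.
#' @examples
#' classify_stiffness(c(2, 3.67, 10))  # low medium high
#' @export
classify_stiffness <- function(v, boundaries = c(3.67, 6.84),
                               v_min = 0.5, v_max = 10) {
  stopifnot(length(boundaries) == 2L, boundaries[1] < boundaries[2])
  if (any(v < v_min | v > v_max, na.rm = TRUE)) {
    stop(sprintf("velocity outside [%g, %g] m/s", v_min, v_max))
  }
  band <- ifelse(v < boundaries[1], "low",
                 ifelse(v < boundaries[2], "medium", "high"))
  factor(band, levels = c("low", "medium", "high"))
}

#' Count pixels per stiffness band
#'
#' Tallies the valid pixels of a velocity field over the three stiffness
#' bands (the `blue_pixels`, `green_pixels`, `red_pixels` features). Invalid
#' pixels are excluded, so the counts sum to the number of valid pixels.
#'
#' @param vf a `velocity_field` (from [rgb_to_velocity()]).
#' @param boundaries interior band cut points (m/s), see
#'   [classify_stiffness()].
#' @return named integer vector `c(low, medium, high)`.
#' @export
count_stiffness_pixels <- function(vf, boundaries = c(3.67, 6.84)) {
  stopifnot(inherits(vf, "velocity_field"))
  v <- vf$velocity[vf$valid]
  if (length(v) == 0L) {
    return(c(low = 0L, medium = 0L, high = 0L))
  }
  tab <- table(classify_stiffness(v, boundaries, vf$v_min, vf$v_max))
  out <- as.integer(tab[c("low", "medium", "high")])
  names(out) <- c("low", "medium", "high")
  out
}

#' Mask a velocity field by per-pixel quality
#'
#' Excludes pixels whose shear-wave tracking quality falls below `threshold`
#' (the scanner's quality map, rescaled to \[0, 1\]); the resulting validity
#' mask is the logical AND of the prior mask and `quality >= threshold`.
#'
#' @param vf a `velocity_field`.
#' @param quality numeric matrix, same dimensions as the field, values in
#'   \[0, 1\].
#' @param threshold quality cut-off; the conventional value is 0.5 (50%).
#' @return a `velocity_field` with the tightened validity mask.
#' @export
apply_quality_mask <- function(vf, quality, threshold = 0.5) {
  stopifnot(inherits(vf, "velocity_field"))
  if (!identical(dim(quality), dim(vf$velocity))) {
    stop("quality map dimensions do not match the velocity field")
  }
  if (any(quality < 0 | quality > 1, na.rm = TRUE)) {
    stop("quality values must lie in [0, 1]")
  }
  keep <- vf$valid & !is.na(quality) & quality >= threshold
  vf$velocity[!keep] <- NA_real_
  vf$valid <- keep
  vf
}
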