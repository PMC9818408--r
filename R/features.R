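#' Convert an RGB image to grayscale
#'
#' ITU-R BT.601 luma weighting: `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param rgb numeric/integer H x W x 3 array, 0-255.
#' @return numeric H x W matrix (not rounded).
#' @export
grayscale <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

#' Gabor filter parameters
#'
#' The Gabor kernel orientation set used for texture features is 45, 90, 135
#' and 180 degrees. A kernel at 180 degrees is identical to one at 0 degrees
#' (even cosine carrier), but 180 is retained as a distinct listed angle for
#' fidelity to the feature naming; the redundancy is intentional and
#' documented. Frequency and bandwidth follow common texture-analysis
#' defaults and are configurable; `sigma` is derived from the half-response
#' spatial-frequency bandwidth in octaves.
#'
#' @param frequency carrier frequency in cycles/pixel.
#' @param bandwidth spatial-frequency bandwidth in octaves.
#' @param gamma spatial aspect ratio of the Gaussian envelope.
#' @param angles orientations in degrees.
#' @param truncate kernel support radius in multiples of `sigma`.
#' @return list of class `gabor_params`.
#' @export
gabor_params <- function(frequency = 0.1, bandwidth = 1, gamma = 1,
                         angles = c(45, 90, 135, 180), truncate = 2.5) {
  stopifnot(frequency > 0, bandwidth > 0, length(angles) >= 1)
  structure(list(frequency = frequency, bandwidth = bandwidth, gamma = gamma,
                 angles = angles, truncate = truncate),
            class = "gabor_params")
}

#' Build a real Gabor kernel
#'
#' Even (cosine-carrier) Gabor kernel with isotropic-by-default Gaussian
#' envelope. `sigma = (1/(pi f)) sqrt(ln 2 / 2) (2^b + 1)/(2^b - 1)` relates
#' the envelope to a frequency bandwidth of `b` octaves.
#'
#' @param angle_deg orientation in degrees (0 = horizontal carrier axis).
#' @param params a [gabor_params()] object.
#' @return numeric square matrix (odd side length).
#' @export
gabor_kernel <- function(angle_deg, params = gabor_params()) {
  f <- params$frequency
  b <- params$bandwidth
  sigma <- (1 / (pi * f)) * sqrt(log(2) / 2) * (2^b + 1) / (2^b - 1)
  r <- ceiling(params$truncate * sigma)
  theta <- angle_deg * pi / 180
  x <- matrix(rep(-r:r, each = 2 * r + 1), 2 * r + 1)   # column offset
  y <- matrix(rep(-r:r, times = 2 * r + 1), 2 * r + 1)  # row offset
  xp <- x * cos(theta) + y * sin(theta)
  yp <- -x * sin(theta) + y * cos(theta)
  exp(-(xp^2 + params$gamma^2 * yp^2) / (2 * sigma^2)) * cos(2 * pi * f * xp)
}

# population variance (denominator N), consistent with the sd convention
pop_var <- function(x) {
  mean((x - mean(x))^2)
}

#' Gabor texture features of a grayscale region
#'
#' Convolves the region with one real Gabor kernel per configured angle
#' (reflect padding, so regions smaller than the kernel support are handled
#' by mirroring, never an error) and summarizes each response by its mean and
#' population variance.
#'
#' @param gray numeric matrix (grayscale region, non-empty).
#' @param params a [gabor_params()] object.
#' @return named numeric vector `gabor_kernel<i>_mean`, `gabor_kernel<i>_var`
#'   per angle, in angle order.
#' @export
gabor_features <- function(gray, params = gabor_params()) {
  stopifnot(is.matrix(gray), length(gray) > 0)
  out <- numeric(0)
  for (i in seq_along(params$angles)) {
    resp <- conv2_reflect(gray, gabor_kernel(params$angles[i], params))
    v <- c(mean(resp), pop_var(resp))
    names(v) <- sprintf("gabor_kernel%d_%s", i, c("mean", "var"))
    out <- c(out, v)
  }
  out
}

#' Split image rows into equal horizontal segments
#'
#' Returns `n_segments` contiguous, non-overlapping row bands covering all
#' rows. Band 1 is the topmost (most superficial tissue), band `n_segments`
#' the deepest (toward the spine). When the height is not divisible, the
#' first `height %% n_segments` bands receive one extra row (deterministic
#' remainder rule).
#'
#' @param n_rows image height in pixels (>= `n_segments`).
#' @param n_segments number of bands (default 10).
#' @return list of integer row-index vectors.
#' @export
segment_horizontal <- function(n_rows, n_segments = 10L) {
  if (n_rows < n_segments) stop("image height smaller than segment count")
  base <- n_rows %/% n_segments
  extra <- n_rows %% n_segments
  sizes <- rep(base, n_segments) + c(rep(1L, extra), rep(0L, n_segments - extra))
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-n_segments] + 1L)
  mapply(function(s, e) s:e, starts, ends, SIMPLIFY = FALSE)
}

region_feature_names <- function() {
  c("mean", "median", "sd",
    "red_layer_value_mean", "red_layer_value_median", "red_layer_value_sum",
    "blue_layer_value_mean", "blue_layer_value_median", "blue_layer_value_sum",
    "green_layer_value_mean", "green_layer_value_median",
    "green_layer_value_sum",
    "gray_value", "gray_value_mean", "gray_value_median",
    "gray_value_min", "gray_value_max",
    "blue_pixels", "green_pixels", "red_pixels",
    sprintf("gabor_kernel%d_%s", rep(1:4, each = 2), c("mean", "var")))
}

#' Handcrafted features of one image region
#'
#' Computes the 28 per-region features: grand mean/median/SD over all pixels
#' and channels; per-channel mean/median/sum for red, blue and green;
#' grayscale grand sum (`gray_value`), mean, median, min and max; the three
#' stiffness-band pixel counts (`blue_pixels` = low, `green_pixels` = medium,
#' `red_pixels` = high, from the LUT inversion); and mean/variance of the four
#' Gabor responses. Statistics are computed on the raw RGB values (black
#' pixels included); only the band counts are restricted to valid
#' color-mapped pixels. SD and variance use the population denominator.
#'
#' @param rgb numeric/integer H x W x 3 region, 0-255.
#' @param vf optional `velocity_field` for the same region (used for band
#'   counts); computed from `rgb` and `lut` when `NULL`.
#' @param lut an [swe_lut()]; required when `vf` is `NULL`.
#' @param gabor a [gabor_params()] object.
#' @param gray optional precomputed grayscale matrix for the region.
#' @return named numeric vector of length 28, in canonical order.
#' @export
region_features <- function(rgb, vf = NULL, lut = NULL,
                            gabor = gabor_params(), gray = NULL) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L, length(rgb) > 0)
  if (is.null(vf)) {
    if (is.null(lut)) stop("either vf or lut must be supplied")
    vf <- rgb_to_velocity(rgb, lut)
  }
  if (is.null(gray)) gray <- grayscale(rgb)
  px <- as.numeric(rgb)
  r <- as.numeric(rgb[, , 1]); g <- as.numeric(rgb[, , 2])
  b <- as.numeric(rgb[, , 3])
  bands <- count_stiffness_pixels(vf)
  out <- c(
    mean = mean(px), median = stats::median(px), sd = sqrt(pop_var(px)),
    red_layer_value_mean = mean(r), red_layer_value_median = stats::median(r),
    red_layer_value_sum = sum(r),
    blue_layer_value_mean = mean(b), blue_layer_value_median = stats::median(b),
    blue_layer_value_sum = sum(b),
    green_layer_value_mean = mean(g),
    green_layer_value_median = stats::median(g),
    green_layer_value_sum = sum(g),
    gray_value = sum(gray), gray_value_mean = mean(gray),
    gray_value_median = stats::median(gray),
    gray_value_min = min(gray), gray_value_max = max(gray),
    blue_pixels = bands[["low"]], green_pixels = bands[["medium"]],
    red_pixels = bands[["high"]]
  )
  c(out, gabor_features(gray, gabor))
}

#' Dummy-encode activity and session labels
#'
#' Reference-category encoding: the first level of each vocabulary is the
#' reference, yielding `length(activity_levels) - 1` activity indicators and
#' `length(session_levels) - 1` session indicators (13 + 2 under the default
#' 14-activity, 3-session protocol).
#'
#' @param activity,session single labels.
#' @param activity_levels,session_levels the fixed vocabularies (character,
#'   first entry = reference).
#' @return named numeric indicator vector (`activity_<label>`,
#'   `session_<label>`).
#' @export
encode_dummies <- function(activity, session,
                           activity_levels = default_activities()$activity,
                           session_levels = c("s1", "s2", "s3")) {
  if (!activity %in% activity_levels) {
    stop("unknown activity label: ", activity)
  }
  if (!session %in% session_levels) stop("unknown session label: ", session)
  a <- as.numeric(activity_levels[-1] == activity)
  s <- as.numeric(session_levels[-1] == session)
  names(a) <- paste0("activity_", activity_levels[-1])
  names(s) <- paste0("session_", session_levels[-1])
  c(a, s)
}

feature_column_names <- function(n_segments = 10L,
                                 activity_levels = default_activities()$activity,
                                 session_levels = c("s1", "s2", "s3")) {
  base <- region_feature_names()
  seg <- as.vector(vapply(seq_len(n_segments), function(n)
    sprintf("%s_hsegment_%d/%d", base, n, n_segments),
    character(length(base))))
  c(base, seg,
    paste0("activity_", activity_levels[-1]),
    paste0("session_", session_levels[-1]))
}

extract_image_features <- function(rgb, quality, lut, n_segments, gabor,
                                   quality_mask, quality_threshold) {
  vf <- rgb_to_velocity(rgb, lut)
  if (quality_mask && !is.null(quality)) {
    vf <- apply_quality_mask(vf, quality, quality_threshold)
  }
  gray <- grayscale(rgb)
  subset_vf <- function(rows) {
    structure(list(velocity = vf$velocity[rows, , drop = FALSE],
                   valid = vf$valid[rows, , drop = FALSE],
                   v_min = vf$v_min, v_max = vf$v_max),
              class = "velocity_field")
  }
  whole <- region_features(rgb, vf = vf, gabor = gabor, gray = gray)
  segs <- segment_horizontal(nrow(gray), n_segments)
  seg_feats <- lapply(seq_along(segs), function(i) {
    rows <- segs[[i]]
    f <- region_features(rgb[rows, , , drop = FALSE], vf = subset_vf(rows),
                         gabor = gabor, gray = gray[rows, , drop = FALSE])
    names(f) <- sprintf("%s_hsegment_%d/%d", names(f), i, n_segments)
    f
  })
  c(whole, unlist(seg_feats))
}

#' Build the full feature table for a dataset
#'
#' For every image in the manifest: invert the colors to velocity, compute
#' the 28 handcrafted features on the whole image and on each of the
#' `n_segments` horizontal segments (stiffness-band counts are derived once
#' from the whole-image inversion and tallied per segment), and append the
#' activity and session dummy variables — 28 + 28 x 10 + 13 + 2 = 323 feature
#' columns under the default protocol. Unreadable images are skipped with a
#' warning and recorded in the `skipped` attribute.
#'
#' @param x an `swe_dataset`, a manifest `data.frame`, or the path to a
#'   manifest CSV (columns `path`, `quality_path`, `participant`, `group`,
#'   `activity`, `session`).
#' @param lut an [swe_lut()]; for an `swe_dataset` the dataset's own LUT is
#'   the default.
#' @param n_segments number of horizontal segments (default 10).
#' @param gabor a [gabor_params()] object.
#' @param quality_mask logical: also exclude low-quality pixels from the
#'   stiffness-band counts (by default quality masking is reserved for the
#'   summary maps).
#' @param quality_threshold quality cut-off used when `quality_mask = TRUE`.
#' @param activity_levels,session_levels dummy-coding vocabularies; defaults
#'   are taken from the dataset config when available, otherwise from the
#'   manifest in order of first appearance.
#' @return object of class `swe_features`: a `data.frame` (names not
#'   syntactically mangled) with the feature columns plus `label` (group) and
#'   `participant`; attributes `feature_cols` (character vector of the 323
#'   feature names) and `skipped` (paths of unreadable images).
#' @export
build_feature_table <- function(x, lut = NULL, n_segments = 10L,
                                gabor = gabor_params(),
                                quality_mask = FALSE, quality_threshold = 0.5,
                                activity_levels = NULL,
                                session_levels = NULL) {
  if (inherits(x, "swe_dataset")) {
    manifest <- x$manifest
    if (is.null(lut)) lut <- x$lut
    if (is.null(activity_levels)) {
      activity_levels <- x$config$activities$activity
    }
  } else if (is.character(x)) {
    manifest <- utils::read.csv(x, stringsAsFactors = FALSE)
  } else {
    manifest <- x
  }
  if (is.null(lut)) lut <- swe_lut()
  stopifnot(all(c("path", "participant", "group", "activity", "session")
                %in% names(manifest)))
  if (is.null(activity_levels)) activity_levels <- unique(manifest$activity)
  if (is.null(session_levels)) {
    session_levels <- unique(sort(unique(manifest$session)))
    if (length(session_levels) < 3L) session_levels <- c("s1", "s2", "s3")
  }
  cols <- feature_column_names(n_segments, activity_levels, session_levels)
  rows <- vector("list", nrow(manifest))
  skipped <- character(0)
  for (i in seq_len(nrow(manifest))) {
    feats <- tryCatch({
      rgb <- read_elastogram(manifest$path[i])
      quality <- if (quality_mask && "quality_path" %in% names(manifest) &&
                     nzchar(manifest$quality_path[i])) {
        read_quality_map(manifest$quality_path[i])
      }
      img <- extract_image_features(rgb, quality, lut, n_segments, gabor,
                                    quality_mask, quality_threshold)
      dums <- encode_dummies(manifest$activity[i], manifest$session[i],
                             activity_levels, session_levels)
      c(img, dums)
    }, error = function(e) {
      warning(sprintf("skipping image %s: %s", manifest$path[i],
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(feats)) {
      skipped <- c(skipped, manifest$path[i])
    } else {
      rows[[i]] <- feats
    }
  }
  keep <- !vapply(rows, is.null, logical(1))
  mat <- do.call(rbind, rows[keep])
  stopifnot(identical(colnames(mat), cols))
  ft <- as.data.frame(mat, check.names = FALSE)
  ft$label <- manifest$group[keep]
  ft$participant <- manifest$participant[keep]
  attr(ft, "feature_cols") <- cols
  attr(ft, "skipped") <- skipped
  class(ft) <- c("swe_features", "data.frame")
  ft
}

#' Feature column names of a feature table
#' @param ft an `swe_features` table.
#' @return character vector (323 names under the default protocol).
#' @export
feature_cols <- function(ft) {
  attr(ft, "feature_cols")
}

#' @export
#' @method print swe_features
print.swe_features <- function(x, ...) {
  cat(sprintf("SWE feature table: %d images x %d feature columns (+ label, participant)\n",
              nrow(x), length(feature_cols(x))))
  if (length(attr(x, "skipped"))) {
    cat(sprintf("  %d images skipped as unreadable\n",
                length(attr(x, "skipped"))))
  }
  invisible(x)
}

#' Write / read a feature table as CSV
#'
#' Column names (including the `"<feature>_hsegment_<n>/10"` pattern) are
#' preserved verbatim.
#'
#' @param ft an `swe_features` table.
#' @param path CSV path.
#' @export
write_feature_table <- function(ft, path) {
  utils::write.csv(as.data.frame(ft, check.names = FALSE), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  attr(df, "feature_cols") <- setdiff(names(df), c("label", "participant"))
  class(df) <- c("swe_features", "data.frame")
  df
}
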