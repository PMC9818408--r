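#' Default activity vocabulary with per-activity force levels
#'
#' Fourteen imaging activities with a relative isometric force scalar in
#' \[0, 1\] (1 = maximal graded neck extension). The graded-extension tasks
#' (12/24/36/48 N) scale linearly with force; resting tasks carry zero force.
#' Labels other than the graded-extension and resting/office/balance tasks are
#' generic stand-ins for the remaining protocol items.
#'
#' @return data.frame with columns `activity` (character) and `force`
#'   (numeric, 0-1). Row order defines the dummy-coding reference (first row).
#' @export
default_activities <- function() {
  data.frame(
    activity = c("resting_prone", "resting_sitting", "office_work", "reading",
                 "head_turn", "shoulder_lift", "balance_weight",
                 "precision_target", "head_lift_prone", "ext_12N", "ext_24N",
                 "ext_36N", "ext_48N", "mvic"),
    force = c(0, 0, 0.10, 0.10,
              0.20, 0.25, 0.30,
              0.40, 0.50, 0.25, 0.50,
              0.75, 1.00, 1.00),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic elastogram study
#'
#' Defines a two-group (chronic-pain vs asymptomatic control) repeated-measures
#' elastography study: each participant is imaged during 14 activities in up to
#' 3 sessions. Per-pixel shear-wave velocity is a base level plus a
#' participant-level random intercept, plus — in the pain group only — a
#' depth-profile offset scaled by the activity's force level, plus spatially
#' correlated Gaussian noise, clipped to the 0.5-10 m/s scale.
#'
#' The group effect is expressed as a per-depth-decile offset
#' (`effect_depth_profile`, 10 values in m/s, decile 1 = most superficial
#' rows, decile 10 = deepest rows near the spine); the default concentrates
#' the effect in the two deepest deciles, emulating stiffness differences that
#' originate in the deep neck extensors. No quantitative effect size in m/s is
#' established for this contrast, so the default (1 m/s at full force) is a
#' plausible placeholder intended for parameter-recovery testing, not an
#' estimate.
#'
#' @param n_pain,n_control participants per group (>= 2).
#' @param image_height,image_width image size in pixels. The default 256 x 192
#'   keeps simulations desk-scale; the native 1024 x 768 is supported.
#' @param activities data.frame with columns `activity`, `force` (14 rows by
#'   default, see [default_activities()]).
#' @param sessions number of imaging sessions (default 3).
#' @param base_velocity baseline shear-wave velocity (m/s).
#' @param effect_depth_profile numeric length 10: additive pain-group offset
#'   (m/s, at force 1) per horizontal decile, decile 1 superficial.
#' @param effect_force_coupling scalar multiplying `force x depth offset`.
#' @param noise_sd marginal SD of the pixel noise (m/s).
#' @param spatial_correlation_length Gaussian correlation length of the noise
#'   in pixels (0 = independent pixels). Elastograms show smooth stiffness
#'   patches, so the default is positive.
#' @param participant_sd SD (m/s) of the participant-level random intercept;
#'   images from one participant are correlated through it.
#' @param dropout_fraction expected fraction of pixels rendered black
#'   (untracked shear waves).
#' @param quality_noise_sd SD of the noise added to the synthetic quality map.
#' @param seed integer RNG seed; all simulation randomness flows from it.
#' @return object of class `swe_sim_config` (a validated list).
#' @export
sim_config <- function(n_pain = 20L, n_control = 18L,
                       image_height = 192L, image_width = 256L,
                       activities = default_activities(),
                       sessions = 3L,
                       base_velocity = 2.5,
                       effect_depth_profile = c(rep(0, 8), 1, 1),
                       effect_force_coupling = 1,
                       noise_sd = 0.5,
                       spatial_correlation_length = 8,
                       participant_sd = 0.3,
                       dropout_fraction = 0.1,
                       quality_noise_sd = 0.1,
                       seed = 1L) {
  cfg <- list(n_pain = as.integer(n_pain), n_control = as.integer(n_control),
              image_height = as.integer(image_height),
              image_width = as.integer(image_width),
              activities = activities, sessions = as.integer(sessions),
              base_velocity = base_velocity,
              effect_depth_profile = effect_depth_profile,
              effect_force_coupling = effect_force_coupling,
              noise_sd = noise_sd,
              spatial_correlation_length = spatial_correlation_length,
              participant_sd = participant_sd,
              dropout_fraction = dropout_fraction,
              quality_noise_sd = quality_noise_sd,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "swe_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_pain < 2L || cfg$n_control < 2L) {
    stop("need at least 2 participants per group", call. = FALSE)
  }
  if (cfg$image_height <= 0L || cfg$image_width <= 0L) {
    stop("image dimensions must be positive", call. = FALSE)
  }
  if (length(cfg$effect_depth_profile) != 10L) {
    stop("effect_depth_profile must have exactly 10 entries", call. = FALSE)
  }
  stopifnot(is.data.frame(cfg$activities),
            all(c("activity", "force") %in% names(cfg$activities)))
  if (any(cfg$activities$force < 0 | cfg$activities$force > 1)) {
    stop("activity force levels must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(cfg$activities$activity)) {
    stop("duplicate activity labels", call. = FALSE)
  }
  if (cfg$sessions < 1L) stop("sessions must be >= 1", call. = FALSE)
  if (cfg$dropout_fraction < 0 || cfg$dropout_fraction > 1) {
    stop("dropout_fraction must lie in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
#' @method print swe_sim_config
print.swe_sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic SWE study config: %d pain + %d control participants,\n",
    "  %d activities x %d session(s), images %d x %d px,\n",
    "  base %.2f m/s, deep-decile effect %s m/s, noise sd %.2f m/s, seed %d\n"),
    x$n_pain, x$n_control, nrow(x$activities), x$sessions,
    x$image_height, x$image_width, x$base_velocity,
    paste(unique(x$effect_depth_profile[9:10]), collapse = "/"),
    x$noise_sd, x$seed))
  invisible(x)
}

gaussian_blur_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- stats::dnorm(-r:r, sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

# spatially correlated Gaussian field with marginal SD `sd`
correlated_noise <- function(h, w, sd, corr_len) {
  z <- matrix(stats::rnorm(h * w), h, w)
  if (sd == 0) return(matrix(0, h, w))
  if (corr_len > 0) {
    k <- gaussian_blur_kernel(corr_len / 2)
    z <- conv2_reflect(z, k)
    z <- z / sqrt(sum(k^2))   # restore unit marginal variance
  }
  sd * z
}

#' Simulate one per-pixel shear-wave velocity field
#'
#' Builds `base_velocity + participant offset + group effect + noise`, where
#' the group effect applies only to the pain group: each horizontal decile of
#' rows receives `effect_depth_profile[decile] * activity_force *
#' effect_force_coupling` m/s. The field is clipped to the 0.5-10 m/s
#' elastogram scale. Randomness is drawn from the current RNG state; seed via
#' `set.seed()` (or use [simulate_dataset()], which seeds from the config).
#'
#' @param config an [sim_config()] object.
#' @param group `"pain"` or `"control"`.
#' @param activity_force force scalar in \[0, 1\].
#' @param participant_offset participant-level intercept (m/s), default 0.
#' @return numeric `image_height` x `image_width` matrix of velocities (m/s).
#' @export
simulate_velocity_field <- function(config, group, activity_force,
                                    participant_offset = 0) {
  validate_sim_config(config)
  group <- match.arg(group, c("pain", "control"))
  h <- config$image_height; w <- config$image_width
  v <- matrix(config$base_velocity + participant_offset, h, w)
  if (group == "pain") {
    offs <- config$effect_depth_profile *
      activity_force * config$effect_force_coupling
    segs <- segment_horizontal(h, 10L)
    for (d in seq_along(segs)) v[segs[[d]], ] <- v[segs[[d]], ] + offs[d]
  }
  v <- v + correlated_noise(h, w, config$noise_sd,
                            config$spatial_correlation_length)
  pmin(pmax(v, 0.5), 10)
}

#' Render a velocity field as a synthetic elastogram
#'
#' Colors each pixel through the LUT, blacks out a random subset of pixels
#' (emulating untracked shear-wave areas), and produces a matching quality
#' map: the smoothed complement of the dropout indicator plus noise, so that
#' dropped pixels fall below the conventional 50% quality threshold and their
#' neighborhoods carry reduced quality.
#'
#' @param velocity numeric matrix of velocities within the LUT range.
#' @param lut an [swe_lut()] object.
#' @param dropout_fraction per-pixel dropout probability (independent
#'   Bernoulli).
#' @param quality_noise_sd SD of the quality-map noise.
#' @return object of class `elastogram`: list with `rgb` (H x W x 3 integer,
#'   0-255) and `quality` (H x W in \[0, 1\]).
#' @export
render_elastogram <- function(velocity, lut, dropout_fraction = 0,
                              quality_noise_sd = 0.1) {
  if (any(velocity < lut$v_min | velocity > lut$v_max)) {
    stop(sprintf("velocity outside LUT range [%g, %g] m/s",
                 lut$v_min, lut$v_max))
  }
  h <- nrow(velocity); w <- ncol(velocity)
  rgb <- velocity_to_rgb(velocity, lut)
  drop <- matrix(stats::runif(h * w) < dropout_fraction, h, w)
  if (any(drop)) {
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[drop] <- 0L
      rgb[, , ch] <- plane
    }
  }
  q <- 1 - drop
  k <- gaussian_blur_kernel(1.5)
  q <- conv2_reflect(q + 0, k)
  q <- q + stats::rnorm(h * w, sd = quality_noise_sd)
  q <- pmin(pmax(q, 0), 1)
  q[drop] <- 0.45 * q[drop]   # dropped pixels always fail the 50% threshold
  structure(list(rgb = rgb, quality = q), class = "elastogram")
}

#' Simulate a complete synthetic elastogram dataset
#'
#' Generates `(n_pain + n_control) x activities x sessions` elastograms with
#' participant-level random intercepts (images of one participant are
#' correlated), renders them through the LUT, writes images and quality maps
#' as lossless PNG under `dir`, and returns the dataset manifest. Fully
#' deterministic given `config$seed`.
#'
#' @param config an [sim_config()] object.
#' @param dir output directory for PNGs (created if needed); default a fresh
#'   temporary directory.
#' @param lut LUT used for rendering; default [swe_lut()] with 256 entries.
#' @return object of class `swe_dataset`: list with `manifest` (data.frame:
#'   `path`, `quality_path`, `participant`, `group`, `activity`, `session`,
#'   `force`), `config`, `lut`, `dir`.
#' @examples
#' cfg <- sim_config(n_pain = 2, n_control = 2, image_height = 40,
#'                   image_width = 30, sessions = 1, seed = 7)
#' ds <- simulate_dataset(cfg)
#' nrow(ds$manifest)  # 4 participants x 14 activities
#' @export
simulate_dataset <- function(config, dir = tempfile("swe_dataset_"),
                             lut = swe_lut()) {
  validate_sim_config(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  participants <- data.frame(
    participant = c(sprintf("P%02d", seq_len(config$n_pain)),
                    sprintf("C%02d", seq_len(config$n_control))),
    group = rep(c("pain", "control"), c(config$n_pain, config$n_control)),
    stringsAsFactors = FALSE
  )
  participants$offset <- stats::rnorm(nrow(participants),
                                      sd = config$participant_sd)
  rows <- vector("list", nrow(participants) * nrow(config$activities) *
                   config$sessions)
  i <- 0L
  for (p in seq_len(nrow(participants))) {
    for (s in seq_len(config$sessions)) {
      for (a in seq_len(nrow(config$activities))) {
        i <- i + 1L
        act <- config$activities$activity[a]
        v <- simulate_velocity_field(config, participants$group[p],
                                     config$activities$force[a],
                                     participants$offset[p])
        el <- render_elastogram(v, lut, config$dropout_fraction,
                                config$quality_noise_sd)
        stem <- sprintf("%s_s%d_%s", participants$participant[p], s, act)
        img_path <- file.path(dir, paste0(stem, ".png"))
        q_path <- file.path(dir, paste0(stem, "_quality.png"))
        write_elastogram(el, img_path, q_path)
        rows[[i]] <- data.frame(
          path = img_path, quality_path = q_path,
          participant = participants$participant[p],
          group = participants$group[p],
          activity = act, session = paste0("s", s),
          force = config$activities$force[a],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  structure(list(manifest = manifest, config = config, lut = lut, dir = dir),
            class = "swe_dataset")
}

write_elastogram <- function(el, img_path, quality_path) {
  png::writePNG(el$rgb / 255, img_path)
  png::writePNG(el$quality, quality_path)
  invisible(img_path)
}

#' Read an elastogram image (PNG, or uncompressed 24-bit BMP as exported by
#' the scanner) as a 0-255 RGB array
#'
#' @param path image file path.
#' @return integer H x W x 3 array, 0-255.
#' @export
read_elastogram <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  if (grepl("\\.bmp$", path, ignore.case = TRUE)) return(read_bmp(path))
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3L))
  a <- a[, , 1:3, drop = FALSE]
  r <- round(a * 255)
  storage.mode(r) <- "integer"
  r
}

#' Read a quality map PNG as a matrix in \[0, 1\]
#' @param path image file path.
#' @return numeric matrix.
#' @export
read_quality_map <- function(path) {
  if (!file.exists(path)) stop("cannot read quality map: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  a
}

#' @export
#' @method print swe_dataset
print.swe_dataset <- function(x, ...) {
  cat(sprintf("Synthetic SWE dataset: %d elastograms (%d pain / %d control images)\n",
              nrow(x$manifest), sum(x$manifest$group == "pain"),
              sum(x$manifest$group == "control")))
  cat(sprintf("  %d participants, %d activities, %d session(s); images in %s\n",
              length(unique(x$manifest$participant)),
              length(unique(x$manifest$activity)),
              length(unique(x$manifest$session)), x$dir))
  invisible(x)
}
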