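# Shared fixtures: all synthetic, generated in code at test time.

tiny_config <- function(...) {
  defaults <- list(n_pain = 3L, n_control = 3L, image_height = 60L,
                   image_width = 40L, sessions = 1L,
                   effect_depth_profile = c(rep(0, 8), 2, 2),
                   noise_sd = 0.3, dropout_fraction = 0.05, seed = 101L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# fast Gabor settings for unit tests (small kernel support)
fast_gabor <- gabor_params(frequency = 0.25, truncate = 2)

# naive 2-D convolution with mirror padding: independent oracle for the
# compiled path
conv2_naive <- function(x, k) {
  h <- nrow(x); w <- ncol(x)
  a <- nrow(k) %/% 2; b <- ncol(k) %/% 2
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      acc <- 0
      for (di in -a:a) {
        for (dj in -b:b) {
          # true convolution: kernel indices flipped
          acc <- acc + k[a + 1 - di, b + 1 - dj] *
            x[refl(i + di, h), refl(j + dj, w)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# study-condition dataset used by the parameter-recovery checks: two groups
# of 20 + 18 participants, 14 activities, one session, deep-decile effect
recovery_config <- function(effect = 1.5, seed = 404L) {
  sim_config(n_pain = 20L, n_control = 18L, sessions = 1L,
             effect_depth_profile = c(rep(0, 8), effect, effect),
             noise_sd = 0.5, seed = seed)
}

# heavyweight artefacts shared between acceptance checks, built once per run
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_fixture <- function(name, builder) {
  if (!exists(name, envir = .acceptance_cache)) {
    assign(name, builder(), envir = .acceptance_cache)
  }
  get(name, envir = .acceptance_cache)
}

effect_features <- function() {
  acceptance_fixture("effect", function() {
    ds <- simulate_dataset(recovery_config(effect = 1.5, seed = 404L))
    list(ds = ds, ft = build_feature_table(ds))
  })
}

null_features <- function() {
  acceptance_fixture("null", function() {
    ds <- simulate_dataset(recovery_config(effect = 0, seed = 405L))
    list(ds = ds, ft = build_feature_table(ds))
  })
}
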