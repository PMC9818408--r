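swe_error <- function(type, msg) {
  stop(structure(class = c(type, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(structure(class = c("swe_stage_error", class(e)),
                   list(message = sprintf("[stage %s] %s", stage,
                                          conditionMessage(e)),
                        call = conditionCall(e), stage = stage)))
  })
}

#' Read a pipeline configuration file (YAML or JSON)
#'
#' @param path configuration file; `.json` is parsed with jsonlite,
#'   everything else with yaml.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) swe_error("swe_config_error",
                                    paste("config file not found:", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

write_provenance <- function(path, config, seed) {
  prov <- list(seed = seed,
               package = "swequant",
               package_version = as.character(utils::packageVersion("swequant")),
               r_version = R.version.string,
               timestamp = format(Sys.time(), tz = "UTC"),
               config = config)
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}

#' Table-style benchmark summary
#'
#' Reshapes a [summary.swe_cv()] result into the conventional benchmark
#' table: one row per metric, one column per algorithm, cells
#' `"mean (ci_low-ci_high)"`.
#'
#' @param cv an `swe_cv` object.
#' @param digits significant digits.
#' @return data.frame.
#' @export
benchmark_table <- function(cv, digits = 3) {
  s <- summary(cv)
  metrics <- unique(s$metric)
  algs <- unique(s$algorithm)
  out <- data.frame(metric = metrics, stringsAsFactors = FALSE)
  for (a in algs) {
    cells <- vapply(metrics, function(m) {
      r <- s[s$algorithm == a & s$metric == m, ]
      sprintf("%.*f (%.*f-%.*f)", digits, r$mean, digits, r$ci_low,
              digits, r$ci_high)
    }, character(1))
    out[[a]] <- cells
  }
  out
}

#' Run the full elastogram analysis pipeline
#'
#' Executes (optionally) simulate, then featurize, classify and map stages,
#' writing flat CSV/PNG/JSON artifacts plus a provenance sidecar (seed,
#' package version, config echo) and a log of image counts read and skipped.
#' Any stage failure aborts with a stage-labeled error; artifacts written by
#' completed stages are retained.
#'
#' @param config a named list or the path to a YAML/JSON config file.
#'   Recognized entries: `seed` (mandatory), `output_dir`, `simulate` (list
#'   of [sim_config()] arguments; omit to analyze an existing dataset),
#'   `manifest` (manifest CSV path when not simulating), `lut` (LUT CSV
#'   path; default built-in ramp), `n_segments`, `quality_threshold`,
#'   `gabor` (list of [gabor_params()] arguments), `cv` (list of
#'   [nested_cv()] arguments), `maps` (list: `category_column` to facet map
#'   stacks, `min_n`).
#' @return invisibly, a list with the feature table, the `swe_cv` object,
#'   the importance ranking, the map objects and the output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(config$seed)) {
    swe_error("swe_config_error", "config must provide a seed")
  }
  seed <- as.integer(config$seed)
  out_dir <- config$output_dir %||% tempfile("swe_pipeline_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log_add <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  lut <- if (!is.null(config$lut)) {
    with_stage("config", read_lut(config$lut))
  } else {
    swe_lut()
  }

  if (!is.null(config$simulate)) {
    ds <- with_stage("simulate", {
      args <- config$simulate
      args$seed <- seed
      if (!is.null(args$activities) && !is.data.frame(args$activities)) {
        args$activities <- as.data.frame(args$activities)
      }
      simulate_dataset(do.call(sim_config, args),
                       dir = file.path(out_dir, "images"), lut = lut)
    })
    manifest <- ds$manifest
    log_add("simulate: %d elastograms written to %s", nrow(manifest), ds$dir)
  } else {
    if (is.null(config$manifest)) {
      swe_error("swe_config_error", "config needs either simulate: or manifest:")
    }
    manifest <- with_stage("io", utils::read.csv(config$manifest,
                                                 stringsAsFactors = FALSE))
    log_add("io: manifest with %d images read from %s", nrow(manifest),
            config$manifest)
  }

  ft <- with_stage("featurize", {
    gb <- do.call(gabor_params, config$gabor %||% list())
    build_feature_table(manifest, lut = lut,
                        n_segments = config$n_segments %||% 10L,
                        gabor = gb,
                        quality_mask = isTRUE(config$quality_mask),
                        quality_threshold = config$quality_threshold %||% 0.5)
  })
  log_add("featurize: %d images featurized (%d skipped), %d feature columns",
          nrow(ft), length(attr(ft, "skipped")), length(feature_cols(ft)))
  write_feature_table(ft, file.path(out_dir, "features.csv"))
  write_provenance(file.path(out_dir, "features_provenance.json"),
                   config, seed)

  cv_args <- config$cv %||% list()
  cv_args$ft <- ft
  cv_args$seed <- seed
  cv <- with_stage("classify", do.call(nested_cv, cv_args))
  utils::write.csv(cv$records, file.path(out_dir, "cv_records.csv"),
                   row.names = FALSE)
  utils::write.csv(benchmark_table(cv), file.path(out_dir, "cv_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(cv$selected, file.path(out_dir, "cv_selected_params.csv"),
                   row.names = FALSE)
  imp <- with_stage("classify", {
    rank_importances(fit_rf_importance(ft, seed = seed),
                     feature_names = feature_cols(ft), top_k = 20L)
  })
  utils::write.csv(as.data.frame(imp), file.path(out_dir, "importances.csv"),
                   row.names = FALSE)
  log_add("classify: %d validation records (%s)", nrow(cv$records),
          paste(cv$algorithms, collapse = ", "))

  maps <- with_stage("maps", {
    skipped <- attr(ft, "skipped")
    if (length(skipped)) manifest <- manifest[!manifest$path %in% skipped, ]
    groups <- unique(manifest$group)
    stopifnot(length(groups) == 2L)
    threshold <- config$quality_threshold %||% 0.5
    min_n <- (config$maps %||% list())$min_n %||% 5L
    sa <- load_stack(manifest[manifest$group == groups[1], ])
    sb <- load_stack(manifest[manifest$group == groups[2], ])
    si_a <- summary_image(sa$rgb, sa$quality, threshold, group = groups[1])
    si_b <- summary_image(sb$rgb, sb$quality, threshold, group = groups[2])
    tm <- t2_map(sa$rgb, sb$rgb, sa$quality, sb$quality, threshold,
                 min_n = min_n)
    render_map(si_a, file.path(out_dir,
                               sprintf("summary_%s.png", groups[1])))
    render_map(si_b, file.path(out_dir,
                               sprintf("summary_%s.png", groups[2])))
    render_map(tm, file.path(out_dir, "t2_map.png"))
    write_t2_csv(tm, file.path(out_dir, "t2_map.csv"))
    list(summary = list(si_a, si_b), t2 = tm)
  })
  log_add("maps: summary images and T2 map written (%d significant pixels)",
          sum(maps$t2$category %in% c("p<0.05", "p<0.01")))

  writeLines(log_lines, file.path(out_dir, "pipeline_log.txt"))
  write_provenance(file.path(out_dir, "provenance.json"), config, seed)
  invisible(list(features = ft, cv = cv, importances = imp, maps = maps,
                 output_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
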