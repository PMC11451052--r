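#' Default pipeline configuration
#'
#' A complete, explicit configuration for the stock simulated experiment: the
#' default Golgi model, one imaging round per target, alignment enabled, and
#' the standard proximity settings (500 nm cutoff, directed medians). All
#' defaults are spelled out in the returned list — and in the YAML written by
#' [write_pipeline_config()] — so a run never depends on silent defaults.
#'
#' @param seed integer seed for the simulation.
#' @param output_dir where [run_pipeline()] writes its exports.
#' @return a named list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L, output_dir = "proximap-out") {
  model <- default_golgi_model(seed = seed)
  geom <- model$geometry
  list(
    mode = "simulate",
    seed = as.integer(seed),
    output_dir = output_dir,
    simulate = list(
      model = list(
        geometry = list(
          ribbon_length = geom$ribbon_length,
          ribbon_width = geom$ribbon_width,
          curvature = geom$curvature,
          stack_axis = geom$stack_axis,
          field_of_view = geom$field_of_view,
          segments = geom$segments,
          face_extent = geom$face_extent),
        layouts = lapply(model$layouts, function(l) {
          Filter(Negate(is.null),
                 l[c("target_id", "kind", "axial_offset", "site_density",
                     "puncta_count", "puncta_radius", "between", "thickness")])
        })),
      acquisition = list(
        round_order = names(model$layouts),
        mean_blinks_per_site = 5,
        blink_count_law = "poisson",
        sigma_loc = 5,
        linkage_radius = 10,
        false_rate = 25,
        erasure_efficiency = 0.995,
        round_shifts = NULL,
        pixel_size = 108,
        n_frames = 30000,
        mean_event_frames = 3)),
    alignment = list(enabled = TRUE, reference = NULL, bin_size = 10,
                     max_shift = 500),
    proximity = list(cutoff = 500, symmetrize = FALSE, min_pair_count = 50),
    precision = list(fit_range = 100)
  )
}

#' Read / write pipeline configurations
#'
#' Configurations are single YAML files; [read_pipeline_config()] validates on
#' read and reports every violation at once.
#'
#' @param path YAML file.
#' @param config configuration list.
#' @return the configuration list (read) or `path` invisibly (write).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

validate_pipeline_config <- function(cfg) {
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)
  mode <- cfg$mode %||% NA
  if (!isTRUE(mode %in% c("simulate", "real"))) {
    note("mode must be 'simulate' or 'real'")
  }
  if (isTRUE(mode == "simulate")) {
    if (is.null(cfg$seed)) note("seed is required when mode = simulate")
    if (is.null(cfg$simulate)) note("simulate section missing")
    if (!is.null(cfg$real)) note("exactly one input source allowed: drop the 'real' section")
  }
  if (isTRUE(mode == "real")) {
    if (is.null(cfg$real$channels) || !length(cfg$real$channels)) {
      note("real section must list input channels")
    }
    if (!is.null(cfg$simulate)) note("exactly one input source allowed: drop the 'simulate' section")
    unit <- cfg$real$unit %||% "nm"
    if (identical(unit, "pixel") && is.null(cfg$real$pixel_size)) {
      note("pixel_size is required when unit = pixel")
    }
  }
  if (is.null(cfg$output_dir)) note("output_dir missing")
  al <- cfg$alignment
  if (!is.null(al$bin_size) && !(is.numeric(al$bin_size) && al$bin_size > 0)) {
    note("alignment bin_size must be positive")
  }
  px <- cfg$proximity
  if (!is.null(px$cutoff) && !(is.numeric(px$cutoff) && px$cutoff > 0)) {
    note("proximity cutoff must be positive")
  }
  if (!is.null(px$min_pair_count) &&
      !(is.numeric(px$min_pair_count) && px$min_pair_count >= 1)) {
    note("proximity min_pair_count must be at least 1")
  }
  if (length(problems)) {
    abort_config(paste0("invalid pipeline configuration:\n  - ",
                        paste(problems, collapse = "\n  - ")))
  }
  invisible(cfg)
}

config_model <- function(cfg) {
  m <- cfg$simulate$model
  geom <- do.call(golgi_geometry, lapply(m$geometry, unlist))
  layouts <- lapply(m$layouts, function(l) {
    l$between <- unlist(l$between)
    do.call(target_layout, l)
  })
  golgi_model(geom, layouts, seed = cfg$seed)
}

config_acquisition <- function(cfg) {
  a <- cfg$simulate$acquisition
  a$round_order <- unlist(a$round_order)
  if (!is.null(a$round_shifts)) {
    a$round_shifts <- matrix(unlist(a$round_shifts), ncol = 2, byrow = TRUE)
  } else {
    a$round_shifts <- NULL
  }
  do.call(acquisition_config, Filter(Negate(is.null), a))
}

load_real_dataset <- function(cfg) {
  rl <- cfg$real
  unit <- rl$unit %||% "nm"
  tables <- lapply(rl$channels, function(ch) {
    read_localizations(ch$path, dialect = ch$dialect %||% "csv",
                       unit = unit, pixel_size = rl$pixel_size %||% 108,
                       channel = ch$target_id,
                       col_map = unlist(rl$col_map))
  })
  names(tables) <- vapply(rl$channels, `[[`, character(1), "target_id")
  tables
}

#' Run the full proximity pipeline
#'
#' Executes the complete workflow from one configuration: simulate (or ingest)
#' the per-round localization tables, optionally align the rounds, compute the
#' median NN-distance matrix, and write every export — per-channel tables,
#' registration report, median matrix, heatmap, long-format pair distances,
#' precision table, and a run manifest. The manifest is written whether the
#' run succeeds or fails.
#'
#' @param config a configuration list (see [default_pipeline_config()]) or the
#'   path to a YAML file.
#' @param output_dir overrides the config's output directory.
#' @param seed overrides the config's seed.
#' @param verbose print one line per stage.
#' @return the run manifest, invisibly (class `run_manifest`).
#' @examples
#' \donttest{
#' cfg <- default_pipeline_config(seed = 7, output_dir = tempfile())
#' man <- run_pipeline(cfg)
#' man$outputs
#' }
#' @export
run_pipeline <- function(config, output_dir = NULL, seed = NULL,
                         verbose = FALSE) {
  t0 <- Sys.time()
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(output_dir)) config$output_dir <- output_dir
  validate_pipeline_config(config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  manifest <- list(
    package = "proximap",
    version = as.character(utils::packageVersion("proximap")),
    seed = config$seed,
    config = config,
    stage_counts = list(),
    outputs = character(0),
    failed_stage = NULL)
  stage <- "setup"
  record <- function(file) manifest$outputs <<- c(manifest$outputs, file)
  finish <- function() {
    manifest$wall_time_s <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    path <- file.path(out, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    path
  }

  result <- tryCatch({
    stage <- "input"
    if (identical(config$mode, "simulate")) {
      model <- config_model(config)
      acq <- config_acquisition(config)
      ex <- simulate_experiment(model, acq, seed = config$seed)
      dataset <- ex$tables
    } else {
      dataset <- load_real_dataset(config)
    }
    manifest$stage_counts$input <- lapply(dataset, nrow)
    say("input: %d channels, %d localizations", length(dataset),
        sum(vapply(dataset, nrow, integer(1))))
    for (id in names(dataset)) {
      f <- file.path(out, paste0("localizations_", id, ".csv"))
      write_localizations(dataset[[id]], f)
      record(f)
    }

    stage <- "alignment"
    al_cfg <- config$alignment %||% list(enabled = TRUE)
    if (isTRUE(al_cfg$enabled %||% TRUE)) {
      al <- align_rounds(dataset,
                         reference = al_cfg$reference,
                         bin_size = al_cfg$bin_size %||% 10,
                         max_shift = al_cfg$max_shift %||% 500)
      dataset <- al$aligned
      reg_df <- as.data.frame(al$registration)
      f <- file.path(out, "registration.csv")
      utils::write.csv(reg_df, f, row.names = FALSE, quote = FALSE)
      record(f)
      manifest$stage_counts$alignment <- nrow(reg_df)
      say("alignment: reference %s, max |shift| %.1f nm",
          al$registration$reference,
          max(abs(c(reg_df$dx_nm, reg_df$dy_nm))))
    }

    stage <- "proximity"
    px <- config$proximity %||% list()
    pm <- proximity_map(dataset,
                        cutoff = px$cutoff %||% 500,
                        symmetrize = isTRUE(px$symmetrize),
                        min_pair_count = px$min_pair_count %||% 50)
    f <- file.path(out, "median_matrix.csv")
    utils::write.csv(as.matrix(pm), f, quote = FALSE)
    record(f)
    long <- as.data.frame(pm)
    f <- file.path(out, "pair_distances.csv")
    utils::write.csv(long, f, row.names = FALSE, quote = FALSE)
    record(f)
    manifest$stage_counts$proximity <- nrow(long)
    say("proximity: %d channels, %d retained pair distances",
        length(pm$channels), nrow(long))
    f <- file.path(out, "heatmap.png")
    ok <- tryCatch({
      grDevices::png(f, width = 960, height = 860, res = 120)
      plot(pm)
      grDevices::dev.off()
      TRUE
    }, error = function(e) {
      warning("heatmap rendering unavailable: ", conditionMessage(e))
      FALSE
    })
    if (ok) record(f)

    stage <- "precision"
    prec <- precision_table(dataset,
                            fit_range = config$precision$fit_range %||% 100)
    f <- file.path(out, "precision.csv")
    utils::write.csv(prec, f, row.names = FALSE, quote = FALSE)
    record(f)
    manifest$stage_counts$precision <- sum(!is.na(prec$sigma_nm))
    say("precision: %d of %d channels estimated",
        sum(!is.na(prec$sigma_nm)), nrow(prec))
    pm
  }, error = function(e) {
    manifest$failed_stage <<- stage
    finish()
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  path <- finish()
  man <- structure(c(manifest, list(manifest_path = path, result = result)),
                   class = "run_manifest")
  invisible(man)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("proximap run (seed %s): %d outputs in %.1f s\n",
              x$seed, length(x$outputs), x$wall_time_s))
  cat(paste0("  ", x$outputs, collapse = "\n"), "\n")
  invisible(x)
}
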