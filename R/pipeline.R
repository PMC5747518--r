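#' Pipeline configuration
#'
#' Collects input paths, thresholds and seeds for [run_pipeline()]. All
#' thresholds default to the conventions used throughout the package:
#' 2 um/min (arrest), 10 um/min and 1.10 (quadrants), >10 voxels and 2 s
#' (transient filters), 20 um^2 (sparkle vs cell-wide).
#'
#' @param out_dir Output directory.
#' @param tracks_csv Optional path to a track table CSV; when `NULL` the
#'   simulate stage generates tracks.
#' @param stack_tiff Optional path to a two-channel TIFF for detection.
#' @param arrest_threshold_um_min,v_threshold_um_min,ratio_threshold
#'   Velocity/ratio thresholds.
#' @param min_voxels,min_duration_s,area_threshold_um2 Transient filters.
#' @param pixel_um,dt_s Optional metadata overrides for TIFF input.
#' @param seed RNG seed for all stochastic stages.
#' @param sim Optional [sim_config()] for the simulate stage.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, tracks_csv = NULL, stack_tiff = NULL,
                            arrest_threshold_um_min = 2,
                            v_threshold_um_min = 10, ratio_threshold = 1.10,
                            min_voxels = 10L, min_duration_s = 2,
                            area_threshold_um2 = 20, pixel_um = NULL,
                            dt_s = NULL, seed = 1L, sim = NULL) {
  thr <- c(arrest_threshold_um_min, v_threshold_um_min, ratio_threshold,
           min_voxels, min_duration_s, area_threshold_um2)
  if (any(thr <= 0)) stop("every threshold must be positive")
  structure(list(out_dir = out_dir, tracks_csv = tracks_csv,
                 stack_tiff = stack_tiff,
                 arrest_threshold_um_min = arrest_threshold_um_min,
                 v_threshold_um_min = v_threshold_um_min,
                 ratio_threshold = ratio_threshold,
                 min_voxels = as.integer(min_voxels),
                 min_duration_s = min_duration_s,
                 area_threshold_um2 = area_threshold_um2,
                 pixel_um = pixel_um, dt_s = dt_s, seed = as.integer(seed),
                 sim = sim %||% sim_config(seed = seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  flat <- unclass(config)
  flat$out_dir <- NULL  # where results land does not change what they are
  flat$sim <- unclass(flat$sim)
  jsonlite::write_json(flat, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes, as configured: simulate (tracks + calcium, when no track CSV
#' is given) -> motility -> calcium -> detect (when a TIFF is given) ->
#' couple -> compare. Writes per-track summary CSV, group curve CSVs,
#' quadrant/state JSON, event table CSV, aligned-average CSV, comparison
#' CSV, and a manifest (package version, seed, config, config hash).
#' Deterministic given the seed.
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector naming the stages to run (default all
#'   applicable).
#' @return Invisibly, a list with the computed objects and output paths.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "motility", "calcium",
                                    "detect", "couple", "compare")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(paths = character(0))
  hash <- config_hash(config)
  emit <- function(df, name) {
    p <- file.path(config$out_dir, name)
    con <- file(p, "w")
    writeLines(sprintf("# config_hash: %s seed: %d", hash, config$seed), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    out$paths <<- c(out$paths, p)
    p
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ts <- NULL
  if ("simulate" %in% stages && is.null(config$tracks_csv)) {
    run_stage("simulate", {
      sim <- simulate_calcium(simulate_tracks(config$sim))
      ts <- sim$tracks
      out$sim <- sim
      emit(sim$truth$pauses, "truth_pauses.csv")
      emit(sim$truth$events, "truth_events.csv")
      write_tracks(ts, file.path(config$out_dir, "tracks.csv"))
      out$paths <- c(out$paths, file.path(config$out_dir, "tracks.csv"))
    })
    ts <- out$sim$tracks
  } else if (!is.null(config$tracks_csv)) {
    ts <- run_stage("read", read_tracks(config$tracks_csv))
  }

  if ("motility" %in% stages && !is.null(ts)) {
    run_stage("motility", {
      summ <- summarize_tracks(ts, config$arrest_threshold_um_min)
      summ$pause_durations_s <- vapply(summ$pause_durations_s,
                                       function(p) paste(p, collapse = ";"),
                                       character(1))
      out$motility <- summ
      emit(summ, "motility_summary.csv")
      dirc <- directionality_ratio_curve(ts)
      out$directionality <- dirc
      emit(dirc$curve, "directionality_curve.csv")
      msd <- msd_curve(ts)
      out$msd <- msd
      emit(msd$curve, "msd_curve.csv")
    })
  }

  has_gr <- !is.null(ts) && !is.null(ts[[1L]]$green)
  if ("calcium" %in% stages && has_gr) {
    run_stage("calcium", {
      traces <- lapply(ts, function(tr) ratio_trace(tr$t_s, tr$green, tr$red))
      names(traces) <- vapply(ts, `[[`, character(1), "cell_id")
      out$traces <- traces
      long <- do.call(rbind, lapply(names(traces), function(cid) {
        cbind(cell_id = cid, as.data.frame(traces[[cid]]))
      }))
      emit(long, "ratio_traces.csv")
      v <- lapply(ts, instantaneous_velocities)
      elev <- lapply(traces, function(rt) {
        classify_elevated(rt$norm_ratio, config$ratio_threshold)[-nrow(rt)]
      })
      qf <- quadrant_fractions(unlist(v), unlist(lapply(traces, function(rt)
        rt$norm_ratio[-nrow(rt)])), config$v_threshold_um_min,
        config$ratio_threshold)
      st <- velocity_by_ca_state(v, elev)
      out$quadrants <- qf
      out$state_velocity <- st
      p <- file.path(config$out_dir, "calcium_summary.json")
      jsonlite::write_json(list(config_hash = hash, seed = config$seed,
                                quadrant_fractions = as.list(qf),
                                velocity_by_state = st$pooled),
                           p, auto_unbox = TRUE, digits = NA)
      out$paths <- c(out$paths, p)
    })
  }

  if ("detect" %in% stages && !is.null(config$stack_tiff)) {
    run_stage("detect", {
      stack <- read_image_tiff(config$stack_tiff, config$pixel_um, config$dt_s)
      masked <- mask_autofluorescence(stack)
      ev <- detect_transients(masked$stack, min_voxels = config$min_voxels,
                              min_duration_s = config$min_duration_s,
                              area_threshold_um2 = config$area_threshold_um2)
      out$events <- ev
      emit(as.data.frame(ev), "transient_events.csv")
    })
  }

  if ("couple" %in% stages && has_gr) {
    run_stage("couple", {
      eta <- event_triggered_average(ts, rise_threshold = config$ratio_threshold)
      out$aligned <- eta
      emit(data.frame(rel_time_s = eta$rel_time_s,
                      mean_velocity = eta$mean_velocity,
                      sem_velocity = eta$sem_velocity),
           "aligned_average.csv")
      sc <- velocity_ratio_scatter(ts)
      out$scatter <- sc
      emit(sc$pairs, "velocity_ratio_scatter.csv")
    })
  }

  if ("compare" %in% stages && !is.null(out$motility) &&
      length(unique(attr(ts, "group"))) >= 2L) {
    run_stage("compare", {
      cmp <- summarize_groups(out$motility$mean_velocity_um_min,
                              out$motility$group)
      out$comparison <- cmp
      emit(cmp$pairs, "group_comparison.csv")
    })
  }

  manifest <- list(package = "stopgo",
                   version = as.character(utils::packageVersion("stopgo")),
                   seed = config$seed, config_hash = hash,
                   stages = stages,
                   config = {
                     flat <- unclass(config); flat$sim <- unclass(flat$sim); flat
                   },
                   outputs = out$paths)
  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, null = "null")
  out$paths <- c(out$paths, mp)
  invisible(out)
}
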