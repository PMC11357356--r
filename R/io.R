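# File formats: MWT-style spine tables, behavior scripts, calcium traces,
# and the nested-YAML run configuration.

#' Write a spine table
#'
#' Tab-delimited, one row per (larva, frame): `larva_id`, `t_s`, then
#' `x1 y1 ... xn yn` in mm, tail first. A leading comment line records the
#' frame rate and spine point count; the header names every column.
#'
#' @param tracks Spine-track tibble.
#' @param path Output file.
#' @param frame_rate_hz Frame rate recorded in the metadata line (inferred
#'   from the data when `NULL`).
#' @return `path`, invisibly.
#' @export
write_spine_table <- function(tracks, path, frame_rate_hz = NULL) {
  sp <- spine_matrices(tracks)
  if (is.null(frame_rate_hz)) {
    dts <- diff(tracks$t[tracks$larva_id == tracks$larva_id[1]])
    frame_rate_hz <- 1 / median(dts)
  }
  df <- dplyr::rename(tracks, t_s = "t")
  writeLines(sprintf("# frame_rate_hz=%g n_spine_points=%d units=mm",
                     frame_rate_hz, sp$n), path)
  readr::write_tsv(df, path, col_names = TRUE, append = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Read a spine table
#'
#' Parses the format written by [write_spine_table()]: rows are grouped by
#' larva and sorted by time on the way in, so shuffled files parse to the
#' same tracks. Malformed rows abort with their line numbers.
#'
#' @param path Spine table file.
#' @return Spine-track tibble with attributes `frame_rate_hz` and
#'   `n_spine_points` from the metadata line.
#' @export
read_spine_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  first <- readLines(path, n = 1)
  meta <- list(frame_rate_hz = NA_real_, n_spine_points = NA_integer_)
  if (startsWith(first, "#")) {
    m <- regmatches(first, gregexpr("(\\w+)=([0-9.]+)", first))[[1]]
    kv <- strsplit(m, "=")
    for (p in kv) meta[[p[1]]] <- as.numeric(p[2])
  } else {
    abort("missing metadata/comment line (expected '# frame_rate_hz=...')")
  }
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!all(c("larva_id", "t_s") %in% names(df)))
    abort("spine table must have larva_id and t_s columns")
  bad <- which(!complete.cases(df))
  if (length(bad))
    abort(paste0("malformed rows (missing fields) at data line(s): ",
                 paste(utils::head(bad, 10), collapse = ", ")))
  df <- df %>%
    rename(t = "t_s") %>%
    arrange(.data$larva_id, .data$t)
  dup <- df %>% group_by(.data$larva_id) %>%
    summarise(bad = any(diff(.data$t) <= 0), .groups = "drop")
  if (any(dup$bad))
    abort(paste0("non-monotone time within larva(e): ",
                 paste(dup$larva_id[dup$bad], collapse = ", ")))
  attr(df, "frame_rate_hz") <- meta$frame_rate_hz
  attr(df, "n_spine_points") <- as.integer(meta$n_spine_points)
  df
}

#' Write / read behavior scripts
#'
#' Ground-truth behavior scripts as CSV (`larva_id`, `behavior`, `start_s`,
#' `end_s`).
#'
#' @param scripts Script tibble.
#' @param path CSV file.
#' @return `path` (write) or the tibble (read).
#' @export
write_behavior_script <- function(scripts, path) {
  readr::write_csv(scripts, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_behavior_script
#' @export
read_behavior_script <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write / read a calcium trace
#'
#' The trace goes to CSV (`t_s`, `f`, `stim`: 1 within 1 s of an onset) and
#' its metadata — onsets, irradiance, frame rate, plus any ground truth — to
#' a JSON sidecar at `<path>.json`.
#'
#' @param trace A [calcium_trace()].
#' @param path CSV file.
#' @param truth Optional ground-truth list stored in the sidecar.
#' @return `path` (write); a [calcium_trace()] (read).
#' @export
write_calcium_trace <- function(trace, path, truth = NULL) {
  stim <- vapply(trace$data$t_s, function(tt)
    any(tt >= trace$stim_onsets & tt < trace$stim_onsets + 1), logical(1))
  readr::write_csv(dplyr::mutate(trace$data, stim = as.integer(stim)), path,
                   progress = FALSE)
  side <- list(stim_onsets = trace$stim_onsets, irradiance = trace$irradiance,
               native_rate_hz = trace$native_rate_hz)
  if (!is.null(truth)) side$truth <- truth
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_calcium_trace
#' @export
read_calcium_trace <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tr <- calcium_trace(df$t_s, df$f, side$stim_onsets,
                      irradiance = side$irradiance %||% NA_real_,
                      native_rate_hz = side$native_rate_hz)
  if (!is.null(side$truth)) tr$truth <- side$truth
  tr
}

# ---- run configuration ----

run_config_defaults <- function() {
  list(
    seed = 1,
    trial = list(pre_stim_s = 45, stim_windows = list(c(45, 75), c(105, 135)),
                 frame_rate_hz = 10, total_s = 165),
    simulator = list(n_larvae = 100, p_roll = 0.6, roll_bout_mean_s = 0.8,
                     roll_bout_shape = 3, baseline_crawl_speed = 0.7,
                     stim_crawl_multiplier = 1.5, inter_bout_crawl = TRUE,
                     body_length_mm = 4, n_spine_points = 11,
                     noise_sd_mm = 0.02),
    classifier = list(roll_curvature_min = 45, roll_crab_ratio_min = 0.5,
                      crawl_speed_min = 0.3, turn_head_angle_min = 30,
                      hunch_length_drop = 0.15, stop_speed_max = 0.1,
                      min_roll_bout_s = 0.2, merge_gap_s = 0.1),
    metrics = list(ci_method = "wilson", conf_level = 0.95, bin_s = 5),
    features = list(smooth_window_s = 0.3, bias_window_s = 1, width_mm = 0.6)
  )
}

#' Read / write a run configuration
#'
#' Nested YAML configuration covering the trial design, simulator,
#' classifier thresholds, feature extraction, and metric options. Unknown
#' keys are rejected so typos cannot silently fall back to defaults;
#' omitted keys take the documented defaults. Round-trips losslessly.
#'
#' @param path YAML file.
#' @param config A run-config list (e.g. from [read_run_config()], possibly
#'   modified).
#' @return A complete run-config list (read); `path` (write).
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path) %||% list()
  defs <- run_config_defaults()
  merge_checked <- function(def, usr, prefix = "") {
    extra <- setdiff(names(usr), names(def))
    if (length(extra))
      abort(paste0("unknown config key(s): ",
                   paste0(prefix, extra, collapse = ", ")))
    for (k in names(usr)) {
      if (is.list(def[[k]]) && !is.null(names(def[[k]])) && is.list(usr[[k]])) {
        def[[k]] <- merge_checked(def[[k]], usr[[k]], paste0(prefix, k, "."))
      } else {
        def[[k]] <- usr[[k]]
      }
    }
    def
  }
  merge_checked(defs, user)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_to_objects <- function(cfg) {
  trial <- trial_design(pre_stim_s = cfg$trial$pre_stim_s,
                        stim_windows = cfg$trial$stim_windows,
                        frame_rate_hz = cfg$trial$frame_rate_hz,
                        total_s = cfg$trial$total_s)
  sim <- do.call(sim_config, c(cfg$simulator, list(trial = trial,
                                                   seed = cfg$seed)))
  thr <- do.call(classifier_thresholds, cfg$classifier)
  list(trial = trial, sim = sim, thresholds = thr)
}
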