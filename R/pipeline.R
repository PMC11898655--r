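# Pipeline orchestration: per-cell analysis driver, configuration
# validation, manifest writing, logging.

.log_levels <- c(debug = 10, info = 20, warn = 30, error = 40)

log_msg <- function(level, fmt, ...) {
  thr <- getOption("mycomorph.log_level", "info")
  if (.log_levels[[level]] >= .log_levels[[thr]])
    message(sprintf("[%s] %s", toupper(level), sprintf(fmt, ...)))
}

#' Per-cell profile extraction over a set of scenes
#'
#' Runs medial-axis extraction and axial profile extraction for every
#' labelled cell of every scene. Cells whose mask is degenerate or whose
#' skeleton is branched are excluded with a logged reason.
#'
#' @param scenes list of `image_scene`.
#' @param channels channel names to profile (default all in the scene).
#' @param width_px,resample_points see [extract_profile()].
#' @return list with `axes` (by cell id), `profiles` (by channel, then cell
#'   id), `lengths` (data frame `cell_id`, `length_um`), `excluded`
#'   (data frame `cell_id`, `reason`).
#' @export
extract_cell_profiles <- function(scenes, channels = NULL, width_px = 10L,
                                  resample_points = 101L) {
  axes <- list(); lengths <- list(); excluded <- list()
  profiles <- list()
  for (scene in scenes) {
    chs <- channels %||% names(scene$channels)
    bg <- lapply(scene$channels[chs], estimate_background, labels = scene$labels)
    ids <- sort(setdiff(unique(as.vector(scene$labels)), 0L))
    for (id in ids) {
      ax <- tryCatch(
        extract_medial_axis(scene$labels, id, scene$pixel_size_um),
        mycomorph_cell_flagged = function(e) e)
      if (inherits(ax, "condition")) {
        log_msg("warn", "cell %d excluded: %s", id, conditionMessage(ax))
        excluded[[length(excluded) + 1]] <-
          data.frame(cell_id = id, reason = ax$reason %||% "flagged")
        next
      }
      key <- as.character(id)
      axes[[key]] <- ax
      lengths[[length(lengths) + 1]] <-
        data.frame(cell_id = id, length_um = measure_length(ax))
      for (ch in chs) {
        profiles[[ch]][[key]] <- extract_profile(
          scene$channels[[ch]], ax, width_px = width_px,
          resample_points = resample_points, background = bg[[ch]],
          channel_name = ch)
      }
    }
  }
  list(axes = axes, profiles = profiles,
       lengths = if (length(lengths)) do.call(rbind, lengths) else
         data.frame(cell_id = integer(0), length_um = numeric(0)),
       excluded = if (length(excluded)) do.call(rbind, excluded) else
         data.frame(cell_id = integer(0), reason = character(0)))
}

#' Full per-cell landmark and asymmetry analysis of a population
#'
#' Chains profile extraction, prominence calibration (or a supplied frozen
#' prominence), foci detection, landmark location, pole-age classification
#' and pole metrics into one per-cell metrics table.
#'
#' @param scenes list of `image_scene`.
#' @param septate logical vector named by cell id (`TRUE` for septate
#'   cells), e.g. from generator ground truth; `NULL` to infer septation
#'   from the presence of a qualifying interior peak.
#' @param channel HADA-like channel name (default `"hada"`).
#' @param ch2 optional second-channel name (e.g. `"mscarlet"`).
#' @param prominence frozen prominence; `NULL` to calibrate on these cells
#'   (then `septate` is required).
#' @param width_px,resample_points see [extract_profile()].
#' @param min_separation see [detect_foci()].
#' @param k_points see [fit_pole_decay()].
#' @return list with `metrics` (per-cell data frame), `profiles`,
#'   `profiles_ch2`, `landmarks`, `foci`, `calibration`, `excluded`.
#' @export
analyze_population <- function(scenes, septate = NULL, channel = "hada",
                               ch2 = NULL, prominence = NULL,
                               width_px = 10L, resample_points = 101L,
                               min_separation = 0.08, k_points = 10L) {
  chs <- c(channel, ch2)
  ex <- extract_cell_profiles(scenes, channels = chs, width_px = width_px,
                              resample_points = resample_points)
  prof <- ex$profiles[[channel]]
  calibration <- NULL
  if (is.null(prominence)) {
    if (is.null(septate)) stop_config("prominence calibration requires septation flags")
    flags <- as.logical(septate[names(prof)])
    calibration <- calibrate_prominence(prof, flags, min_separation = min_separation)
    prominence <- calibration$prominence
    log_msg("info", "calibrated prominence %.4g (agreement %.2f)",
            prominence, calibration$agreement)
  }
  landmarks <- list(); foci <- list(); rows <- list()
  for (key in names(prof)) {
    p <- prof[[key]]
    fs <- detect_foci(p, prominence = prominence, min_separation = min_separation)
    sept_exp <- if (!is.null(septate)) as.logical(septate[[key]]) else NA
    lmk <- locate_landmarks(p, prominence = prominence, septate_expected = sept_exp)
    lmk <- classify_new_old(lmk)
    pm <- pole_metrics(p, lmk, k_points = k_points)
    age <- slope_based_pole_age(pm)
    sl <- c(pm$slope_pole1, pm$slope_pole2)
    ch2_int <- c(old = NA_real_, new = NA_real_)
    if (!is.null(ch2) && !is.na(lmk$new_pole)) {
      ci <- pole_channel_intensity(ex$profiles[[ch2]][[key]], lmk)
      if (!is.null(ci)) ch2_int <- ci
    }
    landmarks[[key]] <- lmk
    foci[[key]] <- fs
    rows[[length(rows) + 1]] <- data.frame(
      cell_id = p$cell_id,
      length_um = p$length_um,
      foci_count = fs$count,
      septum_rel_pos = lmk$septum_rel_pos,
      pole_septum_ratio = pm$pole_septum_ratio,
      slope_pole1 = pm$slope_pole1, slope_pole2 = pm$slope_pole2,
      r2_pole1 = pm$r2_pole1, r2_pole2 = pm$r2_pole2,
      new_pole = if (is.na(lmk$new_pole)) NA_integer_ else lmk$new_pole,
      old_pole = if (is.na(lmk$old_pole)) NA_integer_ else lmk$old_pole,
      slope_new = if (is.na(lmk$new_pole)) NA_real_ else sl[lmk$new_pole],
      slope_old = if (is.na(lmk$old_pole)) NA_real_ else sl[lmk$old_pole],
      slope_age_old_pole = age$old_pole %||% NA_integer_,
      ch2_old = ch2_int[["old"]], ch2_new = ch2_int[["new"]])
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else NULL
  list(metrics = metrics, profiles = prof,
       profiles_ch2 = if (!is.null(ch2)) ex$profiles[[ch2]] else NULL,
       landmarks = landmarks, foci = foci, axes = ex$axes,
       calibration = calibration, prominence = prominence,
       excluded = ex$excluded)
}

#' Read a pipeline configuration file (YAML or JSON)
#'
#' @param path configuration file; `.json` is parsed as JSON, anything else
#'   as YAML. (YAML 1.1 reads a bare key `n` as a boolean; it is restored.)
#' @return the configuration as a named list.
#' @export
read_pipeline_config <- function(path) {
  config <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else yaml::read_yaml(path)
  config$groups <- lapply(config$groups, function(g) {
    names(g)[names(g) %in% c("FALSE", "TRUE")] <- "n"
    g
  })
  config
}

validate_config <- function(config) {
  req <- c("seed", "out", "pixel_size_um", "groups")
  for (f in req) if (is.null(config[[f]])) stop_config("config error: missing field '%s'", f)
  if (!length(config$groups)) stop_config("config error: 'groups' is empty")
  for (i in seq_along(config$groups)) {
    g <- config$groups[[i]]
    for (f in c("name", "preset", "n"))
      if (is.null(g[[f]])) stop_config("config error: groups[[%d]] missing field '%s'", i, f)
  }
  defaults <- list(channel = "hada", width_px = 10L, resample_points = 101L,
                   min_separation = 0.08, k_points = 10L, alpha = 0.05,
                   calibrate_on = NULL,
                   compare = c("length_um", "foci_count", "septum_rel_pos",
                               "pole_septum_ratio", "slope_new", "slope_old"),
                   spectral = NULL, log_level = "info")
  for (f in names(defaults)) config[[f]] <- config[[f]] %||% defaults[[f]]
  if (is.null(config$calibrate_on)) {
    gnames <- vapply(config$groups, `[[`, "", "name")
    config$calibrate_on <- if ("control" %in% gnames) "control" else gnames[1]
  }
  config
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes simulate -> profiles -> landmarks -> asymmetry (and optionally
#' the spectral phasor stage) -> group statistics, writing all scene files,
#' tables and a run manifest (resolved configuration, package version, seed,
#' per-stage cell counts with exclusion reasons, and md5 checksums of every
#' output) under the configured output directory. The same configuration
#' and seed always reproduce identical outputs.
#'
#' @param config a named list, or the path of a YAML/JSON configuration
#'   file. Required fields: `seed`, `out`, `pixel_size_um`, `groups` (each
#'   group a list with `name`, `preset`, `n`, optional `overrides`).
#'   Optional: `channel`, `width_px`, `resample_points`, `min_separation`,
#'   `k_points`, `alpha`, `calibrate_on`, `compare` (metric names),
#'   `spectral` (list with `presets`, `n_cells`, optional `bins`),
#'   `log_level`.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_config(config)
  old_opt <- options(mycomorph.log_level = config$log_level)
  on.exit(options(old_opt))
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  counts <- list()
  group_results <- list()

  # pass 1: simulate and profile every group; calibrate on the control group
  pops <- list()
  for (g in config$groups) {
    log_msg("info", "simulating group '%s' (%s, n = %d)", g$name, g$preset, g$n)
    pops[[g$name]] <- generate_population(
      g$preset, n = g$n, pixel_size_um = config$pixel_size_um,
      seed = config$seed, overrides = g$overrides %||% list())
  }
  cal_name <- config$calibrate_on
  if (is.null(pops[[cal_name]]))
    stop_config("config error: calibrate_on group '%s' not found", cal_name)

  septate_flags <- function(pop) {
    stats::setNames(pop$truth$cells$septate, as.character(pop$truth$cells$cell_id))
  }
  log_msg("info", "calibrating prominence on group '%s'", cal_name)
  cal_res <- analyze_population(
    pops[[cal_name]]$scenes, septate = septate_flags(pops[[cal_name]]),
    channel = config$channel,
    ch2 = if ("mscarlet" %in% names(pops[[cal_name]]$scenes[[1]]$channels)) "mscarlet",
    width_px = config$width_px, resample_points = config$resample_points,
    min_separation = config$min_separation, k_points = config$k_points)
  prominence <- cal_res$prominence
  f_cal <- file.path(out, "calibration.json")
  jsonlite::write_json(list(prominence = prominence,
                            agreement = cal_res$calibration$agreement,
                            grid = cal_res$calibration$grid),
                       f_cal, auto_unbox = TRUE, digits = NA)
  files <- c(files, f_cal)

  for (g in config$groups) {
    pop <- pops[[g$name]]
    gdir <- file.path(out, g$name)
    dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(pop$scenes))
      files <- c(files, write_scene(pop$scenes[[i]], gdir, sprintf("scene%03d", i)))
    files <- c(files, write_ground_truth(pop$truth, pop$params, gdir))
    res <- if (g$name == cal_name) cal_res else analyze_population(
      pop$scenes, septate = septate_flags(pop), channel = config$channel,
      ch2 = if ("mscarlet" %in% names(pop$scenes[[1]]$channels)) "mscarlet",
      prominence = prominence,
      width_px = config$width_px, resample_points = config$resample_points,
      min_separation = config$min_separation, k_points = config$k_points)
    f_prof <- file.path(gdir, "profiles.csv")
    write_profiles_csv(res$profiles, f_prof)
    f_met <- file.path(gdir, "metrics.csv")
    utils::write.csv(res$metrics, f_met, row.names = FALSE)
    f_exc <- file.path(gdir, "excluded.csv")
    utils::write.csv(res$excluded, f_exc, row.names = FALSE)
    files <- c(files, f_prof, f_met, f_exc)
    counts[[g$name]] <- list(cells_in = g$n,
                             cells_analyzed = nrow(res$metrics),
                             cells_excluded = nrow(res$excluded),
                             exclusion_reasons = as.list(table(res$excluded$reason)))
    group_results[[g$name]] <- res
  }

  # population summary and group comparisons
  all_metrics <- do.call(rbind, lapply(names(group_results), function(nm) {
    cbind(group = nm, group_results[[nm]]$metrics)
  }))
  summ <- population_summary(all_metrics[setdiff(names(all_metrics), "cell_id")], "group")
  f_sum <- file.path(out, "summary.csv")
  utils::write.csv(summ, f_sum, row.names = FALSE)
  files <- c(files, f_sum)

  comp_rows <- list()
  if (length(group_results) >= 2) {
    for (m in config$compare) {
      vals <- lapply(group_results, function(r) {
        v <- r$metrics[[m]]
        v[is.finite(v)]
      })
      vals <- vals[vapply(vals, length, 0L) >= 3]
      if (length(vals) < 2) {
        log_msg("warn", "metric '%s': fewer than 2 groups with n >= 3; skipped", m)
        next
      }
      gc <- compare_groups(vals, alpha = config$alpha, metric = m)
      comp_rows[[m]] <- data.frame(
        metric = m, test = gc$test_used, statistic = gc$statistic,
        p_value = gc$p_value, significant = gc$significant,
        n = paste(gc$n, collapse = "/"))
    }
  }
  f_cmp <- file.path(out, "comparisons.csv")
  utils::write.csv(do.call(rbind, comp_rows) %||%
                     data.frame(metric = character(0)), f_cmp, row.names = FALSE)
  files <- c(files, f_cmp)

  # optional spectral phasor stage
  if (!is.null(config$spectral)) {
    sp <- config$spectral
    sp_rows <- list(); curve_rows <- list()
    wl <- seq(423, 713, by = 10)
    ref_a <- phasor_point(exp(-(wl - 440)^2 / (2 * 15^2)))[c("G", "S")]
    ref_b <- phasor_point(exp(-(wl - 520)^2 / (2 * 30^2)))[c("G", "S")]
    for (ps in sp$presets) {
      gen <- generate_spectral_population(ps, n_cells = sp$n_cells %||% 12,
                                          seed = config$seed)
      sdir <- file.path(out, paste0("spectral_", ps))
      files <- c(files, write_spectral_scene(gen$scene, sdir))
      field <- spectral_phasor(gen$scene)
      sm <- phasor_summary(field)
      sm$preset <- ps
      sp_rows[[ps]] <- sm
      fr <- linear_fraction(field, ref_a, ref_b)
      cv <- fraction_curve(field, fr, bins = sp$bins %||% 50)
      curve_rows[[ps]] <- data.frame(preset = ps, fraction = cv$mid,
                                     value = cv$value,
                                     center_of_mass = cv$center_of_mass)
    }
    f_sp <- file.path(out, "spectral_summary.csv")
    utils::write.csv(do.call(rbind, sp_rows), f_sp, row.names = FALSE)
    f_cv <- file.path(out, "fraction_curves.csv")
    utils::write.csv(do.call(rbind, curve_rows), f_cv, row.names = FALSE)
    files <- c(files, f_sp, f_cv)
  }

  manifest <- list(
    package = "mycomorph",
    version = as.character(utils::packageVersion("mycomorph")),
    seed = config$seed,
    config = config[setdiff(names(config), "out")],
    prominence = prominence,
    counts = counts,
    checksums = as.list(tools::md5sum(sort(files)))
  )
  names(manifest$checksums) <-
    sub("^/+", "", substring(names(manifest$checksums), nchar(out) + 1))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_msg("info", "pipeline complete: %d file(s) under %s", length(files) + 1, out)
  invisible(manifest)
}
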