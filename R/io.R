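# Declared CSV schemas: required columns and their types.
table_schemas <- list(
  sensor_trace = c(plant_id = "character", group = "character",
                   time_min = "numeric", i_ds_uA = "numeric",
                   i_ds0_uA = "numeric"),
  physio = c(plant_id = "character", group = "character", day = "integer",
             measure = "character", replicate = "integer", value = "numeric"),
  manifest = c(plant_id = "character", day = "integer", view = "character",
               modality = "character", path = "character"),
  response = c(plant_id = "character", time_min = "numeric", r = "numeric"),
  daily_nr = c(day = "integer", nr = "numeric", n_stressed = "integer",
               n_control = "integer"),
  indices = c(plant_id = "character", day = "integer", biovolume = "numeric",
              height_px = "numeric", compactness = "numeric",
              green_index = "numeric", nir_index = "numeric")
)

#' Write a pipeline table as CSV
#'
#' Plain RFC 4180 CSV; the schema check runs before writing. Provenance
#' (tool version, seed, config hash) accompanies the tables in the run's
#' `manifest.json` rather than in per-file headers.
#'
#' @param df data.frame.
#' @param path output file.
#' @param schema_id one of `names(table_schemas)`.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, schema_id) {
  check_schema(df, schema_id)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a pipeline CSV
#'
#' Missing required columns raise an error naming the column; extra columns
#' produce a warning and are preserved. Integer columns round-trip
#' bit-exactly.
#'
#' @param path CSV file.
#' @param schema_id one of `names(table_schemas)`.
#' @return validated data.frame.
#' @export
read_table <- function(path, schema_id) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, schema_id)
  df
}

check_schema <- function(df, schema_id) {
  schema <- table_schemas[[schema_id]]
  if (is.null(schema)) stop("unknown schema: ", schema_id)
  miss <- setdiff(names(schema), names(df))
  if (length(miss)) {
    stop(sprintf("table does not match schema '%s': missing column(s) %s",
                 schema_id, paste(miss, collapse = ", ")))
  }
  extra <- setdiff(names(df), names(schema))
  if (length(extra)) {
    warning(sprintf("schema '%s': extra column(s) preserved: %s",
                    schema_id, paste(extra, collapse = ", ")))
  }
  for (col in names(schema)) {
    v <- df[[col]]
    ok <- switch(schema[[col]],
                 character = is.character(v) || is.factor(v),
                 integer = is.numeric(v) && all(!is.finite(v) | v == round(v)),
                 numeric = is.numeric(v))
    if (!ok) stop(sprintf("schema '%s': column '%s' is not %s",
                          schema_id, col, schema[[col]]))
  }
  invisible(df)
}

#' Run configuration for the full pipeline
#'
#' @param design an `experiment_design` or preset name.
#' @param config a [generator_config()] (its seed drives every stage).
#' @param out_dir output directory.
#' @param window_h,alpha onset-detection parameters.
#' @param green_window,compactness_view imaging parameters.
#' @param star_map_name `"conventional"` or `"inverted"`.
#' @param test_method `"anova"` or `"t_test"` for per-timepoint tests.
#' @return a `run_config` list.
#' @export
run_config <- function(design = "MAIN", config = generator_config(),
                       out_dir = "phytosense_run", window_h = 12,
                       alpha = 0.05, green_window = c(60, 180),
                       compactness_view = "top",
                       star_map_name = "conventional",
                       test_method = "anova") {
  if (is.character(design)) design <- build_design(design)
  structure(list(design = design, config = config, out_dir = out_dir,
                 window_h = window_h, alpha = alpha,
                 green_window = green_window,
                 compactness_view = compactness_view,
                 star_map_name = star_map_name, test_method = test_method),
            class = "run_config")
}

#' Run the complete pipeline
#'
#' simulate -> sensor -> imaging -> physiology -> stats, writing every
#' intermediate and final artifact under `rc$out_dir`, plus a
#' `manifest.json` with package version, seed, config hash and per-stage row
#' counts. Reruns with the same configuration are byte-identical.
#'
#' @param rc a [run_config()].
#' @param render_images render and analyse the PNG image series (the slowest
#'   stage)? If `FALSE`, image indices are computed from in-memory renders
#'   all the same; this flag only controls writing PNGs to disk.
#' @param quiet suppress stage logging to stderr?
#' @return (invisibly) list with all in-memory results: `traj, trace,
#'   response, daily, nr, segmentation, onset, recovery, physio, summary,
#'   indices, features, correlations, pca, tests`.
#' @export
run_all <- function(rc = run_config(), render_images = TRUE, quiet = FALSE) {
  t_start <- Sys.time()
  log <- function(...) if (!quiet) message(sprintf("[phytosense +%.1fs] ",
    as.numeric(difftime(Sys.time(), t_start, units = "secs"))), sprintf(...))
  design <- rc$design; config <- rc$config
  dir.create(rc$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(rc$out_dir, ...)

  log("simulate: latent states, traces, physiology")
  traj <- simulate_latent_states(config, design)
  trace <- synthesize_sensor_trace(traj)
  write_table(trace, p("sensor_trace.csv"), "sensor_trace")
  physio <- sample_physiology(traj)
  write_table(physio, p("physio.csv"), "physio")
  write_design(design, p("design.yaml"))

  log("sensor: response, daily NR, phases, onset")
  response <- compute_response(trace)
  write_table(response[, c("plant_id", "time_min", "r")], p("response.csv"),
              "response")
  daily <- daily_mean(response, design)
  nr <- normalize_nr(daily[daily$group == "stressed", ],
                     daily[daily$group == "control", ])
  write_table(nr, p("daily_nr.csv"), "daily_nr")
  segmentation <- segment_phases(nr, design)
  onset <- detect_onset(response_ratio_series(response), design,
                        window_h = rc$window_h, alpha = rc$alpha)
  recovery <- tryCatch(recovery_deficit(nr, segmentation),
                       error = function(e) NA_real_)
  jsonlite::write_json(
    list(segments = segmentation$segments,
         breakpoints = segmentation$breakpoints, k = segmentation$k),
    p("phases.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(c(onset, list(recovery_deficit = recovery)),
                       p("onset.json"), auto_unbox = TRUE, digits = NA)

  log("imaging: render + indices (%d days x %d plants)",
      length(design$imaging_days), nrow(traj$plants))
  indices <- if (render_images) {
    img_dir <- p("images")
    man <- render_plant_images(traj, img_dir)
    extract_indices_from_manifest(man, img_dir,
                                  compactness_view = rc$compactness_view,
                                  green_window = rc$green_window)
  } else {
    extract_indices_in_memory(traj, compactness_view = rc$compactness_view,
                              green_window = rc$green_window)
  }
  write_table(indices, p("indices.csv"), "indices")

  log("physiology summary")
  summ <- physio_summary(physio)
  utils::write.csv(summ$sc, p("physio_sc.csv"), row.names = FALSE)
  if (!is.null(summ$rwc_group)) {
    utils::write.csv(summ$rwc_group, p("physio_rwc.csv"), row.names = FALSE)
  }
  utils::write.csv(summ$spad, p("physio_spad.csv"), row.names = FALSE)

  log("stats: correlations, PCA, per-timepoint tests")
  # integrate over the stress-period timepoints only (for the MAIN design,
  # the 11 imaging days from stress start onward); pre-stress rows carry no
  # treatment contrast
  s0 <- stress_start_day(design)
  idx_stress <- if (is.na(s0)) indices else indices[indices$day >= s0, , drop = FALSE]
  features <- build_feature_table(idx_stress, daily, physio)
  utils::write.csv(features, p("features.csv"), row.names = FALSE)
  cors <- correlation_matrix(features)
  utils::write.csv(as.data.frame(cors$r), p("correlations.csv"))
  pca <- run_pca(features)
  utils::write.csv(as.data.frame(pca$scores), p("pca_scores.csv"))
  utils::write.csv(as.data.frame(pca$loadings), p("pca_loadings.csv"))
  utils::write.csv(data.frame(component = seq_along(pca$variance_explained),
                              variance_explained = pca$variance_explained),
                   p("variance_explained.csv"), row.names = FALSE)
  jsonlite::write_json(list(scores = as.data.frame(pca$biplot$scores),
                            loadings = as.data.frame(pca$biplot$loadings),
                            group = pca$group),
                       p("biplot.json"), digits = NA)
  long <- stats::reshape(features[, c("group", "day", feature_variables)],
                         varying = feature_variables, v.names = "value",
                         timevar = "variable", times = feature_variables,
                         direction = "long")
  tests <- timepoint_tests(long, method = rc$test_method,
                           map = star_map(rc$star_map_name))
  utils::write.csv(tests, p("timepoint_tests.csv"), row.names = FALSE)

  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(rc$config[order(names(rc$config))], cfg_file,
                       auto_unbox = TRUE, digits = NA)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  jsonlite::write_json(list(
    tool = "phytosense",
    version = as.character(utils::packageVersion("phytosense")),
    seed = config$seed, config_hash = cfg_hash,
    design = design$name,
    rows = list(sensor_trace = nrow(trace), physio = nrow(physio),
                daily_nr = nrow(nr), indices = nrow(indices),
                features = nrow(features), tests = nrow(tests))),
    p("manifest.json"), auto_unbox = TRUE, digits = NA)
  log("done")
  invisible(list(traj = traj, trace = trace, response = response,
                 daily = daily, nr = nr, segmentation = segmentation,
                 onset = onset, recovery = recovery, physio = physio,
                 summary = summ, indices = indices, features = features,
                 correlations = cors, pca = pca, tests = tests))
}

#' Image indices without touching disk
#'
#' Renders each plant x imaging day in memory and runs the same segmentation
#' and index extraction as the PNG path.
#'
#' @param traj a `plant_trajectories`.
#' @param ... passed to [extract_indices()].
#' @return data.frame of indices.
#' @export
extract_indices_in_memory <- function(traj, ...) {
  design <- traj$design; config <- traj$config
  rows <- list(); k <- 0L
  for (day in design$imaging_days) {
    st_day <- traj$daily[traj$daily$day == day, , drop = FALSE]
    for (i in seq_len(nrow(st_day))) {
      st <- st_day[i, ]
      rv <- lapply(c(side0 = "side0", side90 = "side90", top = "top"),
                   function(v) render_view(st$biomass, st$height, st$turgor,
                                           st$chlorosis_frac, st$hydration,
                                           v, config$image_size))
      iset <- list(plant_id = st$plant_id, day = day,
                   rgb = lapply(rv, `[[`, "rgb"),
                   nir = lapply(rv, `[[`, "nir"))
      k <- k + 1L
      rows[[k]] <- extract_indices(iset, ...)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
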