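#' Experiment designs for drought-stress runs
#'
#' An `experiment_design` encodes the watering/imaging/physiology timetable of
#' a drought experiment so that simulation, phase labelling and per-timepoint
#' statistics all share one schedule. Days are 0-based from bioristor
#' implantation; all timestamps elsewhere in the package are minutes since
#' implantation.
#'
#' Two presets reproduce the published experiments:
#' \describe{
#'   \item{PILOT}{cv. Red Setter, 16 h photoperiod: 3 d settling after sensor
#'     insertion, 14 d drought (DSI), 2 d rewatering (RE), 6 d second drought
#'     (DSII); 25 d total.}
#'   \item{MAIN}{cv. Ikram, 12 h photoperiod: 1 d settling, 16 d drought with
#'     one limited 50 cm\eqn{^3} irrigation at day 8 to preserve turgor, 7 d
#'     rewatering; 24 d total. Imaging every 2 d.}
#' }
#'
#' @param preset `"MAIN"` or `"PILOT"`, or `NULL` to build from the explicit
#'   arguments.
#' @param duration_days,photoperiod_h,sampling_interval_min scalars describing
#'   the run; ignored when a preset is given.
#' @param control_schedule,stressed_schedule character vectors of per-day
#'   watering states (`"FULL"`, `"WITHHELD"`, `"LIMITED"`, `"REWATERED"`),
#'   length `duration_days`.
#' @param limited_volume_cm3 irrigation volume on `LIMITED` days (cm^3).
#' @param imaging_days,physio_days integer day indices within
#'   `[0, duration_days)`.
#' @return An object of class `experiment_design`.
#' @export
build_design <- function(preset = c("MAIN", "PILOT"),
                         duration_days = NULL,
                         photoperiod_h = 12,
                         sampling_interval_min = 15,
                         control_schedule = NULL,
                         stressed_schedule = NULL,
                         limited_volume_cm3 = 50,
                         imaging_days = integer(),
                         physio_days = integer()) {
  if (!is.null(preset) && is.null(duration_days)) {
    preset <- match.arg(preset)
    return(switch(preset,
      MAIN = {
        sch <- rep("FULL", 24)
        sch[day_idx(1:16)] <- "WITHHELD"   # days 1..16 (0-based)
        sch[day_idx(8)] <- "LIMITED"       # emergency irrigation, 50 cm^3
        sch[day_idx(17:23)] <- "REWATERED"
        new_design(
          duration_days = 24, photoperiod_h = 12, sampling_interval_min = 15,
          control = rep("FULL", 24), stressed = sch,
          limited_volume_cm3 = 50,
          imaging_days = seq(0L, 22L, by = 2L),
          physio_days = seq(0L, 22L, by = 2L),
          name = "MAIN"
        )
      },
      PILOT = {
        sch <- rep("FULL", 25)
        sch[day_idx(3:16)] <- "WITHHELD"   # DSI, 14 d from day 3
        sch[day_idx(17:18)] <- "REWATERED" # RE, 2 d
        sch[day_idx(19:24)] <- "WITHHELD"  # DSII, 6 d
        new_design(
          duration_days = 25, photoperiod_h = 16, sampling_interval_min = 15,
          control = rep("FULL", 25), stressed = sch,
          limited_volume_cm3 = NA_real_,
          imaging_days = integer(),
          physio_days = c(10L, 18L),
          name = "PILOT"
        )
      }
    ))
  }
  new_design(
    duration_days = duration_days, photoperiod_h = photoperiod_h,
    sampling_interval_min = sampling_interval_min,
    control = control_schedule, stressed = stressed_schedule,
    limited_volume_cm3 = limited_volume_cm3,
    imaging_days = as.integer(imaging_days),
    physio_days = as.integer(physio_days),
    name = "CUSTOM"
  )
}

# 0-based day index -> 1-based vector position
day_idx <- function(d) d + 1L

watering_states <- c("FULL", "WITHHELD", "LIMITED", "REWATERED")

new_design <- function(duration_days, photoperiod_h, sampling_interval_min,
                       control, stressed, limited_volume_cm3,
                       imaging_days, physio_days, name) {
  d <- structure(
    list(
      name = name,
      duration_days = as.integer(duration_days),
      photoperiod_h = as.numeric(photoperiod_h),
      sampling_interval_min = as.numeric(sampling_interval_min),
      schedule = list(control = as.character(control),
                      stressed = as.character(stressed)),
      limited_volume_cm3 = if (any(stressed == "LIMITED"))
        as.numeric(limited_volume_cm3) else NA_real_,
      imaging_days = as.integer(imaging_days),
      physio_days = as.integer(physio_days)
    ),
    class = "experiment_design"
  )
  validate_design(d)
}

validate_design <- function(d) {
  if (d$duration_days < 1L) stop("duration_days must be >= 1 (empty design)")
  for (g in names(d$schedule)) {
    sch <- d$schedule[[g]]
    if (length(sch) != d$duration_days) {
      stop(sprintf("schedule for group '%s' has length %d, expected %d (gap or overlap)",
                   g, length(sch), d$duration_days))
    }
    bad <- setdiff(unique(sch), watering_states)
    if (length(bad)) stop("unknown watering state(s): ", paste(bad, collapse = ", "))
  }
  if (any(d$schedule$control %in% c("WITHHELD", "LIMITED"))) {
    stop("control group schedule must not contain WITHHELD/LIMITED days")
  }
  if (!is.na(d$limited_volume_cm3) && any(d$schedule$stressed == "LIMITED") &&
      d$limited_volume_cm3 <= 0) {
    stop("limited_volume_cm3 must be > 0 when LIMITED days are present")
  }
  if (length(d$imaging_days) &&
      (min(d$imaging_days) < 0L || max(d$imaging_days) >= d$duration_days)) {
    stop("imaging_days must lie within [0, duration_days)")
  }
  if (length(d$physio_days) &&
      (min(d$physio_days) < 0L || max(d$physio_days) >= d$duration_days)) {
    stop("physio_days must lie within [0, duration_days)")
  }
  d
}

#' First drought day of the stressed group
#'
#' @param design an `experiment_design`.
#' @return 0-based day index of the first water-withholding day, or `NA` if
#'   the design has no drought block.
#' @export
stress_start_day <- function(design) {
  dd <- drought_days(design)
  if (!length(dd)) NA_integer_ else dd[1L]
}

#' Days belonging to a drought block (WITHHELD or LIMITED)
#'
#' The limited emergency irrigation day sits inside the withholding block and
#' counts as a drought day.
#'
#' @param design an `experiment_design`.
#' @return sorted 0-based day indices.
#' @export
drought_days <- function(design) {
  which(design$schedule$stressed %in% c("WITHHELD", "LIMITED")) - 1L
}

#' Rewatering days of the stressed group
#' @param design an `experiment_design`.
#' @return sorted 0-based day indices.
#' @export
rewatered_days <- function(design) {
  which(design$schedule$stressed == "REWATERED") - 1L
}

#' Expected phase windows for a design
#'
#' Labels the normalized-response trajectory phases from the watering
#' schedule: PI (post-implantation settling, before the first drought day),
#' PII (drought decline), DA (the innate "drought avoidance" rebound, a
#' sub-window of PII whose bounds are only determined by segmentation), PIII
#' (post-rewatering recovery) and PIV (a second drought block, if present).
#'
#' @param design an `experiment_design`.
#' @return data.frame with columns `label`, `start_day`, `end_day` (half-open
#'   `[start, end)` windows; `NA` bounds for DA).
#' @export
phase_label_template <- function(design) {
  n <- design$duration_days
  sch <- design$schedule$stressed
  dd <- drought_days(design)
  if (!length(dd)) {
    return(data.frame(label = "PI", start_day = 0L, end_day = n,
                      stringsAsFactors = FALSE))
  }
  s0 <- dd[1L]
  # contiguous drought blocks
  blocks <- split(dd, cumsum(c(1L, diff(dd) != 1L)))
  rw <- rewatered_days(design)
  out <- data.frame(label = "PI", start_day = 0L, end_day = s0,
                    stringsAsFactors = FALSE)
  b1 <- blocks[[1L]]
  out <- rbind(out, data.frame(label = "PII", start_day = b1[1L],
                               end_day = b1[length(b1)] + 1L))
  out <- rbind(out, data.frame(label = "DA", start_day = NA_integer_,
                               end_day = NA_integer_))
  if (length(rw)) {
    piii_end <- if (length(blocks) > 1L) blocks[[2L]][1L] else n
    out <- rbind(out, data.frame(label = "PIII", start_day = rw[1L],
                                 end_day = piii_end))
  }
  if (length(blocks) > 1L) {
    b2 <- blocks[[2L]]
    out <- rbind(out, data.frame(label = "PIV", start_day = b2[1L],
                                 end_day = b2[length(b2)] + 1L))
  }
  rownames(out) <- NULL
  out
}

#' Serialize a design to YAML
#'
#' The schedule is run-length encoded into `{state, start_day, end_day}`
#' blocks (half-open). `read_design()` inverts the encoding exactly.
#'
#' @param design an `experiment_design`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  enc_group <- function(sch) {
    r <- rle(sch)
    ends <- cumsum(r$lengths)
    starts <- c(0L, ends[-length(ends)])
    lapply(seq_along(r$values), function(i) {
      b <- list(state = r$values[i], start_day = starts[i], end_day = ends[i])
      if (r$values[i] == "LIMITED") b$volume_cm3 <- design$limited_volume_cm3
      b
    })
  }
  obj <- list(
    name = design$name,
    duration_days = design$duration_days,
    photoperiod_h = design$photoperiod_h,
    sampling_interval_min = design$sampling_interval_min,
    groups = lapply(design$schedule, enc_group),
    imaging_days = as.list(design$imaging_days),
    physio_days = as.list(design$physio_days)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a design written by [write_design()]
#' @param path YAML file.
#' @return an `experiment_design`.
#' @export
read_design <- function(path) {
  obj <- yaml::read_yaml(path)
  dec_group <- function(blocks, n) {
    sch <- rep(NA_character_, n)
    for (b in blocks) {
      if (b$end_day <= b$start_day) stop("schedule block with end <= start")
      sch[(b$start_day + 1L):b$end_day] <- b$state
    }
    if (anyNA(sch)) stop("schedule has gaps")
    sch
  }
  vol <- NA_real_
  for (b in obj$groups$stressed) if (!is.null(b$volume_cm3)) vol <- b$volume_cm3
  d <- new_design(
    duration_days = obj$duration_days, photoperiod_h = obj$photoperiod_h,
    sampling_interval_min = obj$sampling_interval_min,
    control = dec_group(obj$groups$control, obj$duration_days),
    stressed = dec_group(obj$groups$stressed, obj$duration_days),
    limited_volume_cm3 = vol,
    imaging_days = unlist(obj$imaging_days, use.names = FALSE),
    physio_days = unlist(obj$physio_days, use.names = FALSE),
    name = obj$name
  )
  d
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("<experiment_design '%s'>: %d d, %g h photoperiod, %g min sampling\n",
              x$name, x$duration_days, x$photoperiod_h, x$sampling_interval_min))
  dd <- drought_days(x)
  if (length(dd)) {
    cat(sprintf("  drought days: %s; rewatered: %s\n",
                paste(range(dd), collapse = "-"),
                if (length(rewatered_days(x))) paste(range(rewatered_days(x)), collapse = "-") else "none"))
  }
  invisible(x)
}

#' Plant roster for a two-group experiment
#'
#' @param n_per_group plants per group.
#' @param cultivar cultivar label attached to every plant.
#' @return data.frame with `plant_id`, `cultivar`, `group`.
#' @export
plant_roster <- function(n_per_group = 4L, cultivar = "Ikram") {
  data.frame(
    plant_id = c(sprintf("C%02d", seq_len(n_per_group)),
                 sprintf("S%02d", seq_len(n_per_group))),
    cultivar = cultivar,
    group = rep(c("control", "stressed"), each = n_per_group),
    stringsAsFactors = FALSE
  )
}
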