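#' Relative water content (Barrs-Weatherley)
#'
#' \deqn{RWC = 100 (FW - DW) / (TW - DW)}
#' with fresh (FW), turgid (TW) and dry (DW) leaf weights in grams.
#' FW outside `[DW, TW]` indicates a measurement error: the value is still
#' returned but flagged via the `flagged` attribute. Vectorized.
#'
#' @param fw,tw,dw weights (g); `tw > dw` required.
#' @return RWC in percent, attribute `flagged` (logical vector).
#' @export
compute_rwc <- function(fw, tw, dw) {
  if (any(tw <= dw)) stop("turgid weight must exceed dry weight")
  flagged <- fw < dw | fw > tw
  structure(100 * (fw - dw) / (tw - dw), flagged = flagged)
}

#' Relative SPAD: plant mean over same-day control-group mean
#'
#' @param plant_mean mean SPAD reading(s) of a plant.
#' @param control_mean same-day control-group mean SPAD (> 0).
#' @return ratio; > 1 indicates raised chlorophyll reading versus control.
#' @export
relative_spad <- function(plant_mean, control_mean) {
  if (any(is.na(control_mean)) || any(control_mean <= 0)) {
    stop("control mean SPAD missing or non-positive")
  }
  plant_mean / control_mean
}

#' Stomatal-conductance fold change (control over stressed)
#'
#' @param control_mean,stressed_mean group mean SC on the same day.
#' @return fold reduction; 4-5 at peak drought stress in the emulated
#'   experiment.
#' @export
sc_fold_change <- function(control_mean, stressed_mean) {
  if (any(stressed_mean == 0)) stop("stressed SC mean is zero")
  control_mean / stressed_mean
}

#' Summarize a physiology table
#'
#' Computes, per day: group mean SC and the control/stressed fold change;
#' replicate-level RWC from matched FW/TW/DW triplets and group means;
#' per-plant mean SPAD and the relative SPAD (plant over same-day control
#' mean).
#'
#' @param physio long data.frame `plant_id, group, day, measure, replicate,
#'   value` with measures SC, FW, TW, DW, SPAD.
#' @return list of data.frames: `sc` (day, control_mean, stressed_mean,
#'   fold), `rwc` (plant_id, group, day, replicate, rwc), `rwc_group` (day,
#'   control_mean, stressed_mean, drop_frac), `spad` (plant_id, group, day,
#'   spad_mean, relative_spad).
#' @export
physio_summary <- function(physio) {
  stopifnot(all(c("plant_id", "group", "day", "measure", "replicate", "value")
                %in% names(physio)))
  sc <- physio[physio$measure == "SC", ]
  sc_g <- aggregate(value ~ day + group, sc, mean)
  sc_w <- reshape(sc_g, idvar = "day", timevar = "group", direction = "wide")
  names(sc_w) <- sub("^value\\.", "", names(sc_w))
  sc_w$fold <- ifelse(is.na(sc_w$stressed) | sc_w$stressed == 0, NA_real_,
                      sc_w$control / sc_w$stressed)
  names(sc_w)[names(sc_w) == "control"] <- "control_mean"
  names(sc_w)[names(sc_w) == "stressed"] <- "stressed_mean"

  wide_w <- NULL
  w <- physio[physio$measure %in% c("FW", "TW", "DW"), ]
  if (nrow(w)) {
    wide_w <- reshape(w, idvar = c("plant_id", "group", "day", "replicate"),
                      timevar = "measure", direction = "wide")
    names(wide_w) <- sub("^value\\.", "", names(wide_w))
    wide_w$rwc <- as.numeric(compute_rwc(wide_w$FW, wide_w$TW, wide_w$DW))
  }
  rwc_group <- NULL
  if (!is.null(wide_w)) {
    rg <- aggregate(rwc ~ day + group, wide_w, mean)
    rwc_group <- reshape(rg, idvar = "day", timevar = "group", direction = "wide")
    names(rwc_group) <- sub("^rwc\\.", "", names(rwc_group))
    names(rwc_group)[names(rwc_group) == "control"] <- "control_mean"
    names(rwc_group)[names(rwc_group) == "stressed"] <- "stressed_mean"
    rwc_group$drop_frac <- 1 - rwc_group$stressed_mean / rwc_group$control_mean
  }

  spad <- physio[physio$measure == "SPAD", ]
  spad_p <- aggregate(value ~ plant_id + group + day, spad, mean)
  names(spad_p)[names(spad_p) == "value"] <- "spad_mean"
  ctrl <- aggregate(spad_mean ~ day, spad_p[spad_p$group == "control", ], mean)
  names(ctrl)[2] <- "control_mean"
  spad_p$relative_spad <- relative_spad(
    spad_p$spad_mean, ctrl$control_mean[match(spad_p$day, ctrl$day)])

  list(sc = sc_w[order(sc_w$day), ],
       rwc = wide_w,
       rwc_group = if (!is.null(rwc_group)) rwc_group[order(rwc_group$day), ] else NULL,
       spad = spad_p[order(spad_p$day, spad_p$plant_id), ])
}
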