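#' Sensor response R from raw bioristor currents
#'
#' R is the relative change of the drain current with the gate on versus off:
#' \deqn{R_t = (I_{ds,t} - I_{ds0,t}) / I_{ds0,t}.}
#' Samples where the gate-off current is below `ids0_floor_uA` in magnitude
#' are dropped (division guard) and counted in the `n_dropped` attribute.
#'
#' @param trace data.frame with columns `plant_id`, `time_min`, `i_ds_uA`,
#'   `i_ds0_uA` (a `group` column, if present, is carried through).
#' @param ids0_floor_uA minimum |Ids0| (microampere) for a sample to be kept.
#' @return data.frame `plant_id[, group], time_min, r`, with attribute
#'   `n_dropped`.
#' @export
compute_response <- function(trace, ids0_floor_uA = 1e-3) {
  req <- c("plant_id", "time_min", "i_ds_uA", "i_ds0_uA")
  miss <- setdiff(req, names(trace))
  if (length(miss)) stop("trace is missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(trace)) stop("empty trace")
  for (tt in split(trace$time_min, trace$plant_id)) {
    if (any(diff(tt) <= 0)) stop("time_min must be strictly increasing per plant")
  }
  keep <- abs(trace$i_ds0_uA) >= ids0_floor_uA
  n_dropped <- sum(!keep)
  if (!any(keep)) stop("all samples dropped by the |i_ds0| floor")
  tr <- trace[keep, , drop = FALSE]
  out <- data.frame(plant_id = tr$plant_id, time_min = tr$time_min,
                    r = (tr$i_ds_uA - tr$i_ds0_uA) / tr$i_ds0_uA,
                    stringsAsFactors = FALSE)
  if ("group" %in% names(tr)) out$group <- tr$group
  rownames(out) <- NULL
  structure(out, n_dropped = n_dropped)
}

#' Per-plant daily mean response
#'
#' Averages R over each 24 h window `[d*24h, (d+1)*24h)` of the implantation
#' clock. Days with fewer than `min_coverage` of the expected samples are
#' flagged incomplete and, by default, excluded.
#'
#' @param response data.frame from [compute_response()].
#' @param design the `experiment_design` (supplies the sampling interval).
#' @param min_coverage minimum fraction of expected samples per day.
#' @param keep_incomplete keep flagged days in the output?
#' @return data.frame `plant_id[, group], day, r_mean, n_samples, incomplete`.
#' @export
daily_mean <- function(response, design, min_coverage = 0.5,
                       keep_incomplete = FALSE) {
  expected <- 1440 / design$sampling_interval_min
  day <- floor(response$time_min / 1440)
  agg <- aggregate(response$r, by = list(plant_id = response$plant_id, day = day),
                   FUN = function(v) c(mean(v), length(v)))
  out <- data.frame(plant_id = agg$plant_id, day = agg$day,
                    r_mean = agg$x[, 1], n_samples = agg$x[, 2],
                    stringsAsFactors = FALSE)
  out$incomplete <- out$n_samples < min_coverage * expected
  if ("group" %in% names(response)) {
    map <- unique(response[, c("plant_id", "group")])
    out$group <- map$group[match(out$plant_id, map$plant_id)]
  }
  if (all(out$incomplete)) stop("no complete day in the response series")
  if (!keep_incomplete) out <- out[!out$incomplete, , drop = FALSE]
  out <- out[order(out$plant_id, out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalized response NR: stressed over control group means
#'
#' NR on day d is the ratio of the stressed-group mean daily R to the
#' control-group mean daily R. Days where the control mean lies within
#' `control_floor` of zero are masked with a warning.
#'
#' @param stressed,control data.frames of per-plant daily means
#'   ([daily_mean()] output restricted to one group each).
#' @param control_floor |control mean| below which a day is masked.
#' @return data.frame `day, nr, n_stressed, n_control`.
#' @export
normalize_nr <- function(stressed, control, control_floor = 1e-6) {
  gm <- function(df) {
    a <- aggregate(df$r_mean, by = list(day = df$day),
                   FUN = function(v) c(mean(v), length(v)))
    data.frame(day = a$day, m = a$x[, 1], n = a$x[, 2])
  }
  s <- gm(stressed); c0 <- gm(control)
  days <- intersect(s$day, c0$day)
  if (!length(days)) stop("stressed and control series share no days")
  s <- s[match(days, s$day), ]; c0 <- c0[match(days, c0$day), ]
  masked <- abs(c0$m) < control_floor
  if (any(masked)) {
    warning(sum(masked), " day(s) masked: control mean response within ",
            control_floor, " of zero")
  }
  out <- data.frame(day = days, nr = ifelse(masked, NA_real_, s$m / c0$m),
                    n_stressed = s$n, n_control = c0$n)
  out <- out[order(out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sub-daily NR series (group response ratio per timestamp)
#'
#' Used by onset detection: the diurnal modulation is common to both groups
#' and cancels in the ratio.
#'
#' @param response [compute_response()] output with a `group` column.
#' @param control_floor |control mean| below which a timestamp is dropped.
#' @return data.frame `time_min, nr`.
#' @export
response_ratio_series <- function(response, control_floor = 1e-6) {
  if (!"group" %in% names(response)) stop("response needs a 'group' column")
  sp <- split(response, response$group)
  if (!all(c("stressed", "control") %in% names(sp))) {
    stop("response must contain both 'stressed' and 'control' groups")
  }
  gm <- function(df) {
    a <- aggregate(df$r, by = list(time_min = df$time_min), FUN = mean)
    names(a)[2] <- "m"; a
  }
  s <- gm(sp$stressed); c0 <- gm(sp$control)
  t0 <- intersect(s$time_min, c0$time_min)
  s <- s[match(t0, s$time_min), ]; c0 <- c0[match(t0, c0$time_min), ]
  keep <- abs(c0$m) >= control_floor
  data.frame(time_min = t0[keep], nr = s$m[keep] / c0$m[keep])
}

# --- continuous piecewise-linear fitting -----------------------------------

# Design matrix for a continuous piecewise-linear model with given breaks.
pwlin_matrix <- function(x, breaks) {
  X <- cbind(1, x)
  for (b in breaks) X <- cbind(X, pmax(x - b, 0))
  X
}

pwlin_rss <- function(x, y, breaks) {
  f <- stats::lm.fit(pwlin_matrix(x, breaks), y)
  sum(f$residuals^2)
}

# Candidate integer breakpoints: at least min_seg points on each side.
pwlin_candidates <- function(x, min_seg = 2L) {
  lo <- ceiling(min(x)); hi <- floor(max(x))
  cand <- lo:hi
  cand[vapply(cand, function(b) sum(x <= b) >= min_seg && sum(x > b) >= min_seg,
              logical(1))]
}

# Best integer breakpoints for fixed k by exhaustive search (min RSS).
pwlin_best_k <- function(x, y, k, min_sep = 2L) {
  cand <- pwlin_candidates(x)
  if (k == 0L) return(list(breaks = numeric(0), rss = pwlin_rss(x, y, numeric(0))))
  if (length(cand) < k) return(NULL)
  combos <- utils::combn(cand, k)
  ok <- if (k == 1L) rep(TRUE, ncol(combos)) else {
    apply(combos, 2, function(b) all(diff(b) >= min_sep))
  }
  combos <- combos[, ok, drop = FALSE]
  if (!ncol(combos)) return(NULL)
  rss <- apply(combos, 2, function(b) pwlin_rss(x, y, b))
  i <- which.min(rss)
  list(breaks = combos[, i], rss = rss[i])
}

#' Segment a daily NR series into drought phases
#'
#' Fits a continuous piecewise-linear model to NR vs day, choosing the
#' breakpoints by exhaustive search over integer days for each number of
#' breaks k and the value of k (0..`k_max`) by BIC. The fitted segments are
#' then labelled against the design's phase template: a segment is assigned
#' the template phase containing its midpoint, except that a positive-slope
#' segment lying strictly inside the drought window is labelled `DA`
#' (drought avoidance).
#'
#' @param nr data.frame `day, nr` ([normalize_nr()] output; `NA` days are
#'   dropped).
#' @param design the `experiment_design`.
#' @param k_max maximum number of breakpoints.
#' @param min_sep minimum spacing between breakpoints (days).
#' @return list of class `phase_segmentation`: `segments` (data.frame
#'   `label, start_day, end_day, slope`), `breakpoints`, `k`, `bic` (vector
#'   over k), `fitted` function.
#' @export
segment_phases <- function(nr, design, k_max = 5L, min_sep = 2L) {
  d <- nr[is.finite(nr$nr), , drop = FALSE]
  x <- as.numeric(d$day); y <- d$nr
  n <- length(x)
  if (n < 6) stop("need at least 6 days of NR to segment phases")
  k_max <- min(k_max, max(0L, floor(n / min_sep) - 2L))
  fits <- vector("list", k_max + 1L)
  bic <- rep(NA_real_, k_max + 1L)
  for (k in 0:k_max) {
    f <- pwlin_best_k(x, y, k, min_sep)
    if (is.null(f)) next
    fits[[k + 1L]] <- f
    p <- 2 * k + 2  # slopes/intercept plus the break locations
    bic[k + 1L] <- n * log(max(f$rss, 1e-10) / n) + p * log(n)
  }
  k_best <- which.min(bic) - 1L
  best <- fits[[k_best + 1L]]
  coefs <- stats::lm.fit(pwlin_matrix(x, best$breaks), y)$coefficients
  slopes <- cumsum(coefs[-1])  # slope within each segment
  bounds <- c(min(x), best$breaks, max(x) + 1)
  tmpl <- phase_label_template(design)
  dd <- drought_days(design)
  w_lo <- if (length(dd)) dd[1L] else NA
  w_hi <- if (length(dd)) dd[length(dd)] + 1L else NA
  labs <- character(length(slopes))
  for (i in seq_along(slopes)) {
    a <- bounds[i]; b <- bounds[i + 1L]; mid <- (a + b) / 2
    hit <- tmpl$label[!is.na(tmpl$start_day) &
                        tmpl$start_day <= mid & mid < tmpl$end_day]
    labs[i] <- if (length(hit)) hit[1L] else "PI"
    if (!is.na(w_lo) && slopes[i] > 0.01 && a > w_lo && b < w_hi) labs[i] <- "DA"
  }
  segs <- data.frame(label = labs, start_day = bounds[-length(bounds)],
                     end_day = bounds[-1L], slope = unname(slopes),
                     stringsAsFactors = FALSE)
  structure(list(segments = segs, breakpoints = unname(best$breaks),
                 k = k_best, bic = bic, template = tmpl,
                 fitted = function(xx) drop(pwlin_matrix(xx, best$breaks) %*% coefs)),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf("<phase_segmentation> k = %d breakpoint(s): %s\n", x$k,
              paste(round(x$breakpoints, 2), collapse = ", ")))
  print(x$segments)
  invisible(x)
}

#' Detect drought-stress onset from the NR series
#'
#' Scans forward from the first water-withholding day: at each grid time t,
#' the slope of NR over the trailing window `[t - window_h, t]` is tested
#' one-sided against zero using the pre-stress residual standard deviation
#' (estimated from the 24 h before stress start). `alpha` is controlled over
#' the whole scan: the per-window threshold is Bonferroni-split across the
#' number of grid points tested (conservative under the strong overlap
#' between neighbouring windows). The first significantly negative slope
#' defines the onset.
#'
#' @param nr data.frame `time_min, nr` (sub-daily, from
#'   [response_ratio_series()]) or `day, nr` (daily; day midpoints are used).
#' @param design the `experiment_design`.
#' @param window_h trailing-window length, hours.
#' @param alpha family-wise one-sided significance level for the 72 h scan.
#' @param horizon_h scan horizon after stress start, hours.
#' @return list `detected, onset_h, window_slope` (NR/day), `p_slope`.
#' @export
detect_onset <- function(nr, design, window_h = 12, alpha = 0.05,
                         horizon_h = 72) {
  if (!"time_min" %in% names(nr)) {
    nr <- data.frame(time_min = nr$day * 1440 + 720, nr = nr$nr)
  }
  nr <- nr[is.finite(nr$nr), , drop = FALSE]
  nr <- nr[order(nr$time_min), , drop = FALSE]
  s0 <- stress_start_day(design)
  if (is.na(s0)) stop("design has no drought block")
  s0m <- s0 * 1440
  pre <- nr$nr[nr$time_min >= s0m - 3 * 1440 & nr$time_min < s0m]
  if (length(pre) < 3 || min(nr$time_min) > s0m - 1440 + 1) {
    stop("insufficient pre-stress baseline (need the 24 h before stress start)")
  }
  sigma <- max(stats::sd(pre), 1e-8)
  grid <- nr$time_min[nr$time_min >= s0m & nr$time_min <= s0m + horizon_h * 60]
  thr <- alpha / max(1, length(grid))
  for (t in grid) {
    sel <- nr$time_min > t - window_h * 60 & nr$time_min <= t
    if (sum(sel) < 3) next
    x <- nr$time_min[sel] / 60; y <- nr$nr[sel]
    sxx <- sum((x - mean(x))^2)
    if (sxx <= 0) next
    b <- sum((x - mean(x)) * (y - mean(y))) / sxx
    p <- stats::pnorm(b / (sigma / sqrt(sxx)))
    if (p < thr) {
      return(list(detected = TRUE, onset_h = (t - s0m) / 60,
                  window_slope = b * 24, p_slope = p))
    }
  }
  list(detected = FALSE, onset_h = NA_real_, window_slope = NA_real_,
       p_slope = NA_real_)
}

#' Post-rewatering recovery deficit
#'
#' Ratio of the mean NR over the recovery (PIII) plateau to the mean NR over
#' the post-implantation baseline (PI). Values below 1 indicate incomplete
#' recovery (irreversible damage). The first `transition_d` days of PIII are
#' excluded as the rewatering transient when PIII is long enough.
#'
#' When the fitted segments do not isolate a PI or PIII segment (e.g. a
#' one-day PI absorbed into the first fitted segment), the design's phase
#' template windows stored in the segmentation are used instead.
#'
#' @param nr data.frame `day, nr`.
#' @param segmentation a `phase_segmentation` whose labels (or template)
#'   include PI and PIII.
#' @param transition_d days of PIII discarded as transient.
#' @return scalar ratio.
#' @export
recovery_deficit <- function(nr, segmentation, transition_d = 2) {
  segs <- segmentation$segments
  win <- function(lab) {
    s <- segs[segs$label == lab, , drop = FALSE]
    if (!nrow(s)) {
      s <- segmentation$template
      s <- s[s$label == lab & !is.na(s$start_day), , drop = FALSE]
    }
    if (!nrow(s)) stop("segmentation has no ", lab, " segment")
    c(min(s$start_day), max(s$end_day))
  }
  pi_w <- win("PI"); piii_w <- win("PIII")
  lo <- if (diff(piii_w) > transition_d + 1) piii_w[1] + transition_d else piii_w[1]
  pi_v <- nr$nr[nr$day >= pi_w[1] & nr$day < pi_w[2]]
  piii_v <- nr$nr[nr$day >= lo & nr$day < piii_w[2]]
  if (!length(pi_v) || !length(piii_v)) stop("no NR days inside PI or PIII")
  mean(piii_v, na.rm = TRUE) / mean(pi_v, na.rm = TRUE)
}
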