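# Small design/config fixtures and independent oracles used across tests.

tiny_design <- function(duration_days = 10L, stress_start = 2L,
                        rewater = 7L, photoperiod_h = 12,
                        sampling_interval_min = 60) {
  stressed <- rep("FULL", duration_days)
  rewater <- min(rewater, duration_days)
  stressed[(stress_start + 1):rewater] <- "WITHHELD"
  if (rewater < duration_days) {
    stressed[(rewater + 1):duration_days] <- "REWATERED"
  }
  build_design(preset = NULL, duration_days = duration_days,
               photoperiod_h = photoperiod_h,
               sampling_interval_min = sampling_interval_min,
               control_schedule = rep("FULL", duration_days),
               stressed_schedule = stressed,
               imaging_days = seq(0L, duration_days - 1L, by = 2L),
               physio_days = seq(0L, duration_days - 1L, by = 2L))
}

tiny_config <- function(seed = 1L, ...) {
  generator_config(seed = seed, n_per_group = 2L, image_size = 64L, ...)
}

# mask helper: build a logical matrix from (row, col) pixel coordinates
px_mask <- function(coords, nrow = 10L, ncol = 10L) {
  m <- matrix(FALSE, nrow, ncol)
  m[coords] <- TRUE
  m
}

# --- independent convex-hull oracle (Andrew monotone chain + edge signs) ---

oracle_hull_area <- function(mask, step = 0.01) {
  idx <- which(mask, arr.ind = TRUE)
  r <- idx[, 1]; c <- idx[, 2]
  pts <- unique(cbind(c(c - 0.5, c + 0.5, c + 0.5, c - 0.5),
                      c(r - 0.5, r - 0.5, r + 0.5, r + 0.5)))
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  half <- function(p) {
    h <- list()
    for (i in seq_len(nrow(p))) {
      while (length(h) >= 2 &&
             cross(h[[length(h) - 1]], h[[length(h)]], p[i, ]) <= 0) {
        h[[length(h)]] <- NULL
      }
      h[[length(h) + 1]] <- p[i, ]
    }
    h
  }
  lower <- half(pts)
  upper <- half(pts[rev(seq_len(nrow(pts))), , drop = FALSE])
  hull <- do.call(rbind, c(lower[-length(lower)], upper[-length(upper)]))
  # area by fine-grid counting of points inside all hull edges
  gx <- seq(min(pts[, 1]), max(pts[, 1]), by = step)
  gy <- seq(min(pts[, 2]), max(pts[, 2]), by = step)
  gg <- expand.grid(x = gx, y = gy)
  inside <- rep(TRUE, nrow(gg))
  n <- nrow(hull)
  for (i in seq_len(n)) {
    a <- hull[i, ]; b <- hull[i %% n + 1, ]
    s <- (b[1] - a[1]) * (gg$y - a[2]) - (b[2] - a[2]) * (gg$x - a[1])
    inside <- inside & s >= -1e-9
  }
  mean(inside) * diff(range(gx)) * diff(range(gy))
}

# --- independent piecewise-linear oracle (explicit lm over all break sets) --

oracle_segment <- function(x, y, k_max = 3, min_sep = 2) {
  cand <- Filter(function(b) sum(x <= b) >= 2 && sum(x > b) >= 2,
                 ceiling(min(x)):floor(max(x)))
  fit_rss <- function(breaks) {
    df <- data.frame(x = x, y = y)
    form <- "y ~ x"
    for (j in seq_along(breaks)) {
      df[[paste0("h", j)]] <- pmax(x - breaks[j], 0)
      form <- paste0(form, " + h", j)
    }
    sum(residuals(lm(as.formula(form), data = df))^2)
  }
  n <- length(x)
  best <- list(k = 0L, breaks = numeric(0), rss = fit_rss(numeric(0)))
  best_bic <- n * log(max(best$rss, 1e-10) / n) + 2 * log(n)
  for (k in seq_len(min(k_max, length(cand)))) {
    combos <- combn(cand, k)
    keep <- if (k == 1) rep(TRUE, ncol(combos)) else
      apply(combos, 2, function(b) all(diff(b) >= min_sep))
    combos <- combos[, keep, drop = FALSE]
    if (!ncol(combos)) next
    rss <- apply(combos, 2, fit_rss)
    i <- which.min(rss)
    bic <- n * log(max(rss[i], 1e-10) / n) + (2 * k + 2) * log(n)
    if (bic < best_bic - 1e-9) {
      best <- list(k = k, breaks = combos[, i], rss = rss[i])
      best_bic <- bic
    }
  }
  best
}

# 17 small polyominoes (4- and 5-pixel) as row/col offsets
polyominoes <- local({
  sh <- list(
    I4 = rbind(c(1,1), c(1,2), c(1,3), c(1,4)),
    O4 = rbind(c(1,1), c(1,2), c(2,1), c(2,2)),
    T4 = rbind(c(1,1), c(1,2), c(1,3), c(2,2)),
    S4 = rbind(c(1,2), c(1,3), c(2,1), c(2,2)),
    L4 = rbind(c(1,1), c(2,1), c(3,1), c(3,2)),
    F5 = rbind(c(1,2), c(1,3), c(2,1), c(2,2), c(3,2)),
    I5 = rbind(c(1,1), c(1,2), c(1,3), c(1,4), c(1,5)),
    L5 = rbind(c(1,1), c(2,1), c(3,1), c(4,1), c(4,2)),
    N5 = rbind(c(1,2), c(2,2), c(3,1), c(3,2), c(4,1)),
    P5 = rbind(c(1,1), c(1,2), c(2,1), c(2,2), c(3,1)),
    T5 = rbind(c(1,1), c(1,2), c(1,3), c(2,2), c(3,2)),
    U5 = rbind(c(1,1), c(1,3), c(2,1), c(2,2), c(2,3)),
    V5 = rbind(c(1,1), c(2,1), c(3,1), c(3,2), c(3,3)),
    W5 = rbind(c(1,1), c(2,1), c(2,2), c(3,2), c(3,3)),
    X5 = rbind(c(1,2), c(2,1), c(2,2), c(2,3), c(3,2)),
    Y5 = rbind(c(1,2), c(2,1), c(2,2), c(3,2), c(4,2)),
    Z5 = rbind(c(1,1), c(1,2), c(2,2), c(3,2), c(3,3))
  )
  lapply(sh, function(m) px_mask(m + 2L, 9L, 9L))
})

# plain rgb image of one uniform hue block on blue background
hue_patch_image <- function(hue_deg, S = 20L, rows = 5:15, cols = 5:15,
                            s = 0.8, v = 0.7) {
  col <- drop(grDevices::col2rgb(grDevices::hsv(hue_deg / 360, s, v))) / 255
  bgc <- drop(grDevices::col2rgb(grDevices::hsv(225 / 360, 0.55, 0.75))) / 255
  img <- array(0, dim = c(S, S, 3))
  for (ch in 1:3) img[, , ch] <- bgc[ch]
  for (ch in 1:3) img[rows, cols, ch] <- col[ch]
  img
}
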