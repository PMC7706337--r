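# Parametric plant renderer: stem + elliptical leaves on a uniform mid-blue
# background, three views (side 0/90 degrees, top), RGB + NIR modalities.
# Rendering is fully deterministic given the latent state, so seeded runs
# produce byte-identical PNGs.

plant_palette <- function() {
  to_rgb <- function(h, s, v) drop(grDevices::col2rgb(grDevices::hsv(h / 360, s, v))) / 255
  list(green = to_rgb(120, 0.65, 0.55),
       yellow = to_rgb(50, 0.80, 0.80),
       background = to_rgb(225, 0.55, 0.75),
       nir_background = 12 / 255)
}

# --- scene construction ----------------------------------------------------

# A scene is a list of shapes: rect (x0,x1,y0,y1) or ellipse
# (cx, cy, a, b, theta). Coordinates: x = column, y = row, row 1 = image top.

side_scene <- function(biomass, height, turgor, image_size) {
  S <- image_size
  H <- max(4, min(round(height), S - 2))
  w <- max(2, round(0.02 * S))
  cx <- S / 2
  stem <- list(type = "rect", x0 = cx - w / 2, x1 = cx + w / 2,
               y0 = S - H + 1, y1 = S)
  stem_area <- w * H
  n_leaves <- 6L
  a1 <- max(12, (biomass - stem_area) / n_leaves)
  # uneven leaf sizes (older leaves larger), total area preserved
  wts <- c(1.3, 1.2, 1.1, 1.0, 0.8, 0.6)
  aspect <- 2.6
  theta <- (10 + 50 * (1 - turgor)) * pi / 180  # droop below horizontal
  fr <- seq(0.33, 0.95, length.out = n_leaves)
  shapes <- list(stem)
  for (i in seq_len(n_leaves)) {
    side <- if (i %% 2 == 0) 1 else -1
    bb <- sqrt(a1 * wts[i] / (pi * aspect)); aa <- aspect * bb
    y_att <- S - fr[i] * H
    cx_l <- cx + side * (w / 2 + 0.9 * aa * cos(theta))
    cy_l <- y_att + aa * sin(theta)
    shapes[[length(shapes) + 1L]] <- list(
      type = "ellipse", cx = cx_l, cy = cy_l, a = aa, b = bb,
      theta = side * (-theta))
  }
  shapes
}

top_scene <- function(biomass, turgor, image_size) {
  S <- image_size
  cx <- S / 2; cy <- S / 2
  reach <- 0.852 * sqrt(biomass) * (0.55 + 0.45 * turgor)
  reach <- min(reach, 0.48 * S)
  a <- 0.45 * reach
  area_top <- 0.8 * biomass
  # central crown disk keeps the rosette one connected component
  r_disk <- 0.22 * reach
  b <- max(1, (area_top - pi * r_disk^2) / (8 * pi * a))
  shapes <- list(list(type = "ellipse", cx = cx, cy = cy, a = r_disk,
                      b = r_disk, theta = 0))
  for (k in 0:7) {
    ang <- k * pi / 4 + pi / 16
    shapes[[k + 2L]] <- list(
      type = "ellipse", cx = cx + 0.55 * reach * cos(ang),
      cy = cy + 0.55 * reach * sin(ang), a = a, b = b, theta = ang)
  }
  shapes
}

# Rasterize a scene onto an S x S logical mask (pixel-center rule).
rasterize_scene <- function(shapes, image_size) {
  S <- image_size
  xs <- matrix(rep(seq_len(S), each = S), nrow = S)   # column index
  ys <- matrix(rep(seq_len(S), times = S), nrow = S)  # row index
  mask <- matrix(FALSE, S, S)
  for (sh in shapes) {
    if (sh$type == "rect") {
      m <- xs >= sh$x0 & xs <= sh$x1 & ys >= sh$y0 & ys <= sh$y1
    } else {
      dx <- xs - sh$cx; dy <- ys - sh$cy
      u <- dx * cos(sh$theta) + dy * sin(sh$theta)
      v <- -dx * sin(sh$theta) + dy * cos(sh$theta)
      m <- (u / sh$a)^2 + (v / sh$b)^2 <= 1
    }
    mask <- mask | m
  }
  mask
}

# Analytic area of a scene ignoring overlaps (used by tests as an oracle).
scene_area <- function(shapes) {
  sum(vapply(shapes, function(sh) {
    if (sh$type == "rect") (sh$x1 - sh$x0) * (sh$y1 - sh$y0) else pi * sh$a * sh$b
  }, numeric(1)))
}

#' Render one view of a plant
#'
#' Draws a parametric plant (vertical stem plus elliptical leaves; a petal
#' rosette in the top view) on a uniform mid-blue background. The side-view
#' plant pixel count scales with the latent projected biomass, vertical
#' extent with the latent height, and leaf droop grows as turgor falls. A
#' fraction `chlorosis_frac` of plant pixels (lowest rows first, emulating
#' older leaves) is coloured in the yellow hue band, the rest in green. NIR
#' leaf intensity is an affine map of hydration:
#' intensity = 40 + 180 x hydration (8-bit).
#'
#' @param biomass target side-view plant pixel area.
#' @param height plant height in pixels.
#' @param turgor turgor state in `[0, 1]`.
#' @param chlorosis_frac fraction of chlorotic (yellow) plant pixels.
#' @param hydration hydration state in `[0, 1]`.
#' @param view `"side0"`, `"side90"` or `"top"`.
#' @param image_size image side length (pixels, >= 64).
#' @return list with `rgb` (S x S x 3 array in `[0,1]`), `nir` (S x S matrix
#'   in `[0,1]`) and the ground-truth `mask` (logical).
#' @export
render_view <- function(biomass, height, turgor, chlorosis_frac, hydration,
                        view = c("side0", "side90", "top"), image_size = 128L) {
  view <- match.arg(view)
  if (image_size < 64) stop("image_size must be >= 64")
  shapes <- switch(view,
    side0 = side_scene(biomass, height, turgor, image_size),
    side90 = {
      sh <- side_scene(biomass, height, turgor, image_size)
      lapply(sh, function(s) {  # mirrored aspect for the orthogonal view
        if (s$type == "ellipse") { s$cx <- image_size + 1 - s$cx; s$theta <- -s$theta }
        s
      })
    },
    top = top_scene(biomass, turgor, image_size)
  )
  mask <- rasterize_scene(shapes, image_size)
  pal <- plant_palette()
  S <- image_size
  rgb <- array(0, dim = c(S, S, 3))
  for (ch in 1:3) rgb[, , ch] <- pal$background[ch]
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx)) {
    ord <- order(-idx[, 1], idx[, 2])  # bottom rows first: older leaves yellow
    n_yellow <- round(min(max(chlorosis_frac, 0), 1) * nrow(idx))
    col_of <- matrix(rep(pal$green, each = nrow(idx)), ncol = 3)
    if (n_yellow > 0) {
      col_of[ord[seq_len(n_yellow)], ] <- matrix(rep(pal$yellow, each = n_yellow), ncol = 3)
    }
    for (ch in 1:3) rgb[cbind(idx, ch)] <- col_of[, ch]
  }
  nir <- matrix(pal$nir_background, S, S)
  nir[mask] <- round(40 + 180 * min(max(hydration, 0), 1)) / 255
  list(rgb = rgb, nir = nir, mask = mask)
}

#' Render and write the full multi-view image series
#'
#' For every plant and imaging day of the design, renders the three views in
#' both modalities and writes 8-bit PNGs plus a manifest CSV.
#'
#' @param traj a `plant_trajectories` object.
#' @param out_dir directory for PNGs and `manifest.csv` (created).
#' @param config,design default to those inside `traj`.
#' @return the manifest data.frame
#'   (`plant_id, day, view, modality, path`), invisibly written to
#'   `out_dir/manifest.csv`.
#' @export
render_plant_images <- function(traj, out_dir, config = traj$config,
                                design = traj$design) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); k <- 0L
  for (day in design$imaging_days) {
    st_day <- traj$daily[traj$daily$day == day, , drop = FALSE]
    for (i in seq_len(nrow(st_day))) {
      st <- st_day[i, ]
      for (view in c("side0", "side90", "top")) {
        rv <- render_view(st$biomass, st$height, st$turgor, st$chlorosis_frac,
                          st$hydration, view, config$image_size)
        for (modality in c("rgb", "nir")) {
          fn <- sprintf("%s_d%02d_%s_%s.png", st$plant_id, day, view, modality)
          img <- if (modality == "rgb") rv$rgb else rv$nir
          png::writePNG(img, file.path(out_dir, fn))
          k <- k + 1L
          rows[[k]] <- data.frame(plant_id = st$plant_id, day = day,
                                  view = view, modality = modality, path = fn,
                                  stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
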