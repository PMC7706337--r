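#' Default background / segmentation parameters
#'
#' The synthetic platform uses a uniform mid-blue background; plant material
#' occupies the green-yellow-brown hue range. NIR levels are 8-bit.
#'
#' @param hue_window vegetation hue window in degrees (green, yellow and
#'   brown bands).
#' @param sat_min minimum HSV saturation for a plant pixel.
#' @param nir_level background NIR intensity (0-255).
#' @param nir_margin margin above `nir_level` required for a plant pixel.
#' @return list of segmentation parameters.
#' @export
background_spec <- function(hue_window = c(20, 180), sat_min = 0.25,
                            nir_level = 12, nir_margin = 10) {
  list(hue_window = hue_window, sat_min = sat_min,
       nir_level = nir_level, nir_margin = nir_margin)
}

#' Segment plant pixels in one view
#'
#' RGB images: pixels whose hue lies in the vegetation window and whose
#' saturation exceeds `sat_min` are candidate plant pixels. NIR images:
#' pixels brighter than the stated uniform background level. In both cases
#' only the largest connected component is kept, which removes salt noise.
#'
#' @param img RGB array (S x S x 3, values in `[0,1]`) or NIR matrix
#'   (values in `[0,1]` or 0-255).
#' @param modality `"rgb"` or `"nir"`.
#' @param bg a [background_spec()].
#' @return list of class `plant_mask`: `mask` (logical matrix), `area_px`,
#'   `empty` flag.
#' @export
segment_plant <- function(img, modality = c("rgb", "nir"),
                          bg = background_spec()) {
  modality <- match.arg(modality)
  if (modality == "rgb") {
    if (length(dim(img)) != 3) stop("rgb image must be an S x S x 3 array")
    d <- dim(img)
    hsv <- grDevices::rgb2hsv(rbind(as.vector(img[, , 1]),
                                    as.vector(img[, , 2]),
                                    as.vector(img[, , 3])), maxColorValue = 1)
    hue <- hsv[1, ] * 360
    cand <- hue >= bg$hue_window[1] & hue <= bg$hue_window[2] &
      hsv[2, ] > bg$sat_min
    cand <- matrix(cand, d[1], d[2])
  } else {
    v <- as_8bit(img)
    cand <- v > bg$nir_level + bg$nir_margin
  }
  if (!any(cand)) {
    return(structure(list(mask = cand & FALSE, area_px = 0L, empty = TRUE),
                     class = "plant_mask"))
  }
  lab <- EBImage::bwlabel(cand)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  mask <- lab == keep
  structure(list(mask = mask, area_px = sum(mask), empty = FALSE),
            class = "plant_mask")
}

as_mask_matrix <- function(m) {
  if (inherits(m, "plant_mask")) m$mask else m
}

as_8bit <- function(img) {
  v <- if (max(img) <= 1) img * 255 else img
  round(v)
}

#' Digital biovolume from three view masks
#'
#' \deqn{DB = (A_{side0} + A_{side90} + \log_{10} A_{top}) / 3}
#' where A are plant pixel areas. A missing view yields `NA`; a zero top
#' area sets the log term to 0 (flagged via attribute `top_zero`).
#'
#' @param side0,side90,top plant masks (or pixel areas as scalars).
#' @return biovolume (dimensionless, pixel-based).
#' @export
compute_biovolume <- function(side0, side90, top) {
  area <- function(m) {
    if (is.null(m) || (length(m) == 1 && is.na(m))) return(NA_real_)
    if (is.matrix(m) || inherits(m, "plant_mask")) sum(as_mask_matrix(m)) else as.numeric(m)
  }
  a0 <- area(side0); a90 <- area(side90); at <- area(top)
  if (anyNA(c(a0, a90, at))) return(NA_real_)
  top_zero <- at == 0
  logterm <- if (top_zero) 0 else log10(at)
  structure((a0 + a90 + logterm) / 3, top_zero = top_zero)
}

#' Plant height in pixel rows
#'
#' Per side view the height is the occupied row extent
#' (lowest - highest occupied row + 1, row 1 at image top); the returned
#' value is the mean over the available side views.
#'
#' @param side0,side90 plant masks; one may be `NULL`/empty.
#' @return height in pixels.
#' @export
compute_height <- function(side0, side90 = NULL) {
  ext <- function(m) {
    if (is.null(m)) return(NA_real_)
    m <- as_mask_matrix(m)
    rows <- which(rowSums(m) > 0)
    if (!length(rows)) return(NA_real_)
    max(rows) - min(rows) + 1
  }
  e <- c(ext(side0), ext(side90))
  e <- e[!is.na(e)]
  if (!length(e)) stop("both side masks are empty")
  mean(e)
}

#' Compactness: plant area over convex-hull area
#'
#' The hull is taken over the polygon union of the pixel squares (each pixel
#' contributes its four corners), so a filled convex region scores exactly 1.
#'
#' @param mask a plant mask.
#' @return compactness in `(0, 1]`.
#' @export
compute_compactness <- function(mask) {
  m <- as_mask_matrix(mask)
  idx <- which(m, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask")
  r <- idx[, 1]; c <- idx[, 2]
  px <- c(c - 0.5, c + 0.5, c + 0.5, c - 0.5)
  py <- c(r - 0.5, r - 0.5, r + 0.5, r + 0.5)
  pts <- unique(cbind(px, py))
  h <- grDevices::chull(pts)
  hx <- pts[h, 1]; hy <- pts[h, 2]
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  nrow(idx) / hull_area
}

#' Green index: fraction of plant pixels in the green hue band
#'
#' @param rgb RGB array (S x S x 3, `[0,1]`).
#' @param mask a plant mask.
#' @param window green hue window in degrees.
#' @return fraction in `[0, 1]`.
#' @export
compute_green_index <- function(rgb, mask, window = c(60, 180)) {
  m <- as_mask_matrix(mask)
  if (!any(m)) stop("empty mask")
  pix <- rbind(rgb[, , 1][m], rgb[, , 2][m], rgb[, , 3][m])
  hue <- grDevices::rgb2hsv(pix, maxColorValue = 1)[1, ] * 360
  mean(hue >= window[1] & hue <= window[2])
}

#' NIR hydration index: 128-bin weighted mean intensity
#'
#' Plant-pixel intensities are histogrammed into 128 equal bins over
#' `[0, 256)` and the index is the bin-count-weighted mean of the bin
#' centers. Equals the plain mean intensity to within half a bin width (1).
#'
#' @param nir NIR image (matrix, `[0,1]` or 0-255).
#' @param mask a plant mask.
#' @return index in intensity units (0-255 scale).
#' @export
compute_nir_index <- function(nir, mask) {
  m <- as_mask_matrix(mask)
  if (!any(m)) stop("empty mask")
  v <- as_8bit(nir)[m]
  v <- pmin(v, 255)
  centers <- 2 * floor(v / 2) + 1  # bin width 256/128 = 2
  mean(centers)
}

#' All five phenotyping indices for one plant image set
#'
#' Segments every view and computes digital biovolume, height, compactness
#' (top view by default), green index (pooled over RGB views) and NIR index
#' (pooled over NIR views, area-weighted). Views with empty masks yield
#' missing fields, never silent zeros.
#'
#' @param image_set list with elements `rgb` and `nir`, each a list with
#'   `side0`, `side90`, `top` image arrays, plus `plant_id` and `day`.
#' @param bg a [background_spec()].
#' @param compactness_view view used for compactness.
#' @param green_window green hue window (degrees).
#' @return one-row data.frame `plant_id, day, biovolume, height_px,
#'   compactness, green_index, nir_index`.
#' @export
extract_indices <- function(image_set, bg = background_spec(),
                            compactness_view = "top",
                            green_window = c(60, 180)) {
  masks_rgb <- lapply(image_set$rgb, segment_plant, modality = "rgb", bg = bg)
  masks_nir <- lapply(image_set$nir, segment_plant, modality = "nir", bg = bg)
  if (all(vapply(masks_rgb, `[[`, logical(1), "empty"))) {
    stop("all views empty for plant ", image_set$plant_id)
  }
  a <- function(mk) if (mk$empty) NA_real_ else mk$area_px
  bio <- compute_biovolume(a(masks_rgb$side0), a(masks_rgb$side90),
                           a(masks_rgb$top))
  hgt <- tryCatch(
    compute_height(if (masks_rgb$side0$empty) NULL else masks_rgb$side0,
                   if (masks_rgb$side90$empty) NULL else masks_rgb$side90),
    error = function(e) NA_real_)
  cmp <- if (masks_rgb[[compactness_view]]$empty) NA_real_ else
    compute_compactness(masks_rgb[[compactness_view]])
  gi_num <- 0; gi_den <- 0
  for (v in names(masks_rgb)) {
    mk <- masks_rgb[[v]]
    if (mk$empty) next
    gi_num <- gi_num + compute_green_index(image_set$rgb[[v]], mk, green_window) * mk$area_px
    gi_den <- gi_den + mk$area_px
  }
  ni_num <- 0; ni_den <- 0
  for (v in names(masks_nir)) {
    mk <- masks_nir[[v]]
    if (mk$empty) next
    ni_num <- ni_num + compute_nir_index(image_set$nir[[v]], mk) * mk$area_px
    ni_den <- ni_den + mk$area_px
  }
  data.frame(plant_id = image_set$plant_id, day = image_set$day,
             biovolume = as.numeric(bio), height_px = hgt,
             compactness = cmp,
             green_index = if (gi_den > 0) gi_num / gi_den else NA_real_,
             nir_index = if (ni_den > 0) ni_num / ni_den else NA_real_,
             stringsAsFactors = FALSE)
}

#' Compute indices for every image set in a manifest
#'
#' @param manifest data.frame `plant_id, day, view, modality, path` (paths
#'   relative to `dir`).
#' @param dir directory containing the PNGs.
#' @param ... passed to [extract_indices()].
#' @return data.frame of [extract_indices()] rows for every plant x day.
#' @export
extract_indices_from_manifest <- function(manifest, dir, ...) {
  keys <- unique(manifest[, c("plant_id", "day")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    pid <- keys$plant_id[i]; day <- keys$day[i]
    sub <- manifest[manifest$plant_id == pid & manifest$day == day, ]
    get <- function(modality, view) {
      p <- sub$path[sub$modality == modality & sub$view == view]
      if (!length(p)) return(NULL)
      png::readPNG(file.path(dir, p[1]))
    }
    iset <- list(plant_id = pid, day = day,
                 rgb = list(side0 = get("rgb", "side0"),
                            side90 = get("rgb", "side90"),
                            top = get("rgb", "top")),
                 nir = list(side0 = get("nir", "side0"),
                            side90 = get("nir", "side90"),
                            top = get("nir", "top")))
    extract_indices(iset, ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
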