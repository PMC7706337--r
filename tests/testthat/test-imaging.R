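test_that("digital biovolume follows the three-view expression", {
  expect_equal(as.numeric(compute_biovolume(1000, 1000, 1000)),
               (1000 + 1000 + 3) / 3)
  expect_equal(as.numeric(compute_biovolume(10000, 8000, 10000)),
               (10000 + 8000 + 4) / 3)
  # empty plant: zero sides, single top pixel -> log10(1) = 0
  expect_equal(as.numeric(compute_biovolume(0, 0, 1)), 0)
  # zero top area: log term set to 0 and flagged
  b <- compute_biovolume(100, 100, 0)
  expect_equal(as.numeric(b), 200 / 3)
  expect_true(attr(b, "top_zero"))
  # missing view propagates NA
  expect_true(is.na(compute_biovolume(NA, 100, 100)))
  # strictly increasing in each argument
  base <- as.numeric(compute_biovolume(500, 600, 700))
  expect_gt(as.numeric(compute_biovolume(501, 600, 700)), base)
  expect_gt(as.numeric(compute_biovolume(500, 601, 700)), base)
  expect_gt(as.numeric(compute_biovolume(500, 600, 701)), base)
})

test_that("height is the mean occupied row extent of the side views", {
  m1 <- px_mask(cbind(10:59, 5), 80, 10)
  m2 <- px_mask(cbind(11:70, 5), 80, 10)
  expect_equal(compute_height(m1, m1), 50)
  expect_equal(compute_height(m1, m2), 55)
  expect_equal(compute_height(px_mask(cbind(4, 4), 8, 8)), 1)
  expect_error(compute_height(px_mask(cbind(integer(0), integer(0)), 4, 4),
                              NULL), "empty")
})

test_that("compactness is exact for convex masks and matches the hull oracle", {
  # filled rectangle: exactly 1
  rect <- matrix(FALSE, 10, 10); rect[3:7, 2:9] <- TRUE
  expect_equal(compute_compactness(rect), 1.0)
  # plus-shaped pentomino: 5 px over a hull of area 7 (hand-computed octagon)
  plus <- px_mask(rbind(c(2, 3), c(3, 2), c(3, 3), c(3, 4), c(4, 3)), 6, 6)
  expect_equal(compute_compactness(plus), 5 / 7)
  expect_equal(compute_compactness(plus), 5 / oracle_hull_area(plus),
               tolerance = 5e-3)
  expect_error(compute_compactness(matrix(FALSE, 4, 4)), "empty")
})

test_that("compactness equals the independent hull oracle on all polyominoes", {
  for (nm in names(polyominoes)) {
    m <- polyominoes[[nm]]
    cmp <- compute_compactness(m)
    expect_lte(cmp, 1 + 1e-9)
    expect_equal(cmp, sum(m) / oracle_hull_area(m), tolerance = 5e-3,
                 label = paste("polyomino", nm))
    # convex polyominoes (solid rectangles) score exactly 1
    idx <- which(m, arr.ind = TRUE)
    is_rect <- sum(m) == (diff(range(idx[, 1])) + 1) * (diff(range(idx[, 2])) + 1)
    if (is_rect) expect_equal(cmp, 1.0, label = paste("convex", nm))
  }
})

test_that("a filled disk is more compact than an equal-area ring", {
  S <- 41L
  xs <- matrix(rep(1:S, each = S), S); ys <- t(xs)
  rr <- sqrt((xs - 21)^2 + (ys - 21)^2)
  disk <- rr <= 10
  ring <- rr <= 16 & rr >= 12.6  # approximately the same pixel area
  expect_equal(sum(ring) / sum(disk), 1, tolerance = 0.1)
  expect_gt(compute_compactness(disk), compute_compactness(ring))
})

test_that("green index counts plant pixels in the green hue window", {
  mask <- matrix(TRUE, 20, 20)
  expect_equal(compute_green_index(hue_patch_image(120, rows = 1:20, cols = 1:20),
                                   mask), 1.0)
  expect_equal(compute_green_index(hue_patch_image(50, rows = 1:20, cols = 1:20),
                                   mask), 0.0)   # yellow, outside [60, 180]
  expect_equal(compute_green_index(hue_patch_image(20, rows = 1:20, cols = 1:20),
                                   mask), 0.0)   # brown/necrotic
  # window edges are configurable
  expect_equal(compute_green_index(hue_patch_image(50, rows = 1:20, cols = 1:20),
                                   mask, window = c(40, 180)), 1.0)
  expect_error(compute_green_index(hue_patch_image(120), matrix(FALSE, 20, 20)),
               "empty")
})

test_that("NIR index is the 128-bin weighted mean of plant intensities", {
  m <- matrix(TRUE, 4, 4)
  expect_equal(compute_nir_index(matrix(128, 4, 4), m), 129) # bin [128,130)
  half <- matrix(c(rep(0, 8), rep(254, 8)), 4, 4)
  expect_equal(compute_nir_index(half, m), 128)              # (1 + 255)/2
  expect_error(compute_nir_index(matrix(128, 4, 4), matrix(FALSE, 4, 4)),
               "empty")
  # binning bound: within half a bin width of the plain mean, any image
  set.seed(7)
  for (i in 1:20) {
    img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    msk <- matrix(sample(c(TRUE, FALSE), 64, replace = TRUE, prob = c(0.7, 0.3)), 8, 8)
    if (!any(msk)) next
    expect_lte(abs(compute_nir_index(img, msk) - mean(img[msk])), 1)
  }
})

test_that("index extraction recovers programmed gradients from renders", {
  # green index tracks 1 - chlorosis and NIR tracks hydration over a gradient
  grad <- seq(0, 0.9, length.out = 10)
  gi <- ni <- numeric(10)
  for (i in seq_along(grad)) {
    rv <- lapply(c(side0 = "side0", side90 = "side90", top = "top"),
                 function(v) render_view(1200, 90, 0.9, grad[i],
                                         1 - grad[i] * 0.8, v, 96L))
    iset <- list(plant_id = "p", day = i, rgb = lapply(rv, `[[`, "rgb"),
                 nir = lapply(rv, `[[`, "nir"))
    z <- extract_indices(iset)
    gi[i] <- z$green_index; ni[i] <- z$nir_index
  }
  expect_gte(cor(gi, 1 - grad, method = "spearman"), 0.95)
  expect_gte(cor(ni, 1 - grad * 0.8, method = "spearman"), 0.95)
})

test_that("identical side views give equal heights; stress raises compactness", {
  rv <- render_view(1200, 90, 0.9, 0.1, 0.8, "side0", 96L)
  iset <- list(plant_id = "p", day = 0,
               rgb = list(side0 = rv$rgb, side90 = rv$rgb, top = rv$rgb),
               nir = list(side0 = rv$nir, side90 = rv$nir, top = rv$nir))
  z <- extract_indices(iset, compactness_view = "side0")
  mk <- segment_plant(rv$rgb, "rgb")
  expect_equal(z$height_px, compute_height(mk, mk))
  # wilting (falling turgor) raises top-view compactness
  c_high <- compute_compactness(segment_plant(
    render_view(1500, 90, 1, 0, 0.8, "top", 96L)$rgb, "rgb"))
  c_low <- compute_compactness(segment_plant(
    render_view(1500, 90, 0.55, 0, 0.8, "top", 96L)$rgb, "rgb"))
  expect_gt(c_low, c_high)
})
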