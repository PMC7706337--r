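test_that("segmentation recovers the renderer's ground-truth mask", {
  rv <- render_view(biomass = 1200, height = 90, turgor = 0.9,
                    chlorosis_frac = 0.2, hydration = 0.8, "side0", 128L)
  for (modality in c("rgb", "nir")) {
    mk <- segment_plant(if (modality == "rgb") rv$rgb else rv$nir, modality)
    inter <- sum(mk$mask & rv$mask)
    union <- sum(mk$mask | rv$mask)
    expect_gte(inter / union, 0.99)
  }
})

test_that("chlorosis fraction controls the yellow/green pixel split", {
  rv0 <- render_view(1500, 100, 1, chlorosis_frac = 0, hydration = 0.8,
                     "side0", 128L)
  mk <- segment_plant(rv0$rgb, "rgb")
  gi <- compute_green_index(rv0$rgb, mk)
  expect_equal(gi, 1.0)  # fully healthy: every plant pixel in the green band
  rv <- render_view(1500, 100, 1, chlorosis_frac = 0.7, hydration = 0.8,
                    "side0", 128L)
  mk <- segment_plant(rv$rgb, "rgb")
  expect_equal(compute_green_index(rv$rgb, mk), 0.3, tolerance = 0.02)
})

test_that("NIR leaf intensity is an affine map of hydration", {
  vals <- seq(0, 1, by = 0.25)
  intens <- vapply(vals, function(h) {
    rv <- render_view(1200, 90, 1, 0, hydration = h, "side0", 128L)
    mean(rv$nir[rv$mask]) * 255
  }, numeric(1))
  expect_equal(intens, 40 + 180 * vals, tolerance = 0.51)  # 8-bit rounding
  expect_true(all(diff(intens) > 0))
})

test_that("rasterized area matches analytic area under similarity scaling", {
  S <- 256L
  sc1 <- phytosense:::side_scene(biomass = 1500, height = 141, turgor = 1, S)
  a1 <- sum(phytosense:::rasterize_scene(sc1, S))
  # similarity-scale every shape by sqrt(2): pixel count should double
  scale_shape <- function(s, f, S) {
    ctr <- S / 2
    if (s$type == "rect") {
      s$x0 <- ctr + (s$x0 - ctr) * f; s$x1 <- ctr + (s$x1 - ctr) * f
      s$y0 <- S - (S - s$y0) * f; s$y1 <- S - (S - s$y1) * f
    } else {
      s$cx <- ctr + (s$cx - ctr) * f; s$cy <- S - (S - s$cy) * f
      s$a <- s$a * f; s$b <- s$b * f
    }
    s
  }
  sc2 <- lapply(sc1, scale_shape, f = sqrt(2), S = S)
  a2 <- sum(phytosense:::rasterize_scene(sc2, S))
  expect_equal(a2 / a1, 2, tolerance = 0.05)
  # and each rasterization is close to its analytic (overlap-free) area
  expect_equal(a1, phytosense:::scene_area(sc1), tolerance = 0.1 * a1)
})

test_that("pure background yields an empty-mask flag", {
  pal <- phytosense:::plant_palette()
  img <- array(0, dim = c(64, 64, 3))
  for (ch in 1:3) img[, , ch] <- pal$background[ch]
  mk <- segment_plant(img, "rgb")
  expect_true(mk$empty)
  expect_equal(mk$area_px, 0L)
})

test_that("salt noise in the plant colour band is removed by the largest component", {
  rv <- render_view(1200, 90, 0.9, 0, 0.8, "side0", 128L)
  img <- rv$rgb
  pal <- phytosense:::plant_palette()
  img[2, 2, ] <- pal$green  # isolated plant-coloured pixel in the corner
  mk <- segment_plant(img, "rgb")
  expect_false(mk$mask[2, 2])
  expect_gte(sum(mk$mask & rv$mask) / sum(mk$mask | rv$mask), 0.99)
})

test_that("written PNG series round-trips and is byte-stable", {
  des <- tiny_design(duration_days = 4L)
  cfg <- tiny_config()
  traj <- simulate_latent_states(cfg, des)
  d1 <- file.path(tempdir(), "imgA"); d2 <- file.path(tempdir(), "imgB")
  m1 <- render_plant_images(traj, d1)
  m2 <- render_plant_images(traj, d2)
  expect_equal(m1$path, m2$path)
  h1 <- unname(tools::md5sum(file.path(d1, m1$path)))
  h2 <- unname(tools::md5sum(file.path(d2, m2$path)))
  expect_identical(h1, h2)
  unlink(c(d1, d2), recursive = TRUE)
})
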