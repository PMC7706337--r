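test_that("pearson reproduces hand-computed correlations", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson(x, x)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  p <- pearson(x, c(1, 3, 2, 4))
  expect_equal(p$r, 0.8)
  expect_equal(p$n, 4)
  expect_error(pearson(x, rep(1, 4)), "variance")
  expect_error(pearson(1:2, 2:1), "at least 3")
})

test_that("correlation matrix is symmetric with unit diagonal", {
  set.seed(1)
  tb <- as.data.frame(matrix(rnorm(60), 10))
  names(tb) <- feature_variables
  tb$GI <- tb$C  # duplicated column pair
  cm <- correlation_matrix(tb)
  expect_equal(diag(cm$r), rep(1, 6), ignore_attr = TRUE)
  expect_equal(cm$r, t(cm$r))
  expect_equal(cm$r["C", "GI"], 1)
  expect_lt(cm$p["C", "GI"], 1e-10)
})

test_that("PCA of the standardized table behaves as the 2x2 closed form predicts", {
  set.seed(2)
  # two perfectly correlated variables: PC1 explains everything
  x <- rnorm(50)
  t2 <- data.frame(C = x, GI = 2 * x + 1)
  pc <- run_pca(t2, vars = c("C", "GI"))
  expect_equal(pc$variance_explained[1], 100, tolerance = 1e-8)
  # two independent equal-variance variables: eigenvalues of the 2x2
  # correlation matrix are 1 +/- r, so PC1 -> ~50% at large n
  t3 <- data.frame(C = rnorm(4000), GI = rnorm(4000))
  pc3 <- run_pca(t3, vars = c("C", "GI"))
  expect_equal(pc3$variance_explained[1], 50, tolerance = 5)
  expect_error(run_pca(data.frame(C = rep(1, 5), GI = rnorm(5)),
                       vars = c("C", "GI")), "constant")
})

test_that("variance explained sums to 100 and loadings are orthonormal", {
  set.seed(3)
  tb <- as.data.frame(matrix(rnorm(120), 20))
  names(tb) <- feature_variables
  pc <- run_pca(tb)
  expect_equal(sum(pc$variance_explained), 100, tolerance = 1e-6)
  expect_equal(crossprod(pc$loadings), diag(6), ignore_attr = TRUE,
               tolerance = 1e-8)
})

test_that("variance explained is invariant to orthogonal rotation", {
  set.seed(4)
  Z <- scale(matrix(rnorm(200 * 4), 200) %*% matrix(runif(16), 4))
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  tb1 <- as.data.frame(Z); names(tb1) <- c("C", "GI", "SC", "R")
  tb2 <- as.data.frame(Z %*% Q); names(tb2) <- names(tb1)
  pc1 <- run_pca(tb1, vars = names(tb1), scale = FALSE)
  pc2 <- run_pca(tb2, vars = names(tb1), scale = FALSE)
  expect_equal(pc1$variance_explained, pc2$variance_explained,
               tolerance = 1e-8)
})

test_that("timepoint tests match the pooled-variance t and F = t^2", {
  long <- data.frame(group = rep(c("control", "stressed"), each = 3),
                     day = 1, variable = "SC", value = c(1, 2, 3, 4, 5, 6))
  tt <- timepoint_tests(long, method = "t_test")
  expect_equal(tt$statistic, -3.674, tolerance = 1e-3)
  expect_equal(tt$p_value, 0.02131, tolerance = 1e-3)
  av <- timepoint_tests(long, method = "anova")
  expect_equal(av$statistic, tt$statistic^2, tolerance = 1e-8)
  expect_equal(av$p_value, tt$p_value, tolerance = 1e-10)
  expect_equal(av$stars, "*")
  # identical groups: zero statistic, no stars
  long0 <- transform(long, value = rep(c(1, 2, 3), 2))
  t0 <- timepoint_tests(long0, method = "t_test")
  expect_equal(t0$statistic, 0)
  expect_equal(t0$stars, "")
})

test_that("star maps translate p values to annotations", {
  m <- star_map("conventional")
  expect_equal(phytosense:::stars_for(c(0.03, 0.004, 5e-5, 0.2), m),
               c("*", "**", "****", ""))
  mi <- star_map("inverted")
  expect_equal(phytosense:::stars_for(c(0.03, 0.004), mi), c("**", "*"))
})

test_that("feature table joins indices, daily response and conductance", {
  idx <- data.frame(plant_id = c("C01", "S01"), day = 2,
                    biovolume = c(800, 700), height_px = c(60, 50),
                    compactness = c(0.4, 0.5), green_index = c(0.9, 0.8),
                    nir_index = c(190, 160))
  daily <- data.frame(plant_id = c("C01", "S01"), day = 2,
                      r_mean = c(-0.5, -0.4),
                      group = c("control", "stressed"))
  physio <- data.frame(plant_id = rep(c("C01", "S01"), each = 2),
                       group = rep(c("control", "stressed"), each = 2),
                       day = 2, measure = "SC", replicate = 1:2,
                       value = c(400, 420, 90, 100))
  ft <- build_feature_table(idx, daily, physio)
  expect_equal(names(ft), c("plant_id", "group", "day", feature_variables))
  expect_equal(ft$R, c(0.5, 0.4))       # response magnitude
  expect_equal(ft$SC, c(410, 95))
  expect_equal(ft$DB, c(800, 700))
})
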