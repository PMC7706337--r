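#' Pearson correlation with t-based p value
#'
#' Thin wrapper around [stats::cor.test()]: sample Pearson r and the
#' two-sided p value from the t transform with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors (n >= 3, finite, non-constant).
#' @return list `r, p, n`.
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' The six integrated phenotype variables
#' @export
feature_variables <- c("C", "GI", "SC", "R", "NI", "DB")

#' Assemble the plant x timepoint feature table
#'
#' Joins image indices, the per-plant daily mean sensor response and
#' stomatal conductance into one table with the six variables used by the
#' integrative analysis: compactness (C), green index (GI), stomatal
#' conductance (SC), sensor response magnitude (R), NIR intensity (NI) and
#' digital biovolume (DB). R enters as |daily mean response| on the nearest
#' sensor day; SC as the plant mean on the nearest physiology day (within
#' `max_day_gap`).
#'
#' @param indices data.frame from [extract_indices_from_manifest()].
#' @param daily data.frame from [daily_mean()] (with `group`).
#' @param physio long physiology table ([sample_physiology()] schema).
#' @param max_day_gap largest allowed |day difference| for the joins.
#' @return data.frame `plant_id, group, day, C, GI, SC, R, NI, DB` with
#'   attribute `n_excluded` (rows dropped for missing values).
#' @export
build_feature_table <- function(indices, daily, physio, max_day_gap = 1) {
  sc <- physio[physio$measure == "SC", ]
  sc_p <- aggregate(value ~ plant_id + day, sc, mean)
  nearest <- function(days_avail, day) {
    if (!length(days_avail)) return(NA_integer_)
    d <- days_avail[which.min(abs(days_avail - day))]
    if (abs(d - day) > max_day_gap) NA_integer_ else d
  }
  rows <- lapply(seq_len(nrow(indices)), function(i) {
    z <- indices[i, ]
    dsub <- daily[daily$plant_id == z$plant_id, ]
    rd <- nearest(dsub$day, z$day)
    r <- if (is.na(rd)) NA_real_ else abs(dsub$r_mean[dsub$day == rd][1])
    ssub <- sc_p[sc_p$plant_id == z$plant_id, ]
    sd_ <- nearest(ssub$day, z$day)
    scv <- if (is.na(sd_)) NA_real_ else ssub$value[ssub$day == sd_][1]
    grp <- if (nrow(dsub)) dsub$group[1] else NA_character_
    data.frame(plant_id = z$plant_id, group = grp, day = z$day,
               C = z$compactness, GI = z$green_index, SC = scv, R = r,
               NI = z$nir_index, DB = z$biovolume, stringsAsFactors = FALSE)
  })
  ft <- do.call(rbind, rows)
  complete <- stats::complete.cases(ft[, feature_variables])
  structure(ft[complete, , drop = FALSE], n_excluded = sum(!complete))
}

#' Pairwise Pearson correlation matrix over the six variables
#'
#' Pairwise-complete rows are used per cell; the per-cell n is reported.
#'
#' @param table a feature table ([build_feature_table()]).
#' @param vars variable columns.
#' @return list `r`, `p`, `n` (symmetric matrices; unit diagonal for r).
#' @export
correlation_matrix <- function(table, vars = feature_variables) {
  k <- length(vars)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) {
    nmat[i, i] <- sum(is.finite(table[[vars[i]]]))
    for (j in seq_len(k)) {
      if (j <= i) next
      pr <- pearson(table[[vars[i]]], table[[vars[j]]])
      r[i, j] <- r[j, i] <- pr$r
      p[i, j] <- p[j, i] <- pr$p
      nmat[i, j] <- nmat[j, i] <- pr$n
    }
  }
  list(r = r, p = p, n = nmat)
}

#' PCA of the standardized feature table
#'
#' Variables are centered and scaled to unit variance (PCA of the
#' correlation matrix; the six variables have incommensurate units). Returns
#' scores, orthonormal loadings, percent variance explained (summing to
#' 100), and scores/loadings scaled for biplot co-plotting.
#'
#' @param table a feature table with complete rows.
#' @param vars variable columns.
#' @param scale scale columns to unit variance (the default; set `FALSE`
#'   only for pre-standardized input).
#' @return list of class `pca_result`: `scores`, `loadings`,
#'   `variance_explained`, `biplot` (list `scores`, `loadings`,
#'   `loading_scale`), `group`.
#' @export
run_pca <- function(table, vars = feature_variables, scale = TRUE) {
  X <- as.matrix(table[, vars])
  if (nrow(X) < 3) stop("need at least 3 complete rows for PCA")
  if (any(apply(X, 2, stats::sd) == 0)) stop("constant column in PCA input")
  pc <- stats::prcomp(X, center = TRUE, scale. = scale)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  sc_scale <- max(abs(pc$x[, 1:2]))
  ld_scale <- max(abs(pc$rotation[, 1:2]))
  structure(list(
    scores = pc$x, loadings = pc$rotation, variance_explained = ve,
    biplot = list(scores = pc$x[, 1:2],
                  loadings = pc$rotation[, 1:2] * sc_scale / ld_scale * 0.8,
                  loading_scale = sc_scale / ld_scale * 0.8),
    group = if ("group" %in% names(table)) table$group else NULL),
    class = "pca_result")
}

#' Star annotation maps
#'
#' `conventional`: * p<=0.05, ** p<=0.01, *** p<=0.001, **** p<=0.0001.
#' `inverted`: ** p<=0.05, * p<=0.01 (as printed in some figure legends;
#' kept as a preset).
#'
#' @param name map name.
#' @return named numeric vector of thresholds (names are the star strings).
#' @export
star_map <- function(name = c("conventional", "inverted")) {
  name <- match.arg(name)
  switch(name,
    conventional = c("****" = 1e-4, "***" = 1e-3, "**" = 1e-2, "*" = 5e-2),
    inverted = c("*" = 1e-2, "**" = 5e-2))
}

stars_for <- function(p, map) {
  vapply(p, function(pp) {
    if (is.na(pp)) return("")
    hit <- names(map)[map >= pp]
    if (!length(hit)) "" else names(which.min(map[hit]))
  }, character(1))
}

#' Per-timepoint two-group tests with star annotation
#'
#' For every day x variable, compares stressed vs control values by a pooled
#' (equal-variance) two-sample t test or a one-way ANOVA; for two groups
#' F = t^2 and the p values agree. P values are reported unadjusted; an
#' optional Benjamini-Hochberg correction is available.
#'
#' @param long data.frame `group, day, variable, value`.
#' @param method `"anova"` or `"t_test"`.
#' @param map a [star_map()].
#' @param adjust apply Benjamini-Hochberg across all tests?
#' @return data.frame `day, variable, statistic, p_value, stars`.
#' @export
timepoint_tests <- function(long, method = c("anova", "t_test"),
                            map = star_map("conventional"), adjust = FALSE) {
  method <- match.arg(method)
  keys <- unique(long[, c("day", "variable")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- long[long$day == keys$day[i] & long$variable == keys$variable[i], ]
    sub <- sub[is.finite(sub$value), ]
    ng <- table(sub$group)
    if (length(ng) < 2 || any(ng < 2)) {
      stop(sprintf("day %s, variable %s: need >= 2 values in each group",
                   keys$day[i], keys$variable[i]))
    }
    gm <- tapply(sub$value, sub$group, mean)
    gsd <- tapply(sub$value, sub$group, stats::sd)
    if (all(gsd < 1e-10 * max(1, abs(gm)))) {
      # degenerate cells: no within-group variance
      if (abs(diff(range(gm))) < 1e-10 * max(1, abs(gm[1]))) {
        stat <- 0; p <- 1           # identical groups
      } else {
        stat <- Inf; p <- 0         # separated point masses
      }
    } else if (method == "t_test") {
      tt <- stats::t.test(value ~ group, data = sub, var.equal = TRUE)
      stat <- unname(tt$statistic); p <- tt$p.value
    } else {
      fit <- stats::aov(value ~ group, data = sub)
      s <- summary(fit)[[1]]
      stat <- s[["F value"]][1]; p <- s[["Pr(>F)"]][1]
    }
    data.frame(day = keys$day[i], variable = keys$variable[i],
               statistic = stat, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_value <- stats::p.adjust(out$p_value, method = "BH")
  out$stars <- stars_for(out$p_value, map)
  rownames(out) <- NULL
  out
}
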