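#' Configuration of the synthetic drought experiment generator
#'
#' The generator emulates the statistical structure of a combined
#' bioristor + imaging + physiology drought experiment: a diurnally
#' oscillating sensor response whose stressed/control ratio (NR) starts to
#' decline within `onset_lag_h` hours of water withholding, a transient
#' "drought avoidance" rebound, a low stable plateau with a small bump at the
#' limited-irrigation day, and partial post-rewatering recovery; image
#' trajectories with reduced growth (15% height deficit by stress day 6,
#' rising compactness, falling NIR hydration index, flattening green index);
#' stomatal conductance reduced `sc_fold_reduction`-fold during peak stress;
#' relative water content reduced by `rwc_drop_frac`; SPAD raised by
#' `spad_stress_shift` under stress.
#'
#' One latent state per plant drives sensor, images and physiology, so
#' cross-modal correlations (R vs SC, R vs biovolume) are emergent, not
#' imposed.
#'
#' @param seed integer RNG seed; a fixed seed gives bit-identical outputs.
#' @param n_per_group plants per group.
#' @param r_baseline pre-stress sensor response (dimensionless, negative).
#' @param diurnal_amplitude fractional amplitude of the day/night R
#'   modulation.
#' @param onset_lag_h hours between water withholding and the start of the
#'   NR decline.
#' @param pii_decline_rate NR units lost per day during the drought decline.
#' @param da_start_day,da_duration_d start (days after stress start) and
#'   length of the drought-avoidance rebound.
#' @param da_rebound_frac fraction of the preceding decline regained during
#'   the rebound.
#' @param nr_plateau low stable NR level reached late in the drought.
#' @param limited_bump NR bump amplitude at the limited-irrigation day.
#' @param recovery_fraction NR level (fraction of the pre-stress baseline)
#'   reached after rewatering; < 1 encodes irreversible damage.
#' @param noise_sd_sensor additive Gaussian noise SD on per-sample R.
#' @param growth_rate 1/day rate constant of the saturating growth curves.
#' @param height_deficit_frac stressed/control height deficit reached by
#'   stress day 5 and held (0.15 = "15% lower").
#' @param biomass_decline_frac fraction of peak projected area lost by
#'   stressed plants during the drought.
#' @param turgor_drop maximum turgor loss (drives leaf droop/compactness).
#' @param hydration_dip_depth maximum drop of the latent hydration state.
#' @param hydration_dip_window absolute-day window `[from, to]` of the dip.
#' @param chlorosis_rate extra chlorosis fraction/day accumulated by stressed
#'   plants (on top of a slow age-related drift common to both groups).
#' @param sc_fold_reduction fold reduction of stomatal conductance at peak
#'   stress (4.5 = mid "4-5-fold").
#' @param rwc_drop_frac relative water content drop at peak stress (0.23).
#' @param spad_stress_shift SPAD units added under stress.
#' @param noise_sd_physio relative replicate noise on SC.
#' @param rwc_noise_sd absolute replicate noise (percent RWC).
#' @param spad_noise_sd absolute replicate noise (SPAD units).
#' @param ion_baseline,ion_half_sat baseline xylem-sap ion concentration and
#'   half-saturation constant of the sensor's saturating log ion response
#'   (mol/L).
#' @param image_size rendered image side length in pixels (>= 64).
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_per_group = 4L,
                             r_baseline = -0.5,
                             diurnal_amplitude = 0.15,
                             onset_lag_h = 30,
                             pii_decline_rate = 0.12,
                             da_start_day = 4,
                             da_duration_d = 2,
                             da_rebound_frac = 0.5,
                             nr_plateau = 0.5,
                             limited_bump = 0.05,
                             recovery_fraction = 0.7,
                             noise_sd_sensor = 0.02,
                             growth_rate = 0.10,
                             height_deficit_frac = 0.15,
                             biomass_decline_frac = 0.4,
                             turgor_drop = 0.45,
                             hydration_dip_depth = 0.3,
                             hydration_dip_window = c(6, 16),
                             chlorosis_rate = 0.02,
                             sc_fold_reduction = 4.5,
                             rwc_drop_frac = 0.23,
                             spad_stress_shift = 5,
                             noise_sd_physio = 0.05,
                             rwc_noise_sd = 1.5,
                             spad_noise_sd = 1.5,
                             ion_baseline = 0.05,
                             ion_half_sat = 0.02,
                             image_size = 128L) {
  cfg <- list(
    seed = as.integer(seed %% .Machine$integer.max),
    n_per_group = as.integer(n_per_group),
    r_baseline = r_baseline, diurnal_amplitude = diurnal_amplitude,
    onset_lag_h = onset_lag_h, pii_decline_rate = pii_decline_rate,
    da_start_day = da_start_day, da_duration_d = da_duration_d,
    da_rebound_frac = da_rebound_frac, nr_plateau = nr_plateau,
    limited_bump = limited_bump, recovery_fraction = recovery_fraction,
    noise_sd_sensor = noise_sd_sensor, growth_rate = growth_rate,
    height_deficit_frac = height_deficit_frac,
    biomass_decline_frac = biomass_decline_frac,
    turgor_drop = turgor_drop,
    hydration_dip_depth = hydration_dip_depth,
    hydration_dip_window = hydration_dip_window,
    chlorosis_rate = chlorosis_rate,
    sc_fold_reduction = sc_fold_reduction,
    rwc_drop_frac = rwc_drop_frac,
    spad_stress_shift = spad_stress_shift,
    noise_sd_physio = noise_sd_physio, rwc_noise_sd = rwc_noise_sd,
    spad_noise_sd = spad_noise_sd,
    ion_baseline = ion_baseline, ion_half_sat = ion_half_sat,
    image_size = as.integer(image_size)
  )
  rates <- c("diurnal_amplitude", "pii_decline_rate", "noise_sd_sensor",
             "growth_rate", "height_deficit_frac", "biomass_decline_frac",
             "turgor_drop", "hydration_dip_depth", "chlorosis_rate",
             "rwc_drop_frac", "spad_stress_shift", "noise_sd_physio",
             "rwc_noise_sd", "spad_noise_sd", "limited_bump")
  for (nm in rates) if (cfg[[nm]] < 0) stop(nm, " must be >= 0")
  if (cfg$recovery_fraction <= 0 || cfg$recovery_fraction >= 1) {
    stop("recovery_fraction must lie in (0, 1)")
  }
  if (cfg$sc_fold_reduction < 1) stop("sc_fold_reduction must be >= 1")
  if (cfg$image_size < 64L) stop("image_size must be >= 64")
  class(cfg) <- "generator_config"
  cfg
}

#' Null-effect generator configuration
#'
#' All stress effects switched off: NR stays at 1, stressed and control
#' plants follow identical trajectories up to noise. Used for false-positive
#' calibration.
#'
#' @param seed integer RNG seed.
#' @param ... further overrides passed to [generator_config()].
#' @return a `generator_config`.
#' @export
null_generator_config <- function(seed = 1L, ...) {
  generator_config(seed = seed,
                   pii_decline_rate = 0, limited_bump = 0,
                   height_deficit_frac = 0, biomass_decline_frac = 0,
                   turgor_drop = 0, hydration_dip_depth = 0,
                   chlorosis_rate = 0, sc_fold_reduction = 1,
                   rwc_drop_frac = 0, spad_stress_shift = 0, ...)
}

# Saturating log ion response of the sensor: monotone decreasing (more
# negative) in concentration, g(ion_baseline) = r_baseline.
ion_response <- function(conc, config) {
  l0 <- log10(1 + config$ion_baseline / config$ion_half_sat)
  config$r_baseline * log10(1 + conc / config$ion_half_sat) / l0
}

# Inverse of ion_response on the response fraction f = g(c)/r_baseline.
ion_from_fraction <- function(f, config) {
  l0 <- log10(1 + config$ion_baseline / config$ion_half_sat)
  config$ion_half_sat * (10^(f * l0) - 1)
}

# Programmed NR trajectory (stressed/control response ratio) as a function of
# hours since implantation. Vectorized over t_h.
nr_target_at <- function(t_h, config, design) {
  s0 <- stress_start_day(design)
  if (is.na(s0) || config$pii_decline_rate <= 0) return(rep(1, length(t_h)))
  rh <- config$pii_decline_rate / 24
  t_on <- s0 * 24 + config$onset_lag_h
  da0 <- s0 * 24 + config$da_start_day * 24
  da1 <- da0 + config$da_duration_d * 24
  plateau <- config$nr_plateau
  v_da0 <- max(plateau, 1 - rh * (da0 - t_on))
  v_da1 <- v_da0 + config$da_rebound_frac * (1 - v_da0)
  rw <- rewatered_days(design)
  rwh <- if (length(rw)) rw[1L] * 24 else Inf

  base <- function(t) {
    ifelse(t < t_on, 1,
    ifelse(t < da0, pmax(plateau, 1 - rh * (t - t_on)),
    ifelse(t < da1, v_da0 + (v_da1 - v_da0) * (t - da0) / (da1 - da0),
           pmax(plateau, v_da1 - rh * (t - da1)))))
  }
  lim <- which(design$schedule$stressed == "LIMITED") - 1L
  bump <- function(t) {
    if (!length(lim) || config$limited_bump <= 0) return(rep(0, length(t)))
    ctr <- (lim[1L] + 0.5) * 24
    config$limited_bump * pmax(0, 1 - abs(t - ctr) / 36)
  }
  v <- base(pmin(t_h, rwh)) + ifelse(t_h < rwh, bump(t_h), 0)
  if (is.finite(rwh)) {
    v_rw <- base(rwh)
    target <- max(v_rw, config$recovery_fraction)
    post <- v_rw + (target - v_rw) * pmin(1, pmax(0, t_h - rwh) / 48)
    # second drought block (PIV): faster decline from the recovered level
    dd <- drought_days(design)
    blocks <- split(dd, cumsum(c(1L, diff(dd) != 1L)))
    if (length(blocks) > 1L) {
      piv0 <- blocks[[2L]][1L] * 24
      post <- ifelse(t_h >= piv0,
                     pmax(0.6 * plateau, post - 1.5 * rh * (t_h - piv0)),
                     post)
    }
    v <- ifelse(t_h >= rwh, post, v)
  }
  v
}

#' Simulate latent plant-state trajectories
#'
#' Produces one daily latent state per plant (projected biomass area, height
#' in pixels, hydration, chlorosis fraction, turgor, xylem-sap ion
#' concentration) from which the sensor trace, images and physiology tables
#' are all derived.
#'
#' @param config a [generator_config()].
#' @param design an `experiment_design`.
#' @return object of class `plant_trajectories`: list with `daily`
#'   (data.frame plant_id, group, day, biomass, height, hydration,
#'   chlorosis_frac, turgor, sap_ion_conc), `plants` (roster with per-plant
#'   effects), plus the config and design.
#' @export
simulate_latent_states <- function(config, design) {
  set.seed(config$seed)
  roster <- plant_roster(config$n_per_group)
  # fixed per-plant multiplicative effects (kept day-constant so control
  # biomass stays monotone)
  roster$size_eff <- exp(stats::rnorm(nrow(roster), 0, 0.03))
  roster$ion_eff <- exp(stats::rnorm(nrow(roster), 0, 0.02))
  roster$hydr_eff <- stats::rnorm(nrow(roster), 0, 0.015)
  roster$base_current_uA <- -(4.5 + stats::runif(nrow(roster), 0, 1))

  n <- design$duration_days
  days <- 0:(n - 1L)
  s0 <- stress_start_day(design)
  S <- config$image_size
  scl <- (S / 128)^2
  b0 <- 900 * scl; bmax <- 3000 * scl
  h0 <- 0.35 * S; hmax <- 0.85 * S
  gr <- config$growth_rate

  ctl_biomass <- bmax - (bmax - b0) * exp(-gr * days)
  ctl_height <- hmax - (hmax - h0) * exp(-gr * days)
  ctl_chlor <- pmin(0.6, 0.05 + 0.008 * days)

  ramp <- function(d, from, to) pmin(1, pmax(0, (d - from) / max(to - from, 1e-9)))
  rw <- rewatered_days(design)
  rwd <- if (length(rw)) rw[1L] else Inf

  rows <- lapply(seq_len(nrow(roster)), function(i) {
    p <- roster[i, ]
    stressed <- p$group == "stressed"
    biomass <- ctl_biomass * p$size_eff
    height <- ctl_height * p$size_eff^(1 / 2)
    hydration <- rep(0.85 + p$hydr_eff, n)
    chlor <- ctl_chlor
    turgor <- rep(1, n)
    if (stressed && !is.na(s0)) {
      # height deficit ramps in over stress days 1..5 and is then held
      deficit <- config$height_deficit_frac * ramp(days, s0 + 1, s0 + 5)
      height <- height * (1 - deficit)
      # projected area grows until stress day 2, then declines to a floor
      peak_d <- s0 + 2
      bpeak <- biomass[day_idx(min(peak_d, n - 1L))]
      floor_b <- bpeak * (1 - config$biomass_decline_frac)
      dec <- bpeak - (bpeak - floor_b) * pmin(1, pmax(0, (days - peak_d) / 8))
      biomass <- ifelse(days <= peak_d, biomass, pmin(biomass, dec))
      turgor <- 1 - config$turgor_drop * ramp(days, s0 + 4, s0 + 14) *
        (1 - 0.9 * ramp(days, rwd, rwd + 3))
      dip <- config$hydration_dip_depth *
        ramp(days, config$hydration_dip_window[1], config$hydration_dip_window[1] + 4) *
        (1 - ramp(days, rwd, rwd + 2))
      lim <- which(design$schedule$stressed == "LIMITED") - 1L
      bump <- if (length(lim)) 0.12 * pmax(0, 1 - abs(days - lim[1L]) / 1.5) else 0
      hydration <- pmin(1, 0.85 + p$hydr_eff - dip + bump * (dip > 0))
      chlor <- pmin(0.8, ctl_chlor + config$chlorosis_rate *
                      pmin(pmax(days - (s0 + 2), 0), 12))
    }
    ion <- config$ion_baseline * p$ion_eff
    if (stressed) {
      frac <- nr_target_at((days + 0.5) * 24, config, design)
      ion <- ion_from_fraction(frac, config) * p$ion_eff
    }
    data.frame(plant_id = p$plant_id, group = p$group, day = days,
               biomass = biomass, height = height, hydration = hydration,
               chlorosis_frac = chlor, turgor = turgor, sap_ion_conc = ion,
               stringsAsFactors = FALSE)
  })
  structure(list(daily = do.call(rbind, rows), plants = roster,
                 config = config, design = design),
            class = "plant_trajectories")
}

#' Synthesize raw bioristor current traces
#'
#' For every plant, generates drain currents with the gate off (`i_ds0_uA`, a
#' slowly drifting negative baseline) and on (`i_ds_uA`) such that the
#' implied response R = (Ids - Ids0)/Ids0 equals the saturating log response
#' to the latent sap ion concentration, modulated by a sinusoidal diurnal
#' term clipped to the photoperiod (R falls during the day, rises at night),
#' plus Gaussian noise.
#'
#' @param traj a `plant_trajectories` object from [simulate_latent_states()].
#' @param config a [generator_config()]; defaults to the one inside `traj`.
#' @param design an `experiment_design`; defaults to the one inside `traj`.
#' @return data.frame `plant_id, group, time_min, i_ds_uA, i_ds0_uA`.
#' @export
synthesize_sensor_trace <- function(traj, config = traj$config,
                                    design = traj$design) {
  step <- design$sampling_interval_min
  if (1440 %% step != 0) {
    stop("sampling_interval_min must divide 24 h (1440 min)")
  }
  set.seed(config$seed + 1L)
  t_min <- seq(0, design$duration_days * 1440 - step, by = step)
  t_h <- t_min / 60
  dshape <- diurnal_shape(t_h, design$photoperiod_h)
  dur_min <- design$duration_days * 1440
  out <- lapply(seq_len(nrow(traj$plants)), function(i) {
    p <- traj$plants[i, ]
    frac <- if (p$group == "stressed") nr_target_at(t_h, config, design) else 1
    conc <- ion_from_fraction(rep_len(frac, length(t_h)), config) * p$ion_eff
    r <- ion_response(conc, config) * (1 + config$diurnal_amplitude * dshape) +
      stats::rnorm(length(t_h), 0, config$noise_sd_sensor)
    ids0 <- p$base_current_uA * (1 + 0.05 * t_min / dur_min)
    data.frame(plant_id = p$plant_id, group = p$group, time_min = t_min,
               i_ds_uA = ids0 * (1 + r), i_ds0_uA = ids0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Sinusoid clipped to the photoperiod: positive bump during light hours,
# negative bump at night; multiplies a negative baseline so R is lower
# (more negative) in the daytime.
diurnal_shape <- function(t_h, photoperiod_h) {
  hod <- t_h %% 24
  p <- photoperiod_h
  ifelse(hod < p, sin(pi * hod / p), -sin(pi * (hod - p) / (24 - p)))
}

#' Sample manual physiology tables
#'
#' Emulates the destructive/manual measurements: stomatal conductance (SC,
#' two leaves per plant), fresh/turgid/dry leaf weights for relative water
#' content (two replicates), and SPAD chlorophyll readings (10 leaves).
#' Stressed SC is reduced `sc_fold_reduction`-fold during peak stress, RWC by
#' `rwc_drop_frac` (restored after rewatering), SPAD raised by
#' `spad_stress_shift` during stress.
#'
#' @inheritParams synthesize_sensor_trace
#' @return long data.frame `plant_id, group, day, measure, replicate, value`
#'   with `measure` in SC, FW, TW, DW, SPAD.
#' @export
sample_physiology <- function(traj, config = traj$config,
                              design = traj$design) {
  set.seed(config$seed + 2L)
  s0 <- stress_start_day(design)
  rw <- rewatered_days(design)
  rwd <- if (length(rw)) rw[1L] else Inf
  dd <- drought_days(design)
  dend <- if (length(dd)) dd[length(dd)] else -Inf
  ramp <- function(d, from, to) pmin(1, pmax(0, (d - from) / max(to - from, 1e-9)))

  rows <- list(); k <- 0L
  for (day in design$physio_days) {
    for (i in seq_len(nrow(traj$plants))) {
      p <- traj$plants[i, ]
      stressed <- p$group == "stressed" && !is.na(s0)
      # stomatal conductance, mmol m^-2 s^-1
      sc_base <- 420 - 2 * day
      fold <- 1
      if (stressed && config$sc_fold_reduction > 1) {
        f_peak <- config$sc_fold_reduction
        fold <- if (day <= dend) {
          1 + (f_peak - 1) * ramp(day, s0 + 3, s0 + 6)   # closes in by stress day 6
        } else {
          1 + (f_peak - 1) * (1 - ramp(day, rwd, rwd + 3)) # reopens after rewatering
        }
      }
      sc <- sc_base / fold *
        (1 + stats::rnorm(2, 0, config$noise_sd_physio))
      # RWC -> leaf weights; dw/tw fixed, fw solved from programmed RWC
      rwc_true <- 92
      if (stressed && config$rwc_drop_frac > 0) {
        drop <- config$rwc_drop_frac * ramp(day, s0 + 3, s0 + 9) *
          (1 - ramp(day, rwd, rwd + 2))
        rwc_true <- 92 * (1 - drop)
      }
      rwc_rep <- pmin(100, pmax(0, rwc_true + stats::rnorm(2, 0, config$rwc_noise_sd)))
      dw <- 1; tw <- 5
      fw <- dw + (rwc_rep / 100) * (tw - dw)
      # SPAD
      spad_mu <- 40 + 0.05 * day
      if (stressed && day >= s0 + 4 && day < rwd) {
        spad_mu <- spad_mu + config$spad_stress_shift
      }
      spad <- stats::rnorm(10, spad_mu, config$spad_noise_sd)
      add <- function(measure, vals) {
        k <<- k + 1L
        rows[[k]] <<- data.frame(
          plant_id = p$plant_id, group = p$group, day = day,
          measure = measure, replicate = seq_along(vals), value = vals,
          stringsAsFactors = FALSE)
      }
      add("SC", sc); add("FW", fw); add("TW", rep(tw, 2))
      add("DW", rep(dw, 2)); add("SPAD", spad)
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}
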