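#' Configuration for the synthetic post-ICU cohort generator
#'
#' The generator emulates the study conditions the scoring system is built
#' for: ICU admissions with static fields and time-varying channels, ward
#' vital-sign observation sets every 4-6 hours for up to 14 days after ICU
#' discharge, and first-event outcomes at an ICU-readmission rate of 6.6%
#' and an in-hospital death rate of 2.2% among included admissions.
#' Ward vitals follow patient-level Gaussian baselines with AR(1) noise;
#' adverse events are preceded by a linear deterioration drift in the vitals
#' starting `lead_hours` before the event.
#'
#' @param n_admissions number of ICU admissions (default 5000).
#' @param readmission_rate,death_rate target first-event rates among included
#'   admissions (defaults 0.066 and 0.022).
#' @param obs_interval_hours range of inter-observation gaps (default
#'   c(4, 6), sampled uniformly).
#' @param followup_days post-ICU observation window (default 14).
#' @param deterioration named list: `lead_hours` and per-vital drift
#'   magnitudes reached at the event (`hr`, `rr`, `sbp`, `spo2`, `temp`).
#' @param exclusion_fracs fractions of admissions not discharged alive /
#'   palliative / transferred / status unknown (exercise the inclusion
#'   criteria).
#' @param missing_rate_obs per-cell masking rate for ward vitals.
#' @param missing_rate_channels per-row masking rate for ICU channel values.
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_admissions = 5000,
                             readmission_rate = 0.066,
                             death_rate = 0.022,
                             obs_interval_hours = c(4, 6),
                             followup_days = 14,
                             deterioration = list(lead_hours = 24, hr = 25,
                                                  rr = 8, sbp = -25,
                                                  spo2 = -6, temp = 0.8),
                             exclusion_fracs = c(dead = 0.06,
                                                 palliative = 0.01,
                                                 transferred_out = 0.02,
                                                 unknown = 0.01),
                             missing_rate_obs = 0.02,
                             missing_rate_channels = 0.01,
                             seed = 1) {
  rates <- c(readmission_rate, death_rate)
  if (any(rates < 0) || any(rates > 1) || sum(rates) > 1) {
    stop("event rates must be in [0, 1] and sum to at most 1")
  }
  if (followup_days <= 0) stop("followup_days must be positive")
  if (deterioration$lead_hours <= 0) stop("lead_hours must be positive")
  structure(list(n_admissions = n_admissions,
                 readmission_rate = readmission_rate,
                 death_rate = death_rate,
                 obs_interval_hours = obs_interval_hours,
                 followup_days = followup_days,
                 deterioration = deterioration,
                 exclusion_fracs = exclusion_fracs,
                 missing_rate_obs = missing_rate_obs,
                 missing_rate_channels = missing_rate_channels,
                 seed = seed),
            class = "synthetic_config")
}

# ICU channel dynamics: population mean, between-patient sd, within sd,
# sampling interval in hours, plausible clamp
icu_channel_specs <- function() {
  s <- function(mean, between, within, every_h, lo = -Inf, hi = Inf) {
    list(mean = mean, between = between, within = within,
         every_h = every_h, lo = lo, hi = hi)
  }
  list(hr = s(85, 12, 6, 1, 30, 200),
       sbp = s(120, 15, 8, 1, 50, 250),
       rr = s(18, 4, 2, 1, 5, 60),
       temp = s(37, 0.5, 0.3, 1, 33, 41),
       spo2 = s(96, 2, 1.2, 1, 70, 100),
       fio2 = s(0.35, 0.1, 0.05, 4, 0.21, 1),
       creatinine = s(90, 40, 8, 12, 20, 800),
       urea = s(8, 4, 0.8, 12, 1, 60),
       bilirubin = s(15, 10, 2, 12, 2, 300),
       albumin = s(30, 5, 1, 12, 10, 55),
       sodium = s(139, 3, 1, 12, 120, 160),
       potassium = s(4.2, 0.4, 0.15, 12, 2.5, 7),
       lactate = s(1.5, 0.8, 0.3, 12, 0.3, 15),
       ph = s(7.38, 0.05, 0.02, 12, 7, 7.7),
       glucose = s(7.5, 2, 0.8, 12, 2.5, 30),
       crp = s(80, 60, 10, 24, 1, 500),
       wbc = s(11, 4, 1, 12, 1, 50),
       hgb = s(105, 15, 3, 12, 50, 180),
       hct = s(0.32, 0.04, 0.01, 12, 0.15, 0.55),
       platelets = s(250, 100, 15, 24, 20, 800))
}

# planted log-odds weights on standardised admission-level channel levels;
# ventilation in the final 24 h lowers risk (post-surgical elective pattern)
planted_weights <- function() {
  c(lactate = 0.7, creatinine = 0.5, urea = 0.35, crp = 0.35,
    hr = 0.4, rr = 0.4, sbp = -0.35, albumin = -0.4,
    age = 0.5, ventilated_last24h = -0.6)
}

ar1_noise <- function(k, sd, rho = 0.6) {
  if (k == 0) return(numeric(0))
  as.numeric(stats::filter(rnorm(k, 0, sd * sqrt(1 - rho^2)),
                           rho, method = "recursive"))
}

#' Generate a synthetic post-ICU cohort with ground truth
#'
#' Produces a [cohort_tables()] object plus the ground truth behind it: the
#' latent per-admission risk (a linear combination of standardised
#' ICU-channel levels, age and last-24 h ventilation with planted log-odds
#' weights), the sampled event and deterioration-onset times, and the event
#' probabilities. The logistic intercept is solved numerically so the mean
#' event probability among included admissions equals the configured
#' compound rate; event times are uniform over the follow-up window and the
#' deterioration drift is imposed retrospectively on the pre-event
#' observations. Deterministic given the config seed.
#'
#' @param config a [synthetic_config()].
#' @return list with `cohort` ([cohort_tables()]) and `ground_truth`
#'   (data.frame per admission: `latent`, `p_event`, `event_type`,
#'   `event_hours`, `onset_hours`, `included`; planted weights in attribute
#'   `"weights"`).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  set.seed(config$seed)
  n <- config$n_admissions
  specs <- icu_channel_specs()
  ch_names <- names(specs)

  ids <- sprintf("A%05d", seq_len(n))
  age <- pmin(pmax(round(rnorm(n, 62, 16)), 18), 95)
  sex <- ifelse(runif(n) < 0.41, "female", "male")
  t0 <- iso_to_minutes("2014-01-01 00:00")
  admit <- t0 + round(runif(n, 0, 365 * 1440))
  los_h <- pmin(pmax(rlnorm(n, log(48), 0.8), 12), 24 * 30)
  discharge <- admit + round(los_h * 60)
  los_h <- (discharge - admit) / 60

  # discharge status: most alive, configured fractions excluded
  ef <- config$exclusion_fracs
  u <- runif(n)
  status <- rep("alive", n)
  cuts <- cumsum(ef)
  status[u < cuts[1]] <- "dead"
  status[u >= cuts[1] & u < cuts[2]] <- "palliative"
  status[u >= cuts[2] & u < cuts[3]] <- "transferred_out"
  status[u >= cuts[3] & u < cuts[4]] <- "unknown"

  admissions <- data.frame(admission_id = ids, age = age, sex = sex,
                           icu_admit_time = admit,
                           icu_discharge_time = discharge,
                           discharge_status = status,
                           stringsAsFactors = FALSE)

  # admission-level channel levels
  theta <- sapply(ch_names, function(cn) {
    sp <- specs[[cn]]
    pmin(pmax(rnorm(n, sp$mean, sp$between), sp$lo), sp$hi)
  })

  # interventions: on/off intervals within the stay
  ventilated <- runif(n) < 0.35
  vent_end_h <- ifelse(ventilated, los_h * rbeta(n, 2, 1.2), NA)
  vasopressor <- runif(n) < 0.25
  vaso_end_h <- ifelse(vasopressor, los_h * rbeta(n, 2, 2), NA)
  rrt <- runif(n) < 0.08
  rrt_end_h <- ifelse(rrt, los_h * rbeta(n, 2, 1.5), NA)
  ventilated_last24 <- ventilated & vent_end_h >= los_h - 24

  # channel series: last 48 h at the channel's cadence plus a coarse
  # whole-stay backbone every 24 h
  channel_rows <- vector("list", n)
  for (i in seq_len(n)) {
    per_ch <- vector("list", length(ch_names) + 3)
    for (j in seq_along(ch_names)) {
      sp <- specs[[ch_names[j]]]
      t_late <- seq(max(0, los_h[i] - 48), los_h[i], by = sp$every_h)
      t_early <- if (los_h[i] > 72) {
        head(seq(6, los_h[i] - 49, by = 24), 8)
      } else numeric(0)
      th <- sort(unique(c(t_early, t_late)))
      vals <- theta[i, j] + ar1_noise(length(th), sp$within)
      per_ch[[j]] <- data.frame(channel = ch_names[j],
                                time = admit[i] + round(th * 60),
                                value = pmin(pmax(vals, sp$lo), sp$hi))
    }
    iv <- function(name, active, end_h) {
      if (!active) return(NULL)
      data.frame(channel = name,
                 time = admit[i] + round(c(0, end_h) * 60),
                 value = c(1, 0))
    }
    per_ch[[length(ch_names) + 1]] <- iv("ventilation", ventilated[i],
                                         vent_end_h[i])
    per_ch[[length(ch_names) + 2]] <- iv("vasopressor", vasopressor[i],
                                         vaso_end_h[i])
    per_ch[[length(ch_names) + 3]] <- iv("rrt", rrt[i], rrt_end_h[i])
    chunk <- data.table::rbindlist(per_ch)
    chunk[, admission_id := ids[i]]
    channel_rows[[i]] <- chunk
  }
  channels <- as.data.frame(data.table::rbindlist(channel_rows))
  channels <- channels[, c("admission_id", "channel", "time", "value")]
  # clamp rounding spill at the stay boundaries
  channels$time <- pmin(pmax(channels$time,
                             admit[match(channels$admission_id, ids)]),
                        discharge[match(channels$admission_id, ids)])

  # latent risk from planted weights on standardised levels
  w <- planted_weights()
  zmat <- cbind(
    lactate = (theta[, "lactate"] - specs$lactate$mean) / specs$lactate$between,
    creatinine = (theta[, "creatinine"] - specs$creatinine$mean) /
      specs$creatinine$between,
    urea = (theta[, "urea"] - specs$urea$mean) / specs$urea$between,
    crp = (theta[, "crp"] - specs$crp$mean) / specs$crp$between,
    hr = (theta[, "hr"] - specs$hr$mean) / specs$hr$between,
    rr = (theta[, "rr"] - specs$rr$mean) / specs$rr$between,
    sbp = (theta[, "sbp"] - specs$sbp$mean) / specs$sbp$between,
    albumin = (theta[, "albumin"] - specs$albumin$mean) /
      specs$albumin$between,
    age = (age - 62) / 16,
    ventilated_last24h = (as.numeric(ventilated_last24) - 0.25) / 0.43)
  latent <- as.vector(zmat %*% w[colnames(zmat)])

  included <- status == "alive"
  p_total <- config$readmission_rate + config$death_rate
  a <- if (p_total > 0) {
    uniroot(function(a) mean(plogis(a + latent[included])) - p_total,
            c(-30, 10))$root
  } else -Inf
  p_event <- plogis(a + latent)

  # events only among included admissions; first event only
  has_event <- included & (runif(n) < p_event) & p_total > 0
  etype <- rep("none", n)
  is_readm <- runif(n) < config$readmission_rate / max(p_total, 1e-12)
  etype[has_event] <- ifelse(is_readm[has_event], "readmission", "death")
  followup_h <- config$followup_days * 24
  event_h <- ifelse(has_event, runif(n, 4, followup_h), NA)
  onset_h <- ifelse(has_event,
                    pmax(event_h - config$deterioration$lead_hours, 0), NA)

  # hospital stay after ICU discharge
  hosp_los_h <- pmin(pmax(rlnorm(n, log(7 * 24), 0.5), 24), followup_h)
  hosp_dis_h <- ifelse(has_event & etype == "death", event_h,
                       ifelse(has_event,
                              pmin(event_h + rlnorm(n, log(5 * 24), 0.4),
                                   60 * 24),
                              hosp_los_h))

  # ward observation sets for included admissions
  obs_rows <- vector("list", n)
  det <- config$deterioration
  gap <- config$obs_interval_hours
  for (i in which(included)) {
    end_h <- min(if (has_event[i]) event_h[i] else hosp_los_h[i], followup_h)
    k_max <- ceiling(end_h / gap[1]) + 1
    t_h <- cumsum(runif(k_max, gap[1], gap[2]))
    t_h <- t_h[t_h < end_h]
    k <- length(t_h)
    if (!k) { obs_rows[[i]] <- NULL; next }
    base <- c(hr = 80 + 2.5 * latent[i], sbp = 125 - 1.5 * latent[i],
              rr = 17 + 0.7 * latent[i], temp = 36.8, spo2 = 96.5)
    obs <- data.frame(
      admission_id = ids[i],
      obs_time = discharge[i] + round(t_h * 60),
      heart_rate = base["hr"] + rnorm(1, 0, 9) + ar1_noise(k, 5),
      systolic_bp = base["sbp"] + rnorm(1, 0, 12) + ar1_noise(k, 8),
      resp_rate = base["rr"] + rnorm(1, 0, 2.2) + ar1_noise(k, 1.6),
      temperature = base["temp"] + rnorm(1, 0, 0.35) + ar1_noise(k, 0.25),
      spo2 = base["spo2"] + rnorm(1, 0, 1.4) + ar1_noise(k, 1.1),
      supplemental_o2 = runif(k) < ifelse(t_h < 48, 0.15, 0.05),
      avpu = rep("A", k),
      stringsAsFactors = FALSE)
    obs$t_h <- t_h
    if (has_event[i]) {
      obs <- inject_deterioration(obs, event_h[i], det)
    }
    obs$t_h <- NULL
    obs_rows[[i]] <- obs
  }
  observations <- as.data.frame(data.table::rbindlist(obs_rows))
  if (nrow(observations)) {
    b <- vital_bounds()
    for (v in names(b)) {
      observations[[v]] <- pmin(pmax(round(observations[[v]] /
                                             vital_precision()[v]) *
                                       vital_precision()[v],
                                     b[[v]][1]), b[[v]][2])
    }
  }

  outcomes <- data.frame(
    admission_id = ids[included],
    event_type = etype[included],
    event_time = ifelse(has_event[included],
                        discharge[included] + round(event_h[included] * 60),
                        NA_real_),
    hospital_discharge_time = discharge[included] +
      round(hosp_dis_h[included] * 60),
    stringsAsFactors = FALSE)

  cohort <- cohort_tables(admissions, channels, observations, outcomes)
  cohort <- make_missing(cohort,
                         rates = list(observations = config$missing_rate_obs,
                                      channels = config$missing_rate_channels),
                         seed = config$seed + 1L)

  gt <- data.frame(admission_id = ids, latent = latent, p_event = p_event,
                   event_type = etype, event_hours = event_h,
                   onset_hours = onset_h, included = included,
                   ventilated_last24h = ventilated_last24,
                   stringsAsFactors = FALSE)
  attr(gt, "weights") <- w
  list(cohort = cohort, ground_truth = gt)
}

#' Impose a pre-event deterioration drift on a vital-sign trajectory
#'
#' From `event_hours - lead_hours` to the event, vitals drift linearly
#' towards the configured magnitudes (heart and respiratory rate up, blood
#' pressure and SpO2 down, temperature perturbed); consciousness degrades
#' (A -> V -> P) and supplemental oxygen is given as the drift deepens.
#' Observations before the onset are untouched. The transform is
#' deterministic, so pre-onset rows are identical to their event-free
#' counterfactual under common random numbers. A lead longer than the
#' elapsed post-ICU time is truncated at discharge (attribute
#' `"lead_truncated"`).
#'
#' @param trajectory data.frame of observation rows with a `t_h` column
#'   (hours since ICU discharge) and the vital-sign columns.
#' @param event_hours event time in hours since ICU discharge.
#' @param deterioration config list (see [synthetic_config()]).
#' @return the modified trajectory.
#' @export
inject_deterioration <- function(trajectory, event_hours, deterioration) {
  mags <- unlist(deterioration[c("hr", "rr", "sbp", "spo2", "temp")])
  if (all(mags == 0)) {
    attr(trajectory, "lead_truncated") <- FALSE
    return(trajectory)
  }
  lead <- deterioration$lead_hours
  onset <- event_hours - lead
  truncated <- onset < 0
  onset <- max(onset, 0)
  span <- event_hours - onset
  r <- pmin(pmax((trajectory$t_h - onset) / span, 0), 1)
  trajectory$heart_rate <- trajectory$heart_rate + r * deterioration$hr
  trajectory$resp_rate <- trajectory$resp_rate + r * deterioration$rr
  trajectory$systolic_bp <- trajectory$systolic_bp + r * deterioration$sbp
  trajectory$spo2 <- trajectory$spo2 + r * deterioration$spo2
  trajectory$temperature <- trajectory$temperature + r * deterioration$temp
  esc <- r > 0
  trajectory$avpu[esc & r > 0.6] <- "V"
  trajectory$avpu[esc & r > 0.9] <- "P"
  trajectory$supplemental_o2[esc & r > 0.4] <- TRUE
  attr(trajectory, "lead_truncated") <- truncated
  trajectory
}

#' Mask values at random to emulate charting gaps
#'
#' Applies independent per-cell masking to the ward vital-sign columns and
#' per-row masking to ICU channel values. Timestamps, identifiers and
#' outcome fields are never masked.
#'
#' @param cohort a [cohort_tables()] object.
#' @param rates list with elements `observations` and `channels`, each a
#'   rate in \[0, 1).
#' @param seed integer seed.
#' @return the cohort with masked values.
#' @export
make_missing <- function(cohort, rates = list(observations = 0.02,
                                              channels = 0.01),
                         seed = 1) {
  r_obs <- rates$observations %||% 0
  r_ch <- rates$channels %||% 0
  if (r_obs < 0 || r_obs >= 1 || r_ch < 0 || r_ch >= 1) {
    stop("missingness rates must lie in [0, 1)")
  }
  set.seed(seed)
  obs <- cohort$observations
  if (r_obs > 0 && nrow(obs)) {
    for (v in c(novelty_channels(), "avpu", "supplemental_o2")) {
      mask <- runif(nrow(obs)) < r_obs
      obs[[v]][mask] <- NA
    }
    cohort$observations <- obs
  }
  ch <- cohort$channels
  if (r_ch > 0 && nrow(ch)) {
    # interventions are on/off state changes; masking those would corrupt
    # the state machine, so only measurement channels are masked
    maskable <- !ch$channel %in% c("ventilation", "vasopressor", "rrt")
    mask <- maskable & runif(nrow(ch)) < r_ch
    cohort$channels <- ch[!mask, , drop = FALSE]
  }
  cohort
}

`%||%` <- function(a, b) if (is.null(a)) b else a
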