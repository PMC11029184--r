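# small in-code fixtures shared across test files

t_origin <- rsindex::iso_to_minutes("2014-03-01 00:00")

# a 3-admission cohort with hand-placed channels, observations and events
tiny_cohort <- function() {
  adm <- data.frame(
    admission_id = c("P1", "P2", "P3"),
    age = c(55, 70, 62),
    sex = c("female", "male", "male"),
    icu_admit_time = t_origin + c(0, 0, 0),
    icu_discharge_time = t_origin + c(3, 4, 5) * 1440,
    discharge_status = "alive",
    stringsAsFactors = FALSE)
  ch <- do.call(rbind, lapply(1:3, function(i) {
    dis <- adm$icu_discharge_time[i]
    rbind(
      data.frame(admission_id = adm$admission_id[i], channel = "hr",
                 time = dis - c(24, 18, 12, 6, 0) * 60,
                 value = c(80, 82, 85, 88, 90) + i),
      data.frame(admission_id = adm$admission_id[i], channel = "sbp",
                 time = dis - c(24, 12, 0) * 60, value = 120),
      data.frame(admission_id = adm$admission_id[i], channel = "lactate",
                 time = dis - c(36, 12) * 60, value = c(2.5, 1.5 + i)))
  }))
  # P2 ventilated from 30 h to 2 h before discharge
  ch <- rbind(ch, data.frame(admission_id = "P2", channel = "ventilation",
                             time = adm$icu_discharge_time[2] - c(30, 2) * 60,
                             value = c(1, 0)))
  obs <- do.call(rbind, lapply(1:3, function(i) {
    dis <- adm$icu_discharge_time[i]
    t_h <- seq(5, 48, by = 5)
    data.frame(admission_id = adm$admission_id[i],
               obs_time = dis + t_h * 60,
               heart_rate = 78 + i, systolic_bp = 122, resp_rate = 16,
               temperature = 36.9, spo2 = 97, supplemental_o2 = FALSE,
               avpu = "A", stringsAsFactors = FALSE)
  }))
  oc <- data.frame(
    admission_id = c("P1", "P2", "P3"),
    event_type = c("none", "readmission", "none"),
    event_time = c(NA, adm$icu_discharge_time[2] + 40 * 60, NA),
    hospital_discharge_time = adm$icu_discharge_time + c(8, 10, 9) * 1440,
    stringsAsFactors = FALSE)
  rsindex::cohort_tables(adm, ch, obs, oc, validate = FALSE)
}

normal_obs <- function(...) {
  base <- list(heart_rate = 70, systolic_bp = 120, resp_rate = 16,
               temperature = 37.0, spo2 = 98, supplemental_o2 = FALSE,
               avpu = "A")
  utils::modifyList(base, list(...))
}

# independent hand-coded nested-conditional EWS oracles (transcribed
# separately from the band files; the published charts, as if/else chains)
oracle_news <- function(hr, sbp, rr, temp, spo2, o2, avpu) {
  s <- 0
  s <- s + if (rr <= 8) 3 else if (rr <= 11) 1 else if (rr <= 20) 0 else
    if (rr <= 24) 2 else 3
  s <- s + if (spo2 <= 91) 3 else if (spo2 <= 93) 2 else if (spo2 <= 95) 1 else 0
  s <- s + if (o2) 2 else 0
  s <- s + if (temp <= 35) 3 else if (temp <= 36) 1 else if (temp <= 38) 0 else
    if (temp <= 39) 1 else 2
  s <- s + if (sbp <= 90) 3 else if (sbp <= 100) 2 else if (sbp <= 110) 1 else
    if (sbp <= 219) 0 else 3
  s <- s + if (hr <= 40) 3 else if (hr <= 50) 1 else if (hr <= 90) 0 else
    if (hr <= 110) 1 else if (hr <= 130) 2 else 3
  s + if (avpu == "A") 0 else 3
}

oracle_mews <- function(hr, sbp, rr, temp, spo2, o2, avpu) {
  s <- 0
  s <- s + if (sbp <= 70) 3 else if (sbp <= 80) 2 else if (sbp <= 100) 1 else
    if (sbp <= 199) 0 else 2
  s <- s + if (hr <= 40) 2 else if (hr <= 50) 1 else if (hr <= 100) 0 else
    if (hr <= 110) 1 else if (hr <= 129) 2 else 3
  s <- s + if (rr <= 8) 2 else if (rr <= 14) 0 else if (rr <= 20) 1 else
    if (rr <= 29) 2 else 3
  s <- s + if (temp < 35) 2 else if (temp < 38.5) 0 else 2
  s + switch(avpu, A = 0, V = 1, P = 2, U = 3)
}

oracle_sews <- function(hr, sbp, rr, temp, spo2, o2, avpu) {
  s <- 0
  s <- s + if (rr <= 8) 2 else if (rr <= 20) 0 else if (rr <= 30) 1 else
    if (rr <= 35) 2 else 3
  s <- s + if (spo2 < 85) 3 else if (spo2 < 90) 2 else if (spo2 < 93) 1 else 0
  s <- s + if (temp < 34) 3 else if (temp < 35) 2 else if (temp < 36) 1 else
    if (temp < 38) 0 else if (temp < 39) 1 else 2
  s <- s + if (sbp < 70) 3 else if (sbp < 80) 2 else if (sbp < 100) 1 else
    if (sbp < 200) 0 else 3
  s <- s + if (hr < 30) 3 else if (hr < 40) 2 else if (hr < 50) 1 else
    if (hr < 100) 0 else if (hr < 110) 1 else if (hr < 130) 2 else 3
  s + switch(avpu, A = 0, V = 1, P = 2, U = 3)
}

oracle_cews <- function(hr, sbp, rr, temp, spo2, o2, avpu) {
  s <- 0
  s <- s + if (hr <= 44) 3 else if (hr <= 50) 2 else if (hr <= 54) 1 else
    if (hr <= 103) 0 else if (hr <= 110) 1 else if (hr <= 127) 2 else 3
  s <- s + if (sbp <= 84) 3 else if (sbp <= 96) 2 else if (sbp <= 101) 1 else
    if (sbp <= 160) 0 else if (sbp <= 171) 1 else if (sbp <= 194) 2 else 3
  s <- s + if (rr <= 8) 3 else if (rr <= 10) 2 else if (rr <= 12) 1 else
    if (rr <= 22) 0 else if (rr <= 25) 1 else if (rr <= 31) 2 else 3
  s <- s + if (spo2 <= 84) 3 else if (spo2 <= 89) 2 else if (spo2 <= 92) 1 else 0
  s <- s + if (temp <= 35.5) 3 else if (temp <= 35.9) 2 else
    if (temp <= 36.2) 1 else if (temp <= 37.3) 0 else if (temp <= 37.6) 1 else
    if (temp <= 38.0) 2 else 3
  s + switch(avpu, A = 0, V = 1, P = 2, U = 3)
}

ews_oracles <- function() {
  list(MEWS = oracle_mews, SEWS = oracle_sews, NEWS = oracle_news,
       CEWS = oracle_cews)
}

# sample a grid of plausible observation sets at chart precision
sample_vital_grid <- function(n, seed) {
  set.seed(seed)
  data.frame(
    heart_rate = sample(10:300, n, replace = TRUE),
    systolic_bp = sample(30:300, n, replace = TRUE),
    resp_rate = sample(0:80, n, replace = TRUE),
    temperature = round(runif(n, 30, 43), 1),
    spo2 = sample(50:100, n, replace = TRUE),
    supplemental_o2 = sample(c(TRUE, FALSE), n, replace = TRUE),
    avpu = sample(c("A", "V", "P", "U"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# brute-force pairwise AUROC oracle
auroc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# the default study-scale cohort, generated once per test session
.cohort_cache <- new.env(parent = emptyenv())
default_cohort_5000 <- function() {
  if (is.null(.cohort_cache$g)) {
    .cohort_cache$g <- rsindex::generate_cohort(
      rsindex::synthetic_config(seed = 2025))
  }
  .cohort_cache$g
}

# small gaussian-cloud normality model for novelty tests
toy_novelty_model <- function(n = 200, seed = 42, ...) {
  set.seed(seed)
  tr <- cbind(heart_rate = rnorm(n, 80, 10),
              systolic_bp = rnorm(n, 120, 12),
              resp_rate = rnorm(n, 17, 2),
              temperature = rnorm(n, 36.8, 0.3),
              spo2 = rnorm(n, 96, 1.5))
  fit_normality_model(tr, seed = seed, ...)
}
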