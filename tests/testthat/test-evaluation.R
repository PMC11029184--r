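make_labelled_fixture <- function() {
  adm_ids <- c("P1", "P2", "P3")
  obs <- data.frame(
    admission_id = rep(adm_ids, each = 4),
    obs_time = t_origin + rep(c(10, 20, 30, 40) * 60, 3))
  oc <- data.frame(
    admission_id = adm_ids,
    event_type = c("death", "readmission", "none"),
    event_time = t_origin + c(20, 44, NA) * 60,
    hospital_discharge_time = t_origin + c(20, 200, 45) * 60)
  list(obs = obs, oc = oc)
}

test_that("window labelling is positive in (0, N], censored post-event, else negative", {
  fx <- make_labelled_fixture()
  lab <- label_observations(fx$obs, fx$oc, N = 24)
  p1 <- lab[lab$admission_id == "P1", ]
  # death at +20 h: obs at +10 h positive; obs at/after the event censored
  expect_equal(p1$label, c(1, NA, NA, NA))
  expect_equal(p1$censored, c(FALSE, TRUE, TRUE, TRUE))
  p2 <- lab[lab$admission_id == "P2", ]
  # readmission at +44 h: +20/+30/+40 within 24 h, +10 outside
  expect_equal(p2$label, c(0, 1, 1, 1))
  p3 <- lab[lab$admission_id == "P3", ]
  expect_equal(p3$label, rep(0, 4))

  # endpoint filtering: deaths only
  lab_d <- label_observations(fx$obs, fx$oc, N = 24, endpoint = "death")
  expect_equal(lab_d$label[lab_d$admission_id == "P2"], rep(0, 4))
  # but follow-up still ends at the first event of any type
  lab_r <- label_observations(fx$obs, fx$oc, N = 24, endpoint = "readmission")
  expect_equal(lab_r$censored[lab_r$admission_id == "P1"],
               c(FALSE, TRUE, TRUE, TRUE))

  # near-discharge censoring flag
  lab_c <- label_observations(fx$obs, fx$oc, N = 24,
                              censor_near_discharge = TRUE)
  # P3 discharged at +45 h: observations within 24 h of discharge censored
  p3c <- lab_c[lab_c$admission_id == "P3", ]
  expect_equal(p3c$censored, c(FALSE, FALSE, TRUE, TRUE))

  expect_error(label_observations(fx$obs, fx$oc, N = 0), "positive")
})

test_that("labelled observations partition and positives nest across horizons", {
  g <- generate_cohort(synthetic_config(n_admissions = 150, seed = 41))
  obs <- g$cohort$observations
  oc <- g$cohort$outcomes
  prev_pos <- NULL
  for (N in c(12, 24, 36, 48, 72)) {
    lab <- label_observations(obs, oc, N)
    n_pos <- sum(lab$label == 1, na.rm = TRUE)
    n_neg <- sum(lab$label == 0, na.rm = TRUE)
    n_cen <- sum(lab$censored)
    expect_equal(n_pos + n_neg + n_cen, nrow(obs), info = paste("N =", N))
    pos_key <- paste(lab$admission_id, lab$obs_time)[!is.na(lab$label) &
                                                       lab$label == 1]
    if (!is.null(prev_pos)) {
      expect_true(all(prev_pos %in% pos_key), info = paste("N =", N))
    }
    prev_pos <- pos_key
  }
})

test_that("rank-based AUROC matches brute-force pairwise counting", {
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auroc(1:4, rep(1, 4)), "both classes")

  set.seed(51)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    s <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # force ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(auroc(s, y), auroc_pairwise(s, y), tolerance = 1e-12)
  }
})

test_that("grouped bootstrap is deterministic, respects admissions, and covers", {
  set.seed(61)
  d <- data.frame(admission_id = rep(sprintf("A%02d", 1:30), each = 5),
                  x = rnorm(150, mean = 2))
  ci1 <- bootstrap_ci(function(dd) mean(dd$x), d, B = 200, seed = 9)
  ci2 <- bootstrap_ci(function(dd) mean(dd$x), d, B = 200, seed = 9)
  expect_identical(ci1, ci2)
  expect_lte(ci1[["low"]], ci1[["high"]])

  # degenerate cohort of identical admissions -> zero width
  d0 <- data.frame(admission_id = rep(c("A", "B"), each = 3), x = 1)
  ci0 <- bootstrap_ci(function(dd) mean(dd$x), d0, B = 50, seed = 1)
  expect_equal(unname(ci0[["high"]] - ci0[["low"]]), 0)

  # width shrinks with cohort size (same data-generating process)
  set.seed(62)
  big <- data.frame(admission_id = rep(sprintf("B%03d", 1:300), each = 5),
                    x = rnorm(1500, mean = 2))
  ci_big <- bootstrap_ci(function(dd) mean(dd$x), big, B = 200, seed = 9)
  expect_lt(ci_big[["high"]] - ci_big[["low"]],
            ci1[["high"]] - ci1[["low"]])

  expect_error(bootstrap_ci(function(dd) stop("nope"), d, B = 20, seed = 1),
               "10%")
})

test_that("calibration statistics reduce to closed forms", {
  set.seed(71)
  n <- 10000
  y <- rep(c(0, 1), n / 2)
  # constant 0.5 prediction on balanced labels
  rep_const <- calibration_report(rep(0.5, n) + rnorm(n, 0, 1e-9), y)
  expect_equal(rep_const$brier, 0.25, tolerance = 1e-6)

  # probabilities equal to group event rates -> alpha ~ 0, beta ~ 1
  p_true <- rbeta(n, 2, 5)
  y2 <- rbinom(n, 1, p_true)
  rep_cal <- calibration_report(p_true, y2)
  expect_equal(rep_cal$cox_alpha, 0, tolerance = 0.05)
  expect_equal(rep_cal$cox_beta, 1, tolerance = 0.05)

  # near-perfect predictions -> Brier ~ 0 and small HL
  p3 <- ifelse(y == 1, 0.999, 0.001)
  # perfect separation: the recalibration glm legitimately fails to converge
  rep_perf <- suppressWarnings(calibration_report(p3, y))
  expect_lt(rep_perf$brier, 1e-4)

  expect_error(calibration_report(c(0, 0.5), c(0, 1)), "strictly")
})

test_that("trigger burden counts match exhaustive counting", {
  scores <- c(1, 3, 2, 5, 4, 2)
  labels <- c(0, 1, 0, 1, 0, 0)
  bc <- trigger_burden(scores, labels, thresholds = c(0, 2, 4, 6))
  expect_equal(bc$triggers, c(6, 5, 2, 0))
  expect_equal(bc$true_positive, c(2, 2, 1, 0))
  expect_equal(bc$burden, c(3, 2.5, 2, Inf))
  expect_equal(bc$burden_defined, c(TRUE, TRUE, TRUE, FALSE))
  expect_error(trigger_burden(scores, labels, c(4, 2)), "sorted")

  # per-event normalisation counts admissions, not observations
  ids <- c("A", "A", "A", "B", "B", "C")
  bc2 <- trigger_burden(scores, labels, thresholds = 0, per_event = TRUE,
                        admission_id = ids)
  expect_equal(bc2$burden, 6 / 2)
})

test_that("system comparison uses identical labelled sets for every system", {
  g <- generate_cohort(synthetic_config(n_admissions = 200, seed = 43))
  scores <- score_cohort_systems(g$cohort, systems = c("NEWS", "MEWS"))
  cmp <- compare_systems(scores, g$cohort$observations, g$cohort$outcomes,
                         horizons = c(24, 72), endpoints = c("compound"),
                         B = 0)
  expect_equal(nrow(cmp), 2 * 2 * 1)
  audit <- attr(cmp, "audit")
  expect_equal(nrow(audit), 2)
  # every system row at a given (horizon, endpoint) shares n_obs and n_pos
  for (h in c(24, 72)) {
    sub <- cmp[cmp$horizon == h, ]
    expect_equal(length(unique(sub$n_obs)), 1)
    expect_equal(length(unique(sub$n_pos)), 1)
    expect_equal(sub$n_obs[1], audit$n_obs[audit$horizon == h])
  }
  # each AUROC is reproduced by the independent pairwise oracle
  lab24 <- label_observations(g$cohort$observations, g$cohort$outcomes, 24)
  keep <- !lab24$censored
  for (sys in c("NEWS", "MEWS")) {
    want <- auroc_pairwise(scores[[sys]][keep], lab24$label[keep])
    expect_equal(cmp$auroc[cmp$system == sys & cmp$horizon == 24], want,
                 tolerance = 1e-12)
  }
})

test_that("evaluate_scores assembles AUROC, calibration and burden", {
  g <- generate_cohort(synthetic_config(n_admissions = 200, seed = 47))
  m <- toy_novelty_model(n = 150)
  sc <- rs2_score(m, g$cohort$observations)
  rep <- evaluate_scores(sc, g$cohort$observations, g$cohort$outcomes,
                         horizons = c(24, 48), B = 50, seed = 3,
                         calibration = TRUE)
  expect_s3_class(rep, "evaluation_report")
  expect_equal(rep$auroc$horizon, c(24, 48))
  expect_true(all(rep$auroc$auroc >= 0 & rep$auroc$auroc <= 1))
  expect_true(all(rep$auroc$ci_low <= rep$auroc$auroc &
                    rep$auroc$auroc <= rep$auroc$ci_high))
  expect_true(rep$calibration$brier >= 0 && rep$calibration$brier <= 1)
  expect_true(all(diff(rep$burden$triggers) <= 0))
})
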