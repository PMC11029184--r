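test_that("feature extraction summarises channels and interventions", {
  cohort <- tiny_cohort()
  spec <- feature_spec(data.frame(
    name = c("hr_mean_last24h", "hr_slope_last24h", "sbp_slope_last24h",
             "lactate_last_last24h", "lactate_min_stay",
             "ventilated_last24h", "age", "icu_los_days"),
    channel = c("hr", "hr", "sbp", "lactate", "lactate", "ventilation",
                "age", "icu_los_days"),
    operator = c("mean", "slope", "slope", "last", "min", "present",
                 "static", "static"),
    window_hours = c(24, 24, 24, 24, NA, 24, NA, NA)))
  p2 <- extract_features(cohort$admissions[2, ],
                         cohort$channels[cohort$channels$admission_id == "P2", ],
                         spec)
  v <- p2$values
  # ventilation active 30 h -> 2 h before discharge overlaps the window
  expect_equal(unname(v["ventilated_last24h"]), 1)
  expect_equal(unname(v["hr_mean_last24h"]), mean(c(80, 82, 85, 88, 90) + 2))
  # constant SBP over the window -> zero slope
  expect_equal(unname(v["sbp_slope_last24h"]), 0)
  # whole-stay min sees the early lactate point outside the 24 h window
  expect_equal(unname(v["lactate_min_stay"]), 2.5)
  expect_equal(unname(v["lactate_last_last24h"]), 3.5)
  expect_equal(unname(v["age"]), 70)
  expect_equal(unname(v["icu_los_days"]), 4)

  # empty channel -> missing flag, not zero
  p_empty <- extract_features(cohort$admissions[2, ],
                              cohort$channels[0, ],
                              spec[spec$operator != "present", ])
  expect_true(is.na(p_empty$values["hr_mean_last24h"]))

  # hr slope: values rise 80+2 .. 90+2 over -24..0 h -> positive
  expect_gt(unname(v["hr_slope_last24h"]), 0)

  # matrix extraction agrees with per-admission extraction
  X <- extract_feature_matrix(cohort, spec)
  expect_equal(X["P2", ], v)

  bad <- feature_spec(data.frame(name = "x", channel = "no_such",
                                 operator = "mean", window_hours = 24))
  expect_error(extract_feature_matrix(cohort, bad), "unknown channel")
})

test_that("impute_and_standardise uses training parameters only in apply mode", {
  set.seed(5)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  X[3, 2] <- NA
  fit <- impute_and_standardise(X)
  expect_equal(unname(colMeans(fit$design)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(fit$design, 2, sd)), rep(1, 4), tolerance = 1e-12)
  # the missing cell was filled with the training median
  filled <- fit$design[3, 2] * fit$params$scales[2] + fit$params$centers[2]
  expect_equal(unname(filled), unname(fit$params$medians[2]))

  # apply mode: new data scaled with stored parameters
  Xnew <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  app <- impute_and_standardise(Xnew, params = fit$params)
  expect_equal(app$design,
               sweep(sweep(Xnew, 2, fit$params$centers), 2,
                     fit$params$scales, "/"))

  # all-missing and zero-variance features are dropped with a warning
  X2 <- cbind(X, allna = NA_real_, const = 1)
  expect_warning(f2 <- impute_and_standardise(X2), "dropping")
  expect_setequal(f2$params$dropped, c("allna", "const"))
})

test_that("lasso limits behave: huge penalty gives the null model, separable data gives AUROC 1", {
  set.seed(9)
  n <- 300
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- rbinom(n, 1, plogis(2 * X[, 1]))
  m_null <- fit_rs1(X, y, lambda_grid = c(1e6), seed = 1)
  expect_equal(length(m_null$coefficients), 0)
  expect_equal(m_null$intercept, qlogis(mean(y)), tolerance = 1e-4)

  # linearly separable toy set
  Xs <- matrix(c(rnorm(50, -3), rnorm(50, 3)), ncol = 1,
               dimnames = list(NULL, "f1"))
  ys <- rep(0:1, each = 50)
  ms <- fit_rs1(Xs, ys, seed = 1)
  expect_equal(auroc(predict_rs1(ms, Xs), ys), 1)
})

test_that("retained-feature count is non-increasing in the penalty", {
  set.seed(13)
  X <- matrix(rnorm(500 * 20), 500, 20, dimnames = list(NULL, paste0("f", 1:20)))
  y <- rbinom(500, 1, plogis(X[, 1] - X[, 2]))
  m <- fit_rs1(X, y, seed = 2)
  # lambda_grid is stored decreasing: support grows (weakly) along it
  path <- m$n_retained_path
  expect_true(all(diff(path) >= 0))
})

test_that("predictions are invariant to affine rescaling of a raw feature", {
  set.seed(17)
  X <- matrix(rnorm(400 * 5), 400, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rbinom(400, 1, plogis(1.5 * X[, 1]))
  m1 <- fit_rs1(X, y, seed = 3)
  X2 <- X
  X2[, 1] <- 100 + 42 * X2[, 1]
  m2 <- fit_rs1(X2, y, seed = 3)
  expect_equal(predict_rs1(m1, X), predict_rs1(m2, X2), tolerance = 1e-6)
})

test_that("predict_rs1 reduces to closed forms", {
  m <- structure(list(intercept = 0, coefficients = numeric(0),
                      preprocessing = list(medians = c(f1 = 0),
                                           centers = c(f1 = 0),
                                           scales = c(f1 = 1),
                                           features = "f1",
                                           dropped = character(0))),
                 class = "rs1_model")
  expect_equal(unname(predict_rs1(m, c(f1 = 3))), 0.5)
  m$coefficients <- c(f1 = 1)
  expect_equal(unname(predict_rs1(m, c(f1 = 1))), plogis(1))
  # missing feature flows through imputation (median 0 here)
  expect_equal(unname(predict_rs1(m, c(f1 = NA))), 0.5)
  p <- predict_rs1(m, matrix(rnorm(20), 20, 1, dimnames = list(NULL, "f1")))
  expect_true(all(p > 0 & p < 1))
})

test_that("degenerate labels are rejected", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_rs1(X, rep(1, 20)), "2 events")
  expect_error(fit_rs1(X, c(1, rep(0, 19))), "2 events")
})

test_that("rs1 model round-trips through JSON", {
  set.seed(23)
  X <- matrix(rnorm(200 * 4), 200, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(200, 1, plogis(X[, 1]))
  m <- fit_rs1(X, y, seed = 4)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  expect_equal(predict_rs1(m2, X), predict_rs1(m, X), tolerance = 1e-12)
})
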