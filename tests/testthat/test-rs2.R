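test_that("normality training set is discharge-day observations of event-free admissions", {
  cohort <- tiny_cohort()
  # move P1 and P3 observations so some fall on the hospital discharge day
  oc <- cohort$outcomes
  obs <- cohort$observations
  dis_day_start <- floor(oc$hospital_discharge_time[1] / 1440) * 1440
  obs$obs_time[obs$admission_id == "P1"][1:3] <-
    dis_day_start + c(60, 300, 600)
  cohort$observations <- obs
  tr <- select_normality_training_set(cohort)
  # P2 had an event: contributes nothing; P3 has no discharge-day obs
  expect_equal(nrow(tr), 3)
  expect_equal(colnames(tr), novelty_channels())

  # a cohort with no eligible survivors errors
  oc$event_type <- "death"
  oc$event_time <- oc$hospital_discharge_time
  bad <- cohort
  bad$outcomes <- oc
  expect_error(select_normality_training_set(bad), "larger cohort")
})

test_that("fitting requires enough complete vectors and positive variance", {
  set.seed(2)
  tr <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, novelty_channels()))
  expect_error(fit_normality_model(tr), "at least 50")
  tr2 <- matrix(rnorm(100 * 5), 100, 5,
                dimnames = list(NULL, novelty_channels()))
  tr2[, 3] <- 7
  expect_error(fit_normality_model(tr2), "zero-variance")
  # incomplete rows are dropped from training
  tr3 <- rbind(tr2, tr2)
  tr3[, 3] <- rnorm(200)
  tr3[1:120, 1] <- NA
  m <- fit_normality_model(tr3)
  expect_equal(nrow(m$points), 80)
})

test_that("novelty values match a brute-force double-loop oracle", {
  m <- toy_novelty_model(n = 150)
  set.seed(8)
  probes <- data.frame(heart_rate = rnorm(25, 80, 20),
                       systolic_bp = rnorm(25, 120, 25),
                       resp_rate = rnorm(25, 17, 5),
                       temperature = rnorm(25, 36.8, 1),
                       spo2 = rnorm(25, 96, 4))
  got <- novelty_value(m, probes)
  Z <- sweep(sweep(as.matrix(probes)[, m$channels], 2, m$centers), 2,
             m$scales, "/")
  want <- vapply(seq_len(nrow(Z)), function(i) {
    dens <- 0
    for (j in seq_len(nrow(m$points))) {
      dens <- dens + prod(dnorm((Z[i, ] - m$points[j, ]) / m$bandwidths)) /
        prod(m$bandwidths)
    }
    -log(dens / nrow(m$points))
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("marginalised novelty equals the KDE over observed channels only", {
  m <- toy_novelty_model(n = 120)
  probe <- data.frame(heart_rate = 95, systolic_bp = NA, resp_rate = 20,
                      temperature = 37.4, spo2 = NA)
  got <- novelty_value(m, probe)
  use <- c("heart_rate", "resp_rate", "temperature")
  z <- (unlist(probe[use]) - m$centers[use]) / m$scales[use]
  dens <- mean(vapply(seq_len(nrow(m$points)), function(j) {
    prod(dnorm((z - m$points[j, use]) / m$bandwidths[use])) /
      prod(m$bandwidths[use])
  }, numeric(1)))
  expect_equal(got, -log(dens), tolerance = 1e-10)

  all_na <- data.frame(heart_rate = NA, systolic_bp = NA, resp_rate = NA,
                       temperature = NA, spo2 = NA)
  expect_error(novelty_value(m, all_na), "all channels missing")
  expect_error(novelty_value(m, probe, missing_policy = "strict"), "missing")
})

test_that("kernel density integrates to one over a 5-D quadrature grid", {
  m <- toy_novelty_model(n = 60)
  # Riemann quadrature in the normalised coordinates the density lives in
  grid1 <- seq(-5, 5, by = 0.5)
  gg <- as.matrix(expand.grid(grid1, grid1, grid1, grid1, grid1))
  colnames(gg) <- m$channels
  probe <- sweep(sweep(gg, 2, m$scales, "*"), 2, m$centers, "+")
  nv <- novelty_value(m, as.data.frame(probe))
  dz <- grid1[2] - grid1[1]
  mass <- sum(exp(-nv)) * dz^5
  expect_equal(mass, 1, tolerance = 0.02)
})

test_that("novelty is invariant to channel order and training multiplicity", {
  m <- toy_novelty_model(n = 100)
  probe <- data.frame(heart_rate = 90, systolic_bp = 110, resp_rate = 22,
                      temperature = 37.2, spo2 = 94)
  shuffled <- probe[, c(4, 1, 5, 2, 3)]
  expect_equal(novelty_value(m, probe), novelty_value(m, shuffled))

  # duplicating every training point rescales nothing
  m2 <- m
  m2$points <- rbind(m$points, m$points)
  expect_equal(novelty_value(m2, probe), novelty_value(m, probe),
               tolerance = 1e-12)
})

test_that("calibrated scores are monotone in novelty and hit the extremes", {
  m <- toy_novelty_model(n = 200)
  set.seed(3)
  probes <- data.frame(heart_rate = seq(80, 200, length.out = 30),
                       systolic_bp = 120, resp_rate = 17,
                       temperature = 36.8, spo2 = 96)
  nv <- novelty_value(m, probes)
  sc <- rs2_score(m, probes)
  expect_true(all(sc >= 0 & sc <= 1))
  o <- order(nv)
  expect_true(all(diff(sc[o]) >= 0))

  # gross outlier beats all training novelty values
  expect_gt(rs2_score(m, data.frame(heart_rate = 170, systolic_bp = 75,
                                    resp_rate = 38, temperature = 36.8,
                                    spo2 = 96)), 0.99)
  # the most typical training point scores near 0; the median near 0.5
  i_min <- which.min(m$calibration)
  raw <- sweep(sweep(m$points, 2, m$scales, "*"), 2, m$centers, "+")
  typical <- as.data.frame(raw)[which.min(novelty_value(m, as.data.frame(raw))), ]
  expect_lt(rs2_score(m, typical), 0.02)
  med_i <- which(rank(novelty_value(m, as.data.frame(raw)),
                      ties.method = "first") == 100)
  expect_equal(rs2_score(m, as.data.frame(raw)[med_i, ]), 0.5,
               tolerance = 0.01)
})

test_that("refit with identical data and seed is bit-identical and JSON round-trips", {
  set.seed(31)
  tr <- matrix(rnorm(300 * 5), 300, 5, dimnames = list(NULL, novelty_channels()))
  m1 <- fit_normality_model(tr, seed = 5, max_points = 100)
  m2 <- fit_normality_model(tr, seed = 5, max_points = 100)
  expect_identical(m1, m2)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m1, f)
  m3 <- read_model(f)
  probe <- data.frame(heart_rate = tr[1, 1], systolic_bp = tr[1, 2],
                      resp_rate = tr[1, 3], temperature = tr[1, 4],
                      spo2 = tr[1, 5])
  expect_equal(rs2_score(m3, probe), rs2_score(m1, probe), tolerance = 1e-12)
})
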