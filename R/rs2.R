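#' Select the vital-sign normality training set
#'
#' The normality model is trained on observation sets recorded on the
#' calendar day of hospital discharge, restricted to admissions that
#' survived to discharge with no adverse event (no in-hospital death, never
#' readmitted to the ICU). These observations represent patients well enough
#' to leave hospital and anchor what "physiologically normal" means for this
#' population.
#'
#' @param cohort a [cohort_tables()] object with linked outcomes.
#' @param channels vital-sign columns used (default the five continuous
#'   vitals).
#' @return numeric matrix (observation sets x channels), possibly with NAs.
#' @export
select_normality_training_set <- function(cohort,
                                          channels = novelty_channels()) {
  oc <- cohort$outcomes
  ok_ids <- oc$admission_id[oc$event_type == "none" &
                              !is.na(oc$hospital_discharge_time)]
  obs <- cohort$observations
  obs <- obs[obs$admission_id %in% ok_ids, , drop = FALSE]
  m <- match(obs$admission_id, oc$admission_id)
  dis_day <- floor(oc$hospital_discharge_time[m] / 1440)
  obs_day <- floor(obs$obs_time / 1440)
  sel <- obs[obs_day == dis_day, , drop = FALSE]
  if (!nrow(sel)) {
    stop("no discharge-day observations from event-free admissions; ",
         "a larger cohort is needed to train the normality model")
  }
  as.matrix(sel[, channels, drop = FALSE])
}

#' Channels used by the vital-sign normality model
#' @return character vector of the five continuous vitals.
#' @export
novelty_channels <- function() {
  c("heart_rate", "systolic_bp", "resp_rate", "temperature", "spo2")
}

#' Fit the one-class vital-sign normality model
#'
#' Fits a product-Gaussian kernel density estimator over z-normalised
#' complete vital-sign vectors. Novelty is the negative log density; the
#' model stores the sorted novelty values of its own training points as an
#' empirical calibration distribution so that scores can be mapped to \[0, 1\]
#' ([rs2_score()]). Incomplete training vectors are dropped. Training is
#' capped at `max_points` vectors by seeded subsampling to bound scoring
#' cost.
#'
#' @param training numeric matrix (observation sets x channels).
#' @param bandwidth_rule function(Z) returning per-channel bandwidths for a
#'   normalised training matrix; default [silverman_bandwidth()].
#' @param seed integer seed (subsampling only).
#' @param max_points training-set size cap (default 10000).
#' @param min_points minimum complete vectors required (default 50).
#' @return object of class `novelty_model`.
#' @export
fit_normality_model <- function(training, bandwidth_rule = silverman_bandwidth,
                                seed = 1, max_points = 10000,
                                min_points = 50) {
  training <- as.matrix(training)
  cc <- complete.cases(training)
  training <- training[cc, , drop = FALSE]
  if (nrow(training) < min_points) {
    stop("need at least ", min_points, " complete training vectors (got ",
         nrow(training), ")")
  }
  if (nrow(training) > max_points) {
    set.seed(seed)
    training <- training[sort(sample.int(nrow(training), max_points)), ,
                         drop = FALSE]
  }
  ctr <- colMeans(training)
  scl <- apply(training, 2, sd)
  if (any(scl == 0)) {
    stop("zero-variance channel: '", colnames(training)[scl == 0][1], "'")
  }
  Z <- sweep(sweep(training, 2, ctr), 2, scl, "/")
  h <- bandwidth_rule(Z)
  if (any(h <= 0)) stop("bandwidths must be strictly positive")
  model <- structure(list(channels = colnames(training),
                          centers = ctr, scales = scl,
                          bandwidths = h, points = Z,
                          calibration = NULL,
                          metadata = list(seed = seed,
                                          n_train = nrow(Z))),
                     class = "novelty_model")
  nov <- novelty_value(model, as.data.frame(training))
  model$calibration <- sort(nov)
  model
}

#' Silverman rule-of-thumb bandwidths for a multivariate Gaussian kernel
#'
#' \eqn{h_j = \sigma_j (4 / ((d + 2) n))^{1/(d+4)}} with `d` channels and `n`
#' training points.
#'
#' @param Z normalised training matrix.
#' @return positive numeric vector, one bandwidth per channel.
#' @export
silverman_bandwidth <- function(Z) {
  n <- nrow(Z); d <- ncol(Z)
  apply(Z, 2, sd) * (4 / ((d + 2) * n))^(1 / (d + 4))
}

#' @export
print.novelty_model <- function(x, ...) {
  cat("novelty_model:", length(x$channels), "channels,",
      nrow(x$points), "training points\n")
  invisible(x)
}

#' Novelty value of observation sets under the normality model
#'
#' Returns the negative log of the kernel density estimate at each
#' observation's normalised vitals. Under `missing_policy = "marginalise"`
#' (default), channels missing from an observation are dropped from both the
#' kernel and the probe, i.e. the marginal density of the observed channels
#' is used (exact for a product kernel). All-missing observations are an
#' error under "marginalise" and any missing channel is an error under
#' "strict".
#'
#' @param model a [fit_normality_model()] fit.
#' @param obs data.frame (or named list for one observation) containing the
#'   model's channels.
#' @param missing_policy "marginalise" or "strict".
#' @return numeric vector of novelty values (non-negative up to the additive
#'   log-normalisation constant; larger = more abnormal).
#' @export
novelty_value <- function(model, obs,
                          missing_policy = c("marginalise", "strict")) {
  missing_policy <- match.arg(missing_policy)
  if (!is.data.frame(obs)) obs <- as.data.frame(as.list(obs))
  P <- as.matrix(obs[, model$channels, drop = FALSE])
  Pz <- sweep(sweep(P, 2, model$centers), 2, model$scales, "/")
  miss <- is.na(Pz)
  if (missing_policy == "strict" && any(miss)) {
    stop("missing channel '",
         model$channels[which(miss, arr.ind = TRUE)[1, 2]],
         "' under strict missing policy")
  }
  all_missing <- rowSums(!miss) == 0
  if (any(all_missing)) {
    stop("observation with all channels missing at row ",
         which(all_missing)[1])
  }
  out <- rep(NA_real_, nrow(Pz))
  # group probes by missingness pattern so each group is one matrix op
  pat <- apply(miss, 1, function(r) paste(as.integer(r), collapse = ""))
  for (p in unique(pat)) {
    rows <- which(pat == p)
    use <- !miss[rows[1], ]
    out[rows] <- kde_neglog_density(Pz[rows, use, drop = FALSE],
                                    model$points[, use, drop = FALSE],
                                    model$bandwidths[use])
  }
  out
}

# -log of a product-Gaussian KDE, blocked for memory; probes x_z and training
# points t_z are already on the normalised scale.
kde_neglog_density <- function(x_z, t_z, h, block = 4096) {
  n <- nrow(t_z); d <- ncol(t_z)
  xs <- sweep(x_z, 2, h, "/")
  ts <- sweep(t_z, 2, h, "/")
  t_sq <- rowSums(ts^2)
  log_norm <- log(n) + d / 2 * log(2 * pi) + sum(log(h))
  out <- numeric(nrow(xs))
  for (s in seq(1, nrow(xs), by = block)) {
    e <- min(s + block - 1, nrow(xs))
    xb <- xs[s:e, , drop = FALSE]
    d2 <- outer(rowSums(xb^2), t_sq, "+") - 2 * tcrossprod(xb, ts)
    d2[d2 < 0] <- 0
    m <- apply(d2, 1, min)
    lse <- m / 2 - log(rowSums(exp(-(d2 - m) / 2)))
    out[s:e] <- lse + log_norm
  }
  out
}

#' Dynamic vital-sign risk score
#'
#' Maps a novelty value to \[0, 1\] by its position in the model's training
#' novelty distribution (empirical CDF with the midpoint convention for
#' ties): an observation as typical as the most typical training point
#' scores near 0 and one more novel than every training point scores 1.
#' Shares the probability scale of the static score so the two can be
#' blended ([compute_rsi()]).
#'
#' @inheritParams novelty_value
#' @return numeric vector in \[0, 1\].
#' @export
rs2_score <- function(model, obs,
                      missing_policy = c("marginalise", "strict")) {
  if (is.null(model$calibration)) stop("model is not calibrated")
  nov <- novelty_value(model, obs, missing_policy)
  cal <- model$calibration
  n <- length(cal)
  below <- findInterval(nov, cal)                       # count <= nov
  strictly_below <- findInterval(nov, cal, left.open = TRUE)  # count < nov
  score <- (strictly_below + (below - strictly_below) / 2) / n
  pmin(pmax(score, 0), 1)
}
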