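#' Label observation sets against an N-hour outcome window
#'
#' The unit of analysis is a vital-sign observation set: an observation is
#' positive if the admission's first event of the chosen endpoint occurs
#' within (0, N] hours after it, censored if it was recorded at or after the
#' event (first-event analysis), and negative otherwise. With
#' `censor_near_discharge = TRUE`, event-free observations within N hours of
#' hospital discharge are censored instead of negative.
#'
#' @param observations observations table (see [cohort_tables()]).
#' @param outcomes outcomes table.
#' @param N horizon in hours (> 0).
#' @param endpoint "compound" (death or readmission), "death" or
#'   "readmission".
#' @param censor_near_discharge censor event-free observations within N hours
#'   of hospital discharge (default FALSE: kept as negatives).
#' @return data.frame `admission_id`, `obs_time`, `t_to_event` (hours, NA if
#'   none), `label` (0/1, NA when censored), `censored` (logical),
#'   `horizon_n`.
#' @export
label_observations <- function(observations, outcomes, N,
                               endpoint = c("compound", "death",
                                            "readmission"),
                               censor_near_discharge = FALSE) {
  endpoint <- match.arg(endpoint)
  if (is.na(N) || N <= 0) stop("N must be a positive number of hours")
  obs <- as.data.frame(observations)
  oc <- as.data.frame(outcomes)
  m <- match(obs$admission_id, oc$admission_id)
  if (anyNA(m)) {
    stop("observation for admission with no outcome record: '",
         obs$admission_id[which(is.na(m))[1]], "'")
  }
  ev_type <- oc$event_type[m]
  ev_time <- oc$event_time[m]
  relevant <- switch(endpoint,
                     compound = ev_type %in% c("death", "readmission"),
                     death = ev_type == "death",
                     readmission = ev_type == "readmission")
  # censoring is driven by the FIRST event of any type: follow-up ends there
  post_event <- !is.na(ev_time) & obs$obs_time >= ev_time
  dt_h <- ifelse(relevant, (ev_time - obs$obs_time) / 60, NA_real_)
  label <- ifelse(!is.na(dt_h) & dt_h > 0 & dt_h <= N, 1, 0)
  censored <- post_event
  if (censor_near_discharge) {
    hd <- oc$hospital_discharge_time[m]
    near <- is.na(ev_time) & !is.na(hd) &
      (hd - obs$obs_time) / 60 <= N
    censored <- censored | near
  }
  label[censored] <- NA
  data.frame(admission_id = obs$admission_id, obs_time = obs$obs_time,
             t_to_event = dt_h, label = label, censored = censored,
             horizon_n = N, stringsAsFactors = FALSE)
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Probability that a randomly chosen positive scores above a randomly
#' chosen negative, with ties counted one half, computed from midranks.
#'
#' @param scores numeric scores (higher = more at risk).
#' @param labels binary labels.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.numeric(labels[keep])
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUROC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile bootstrap confidence interval with admission-level resampling
#'
#' Resamples whole admissions with replacement (repeated measurements from
#' one patient are correlated, so observation-level resampling would be
#' anti-conservative), recomputes the metric on each resample and returns
#' the 2.5 and 97.5 percentiles. Deterministic given `seed`.
#'
#' @param metric_fn function(data.frame) -> single number; may return NA or
#'   throw on degenerate resamples (tolerated on at most 10% of resamples).
#' @param data data.frame with an `admission_id` column.
#' @param B number of resamples (default 500).
#' @param seed integer seed.
#' @param probs percentile pair (default c(0.025, 0.975)).
#' @return named numeric c(low, high), with the resample values in attribute
#'   `"replicates"`.
#' @export
bootstrap_ci <- function(metric_fn, data, B = 500, seed = 1,
                         probs = c(0.025, 0.975)) {
  if (B < 2) stop("B must be at least 2")
  ids <- unique(data$admission_id)
  rows_of <- split(seq_len(nrow(data)), data$admission_id)
  set.seed(seed)
  vals <- vapply(seq_len(B), function(b) {
    take <- sample(ids, length(ids), replace = TRUE)
    idx <- unlist(rows_of[take], use.names = FALSE)
    tryCatch(metric_fn(data[idx, , drop = FALSE]),
             error = function(e) NA_real_)
  }, numeric(1))
  if (mean(is.na(vals)) > 0.10) {
    stop("metric undefined on more than 10% of bootstrap resamples")
  }
  ci <- quantile(vals, probs, na.rm = TRUE, names = FALSE, type = 7)
  structure(setNames(ci, c("low", "high")), replicates = vals)
}

#' Calibration report: Hosmer-Lemeshow C, Brier score, Cox regression
#'
#' The Hosmer-Lemeshow C statistic groups observations into `n_groups`
#' equal-count bins of predicted risk and sums
#' \eqn{(O_g - E_g)^2 / (E_g (1 - \bar p_g))} over groups, where O and E are
#' observed and expected event counts and \eqn{\bar p_g} the mean predicted
#' risk; groups whose expected event count is zero are merged upward with a
#' warning. The Brier score is the mean squared difference between predicted
#' probability and outcome. Cox's calibration regression refits the outcome
#' on the logit of the prediction by unpenalised maximum likelihood: an
#' intercept (alpha) near 0 and slope (beta) near 1 indicate good
#' calibration. Probabilities are clipped to \[1e-6, 1 - 1e-6\] before the
#' logit.
#'
#' @param probabilities predicted event probabilities in (0, 1).
#' @param labels binary outcomes.
#' @param n_groups number of risk groups for Hosmer-Lemeshow (default 10).
#' @return list `hosmer_lemeshow_c`, `brier`, `cox_alpha`, `cox_beta`.
#' @export
calibration_report <- function(probabilities, labels, n_groups = 10) {
  keep <- !is.na(probabilities) & !is.na(labels)
  p <- probabilities[keep]; y <- as.numeric(labels[keep])
  if (any(p <= 0 | p >= 1)) stop("probabilities must lie strictly in (0, 1)")
  brier <- mean((p - y)^2)
  pc <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  fit <- glm(y ~ qlogis(pc), family = binomial())
  cox_alpha <- unname(coef(fit)[1])
  cox_beta <- unname(coef(fit)[2])
  # equal-count groups by predicted risk, stable in the original order
  o <- order(p)
  grp_sorted <- ceiling(seq_along(o) / (length(o) / n_groups))
  grp <- integer(length(p)); grp[o] <- pmin(grp_sorted, n_groups)
  obs_g <- tapply(y, grp, sum)
  exp_g <- tapply(p, grp, sum)
  pbar_g <- tapply(p, grp, mean)
  if (any(exp_g == 0)) {
    warning("merging risk group(s) with zero expected events")
    zero <- which(exp_g == 0)
    for (z in zero) {
      target <- if (z < length(exp_g)) z + 1 else z - 1
      obs_g[target] <- obs_g[target] + obs_g[z]
      exp_g[target] <- exp_g[target] + exp_g[z]
    }
    obs_g <- obs_g[-zero]; exp_g <- exp_g[-zero]; pbar_g <- pbar_g[-zero]
  }
  hl <- sum((obs_g - exp_g)^2 / (exp_g * (1 - pbar_g)))
  list(hosmer_lemeshow_c = hl, brier = brier,
       cox_alpha = cox_alpha, cox_beta = cox_beta)
}

#' Trigger-burden curve
#'
#' For each threshold: how many observation sets trigger (score at or above
#' the threshold), how many of those are true positives (followed by an
#' event within the horizon) and the burden, i.e. triggers per true-positive
#' trigger (infinite and flagged when no true positive triggers).
#'
#' @param scores numeric scores.
#' @param labels binary labels (NA = censored, dropped).
#' @param thresholds sorted numeric thresholds.
#' @param per_event alternative normalisation: triggers per correctly
#'   flagged EVENT (an admission-level column `admission_id` must then be
#'   supplied via `admission_id`).
#' @param admission_id admission ids aligned with scores (per-event mode).
#' @return data.frame threshold, triggers, true_positive, burden,
#'   burden_defined.
#' @export
trigger_burden <- function(scores, labels, thresholds, per_event = FALSE,
                           admission_id = NULL) {
  if (is.unsorted(thresholds)) stop("thresholds must be sorted increasingly")
  keep <- !is.na(labels) & !is.na(scores)
  scores <- scores[keep]; labels <- as.numeric(labels[keep])
  if (per_event) {
    if (is.null(admission_id)) stop("per_event mode needs admission_id")
    admission_id <- admission_id[keep]
  }
  out <- lapply(thresholds, function(th) {
    trig <- scores >= th
    tp <- sum(trig & labels == 1)
    denom <- if (per_event) {
      length(unique(admission_id[trig & labels == 1]))
    } else tp
    data.frame(threshold = th, triggers = sum(trig), true_positive = tp,
               burden = if (denom > 0) sum(trig) / denom else Inf,
               burden_defined = denom > 0)
  })
  do.call(rbind, out)
}

#' Full evaluation report for one scoring system
#'
#' Windowed AUROC with grouped percentile-bootstrap confidence intervals per
#' horizon, calibration statistics (only when the scores are probabilities)
#' and a trigger-burden curve at the 24 h horizon.
#'
#' @param scores numeric scores aligned with `observations` rows.
#' @param observations observations table.
#' @param outcomes outcomes table.
#' @param horizons outcome windows in hours (default c(12, 24, 36, 48, 72)).
#' @param endpoint outcome definition (see [label_observations()]).
#' @param B bootstrap resamples (default 500).
#' @param seed integer seed.
#' @param calibration compute calibration statistics (requires probability
#'   scores in (0,1); default FALSE).
#' @param burden_thresholds thresholds for the burden curve, or NULL for the
#'   sorted unique scores' deciles.
#' @return list of class `evaluation_report`.
#' @export
evaluate_scores <- function(scores, observations, outcomes,
                            horizons = c(12, 24, 36, 48, 72),
                            endpoint = "compound", B = 500, seed = 1,
                            calibration = FALSE,
                            burden_thresholds = NULL) {
  per_h <- lapply(horizons, function(N) {
    lab <- label_observations(observations, outcomes, N, endpoint)
    d <- data.frame(admission_id = lab$admission_id, score = scores,
                    label = lab$label)[!lab$censored, , drop = FALSE]
    point <- auroc(d$score, d$label)
    ci <- bootstrap_ci(function(dd) auroc(dd$score, dd$label), d,
                       B = B, seed = seed)
    data.frame(horizon = N, auroc = point, ci_low = ci[["low"]],
               ci_high = ci[["high"]], n_obs = nrow(d),
               n_pos = sum(d$label == 1))
  })
  auroc_tab <- do.call(rbind, per_h)
  lab24 <- label_observations(observations, outcomes, 24, endpoint)
  ok <- !lab24$censored
  calib <- if (calibration) {
    calibration_report(pmin(pmax(scores[ok], 1e-6), 1 - 1e-6), lab24$label[ok])
  } else NULL
  if (is.null(burden_thresholds)) {
    burden_thresholds <- unique(quantile(scores[ok], seq(0.1, 0.9, 0.1),
                                         names = FALSE))
  }
  burden <- trigger_burden(scores[ok], lab24$label[ok],
                           sort(burden_thresholds))
  structure(list(auroc = auroc_tab, calibration = calib, burden = burden,
                 endpoint = endpoint),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report (endpoint:", x$endpoint, ")\n")
  print(x$auroc, row.names = FALSE)
  invisible(x)
}

#' Compare scoring systems on identical labelled observation sets
#'
#' Builds the systems x horizons x endpoints comparison table: AUROC with
#' grouped bootstrap CI per cell. Every system is evaluated on exactly the
#' same labelled observation sets; the attribute `"audit"` records per
#' (horizon, endpoint) the number of observations and positives shared by
#' all systems.
#'
#' @param scores data.frame with `admission_id`, `obs_time` and one numeric
#'   column per system (e.g. from [score_cohort_systems()]).
#' @param observations observations table aligned row-by-row with `scores`.
#' @param outcomes outcomes table.
#' @param systems character vector of system columns to compare.
#' @param horizons outcome windows in hours.
#' @param endpoints subset of c("compound", "death", "readmission").
#' @param B bootstrap resamples (0 skips the CIs).
#' @param seed integer seed.
#' @return data.frame system, horizon, endpoint, auroc, ci_low, ci_high,
#'   n_obs, n_pos; audit table in attribute `"audit"`.
#' @export
compare_systems <- function(scores, observations, outcomes,
                            systems = setdiff(names(scores),
                                              c("admission_id", "obs_time")),
                            horizons = c(12, 24, 36, 48, 72),
                            endpoints = c("compound", "death", "readmission"),
                            B = 500, seed = 1) {
  stopifnot(nrow(scores) == nrow(observations))
  rows <- list(); audit <- list()
  for (ep in endpoints) {
    for (N in horizons) {
      lab <- label_observations(observations, outcomes, N, ep)
      keep <- !lab$censored
      audit[[paste(ep, N)]] <- data.frame(endpoint = ep, horizon = N,
                                          n_obs = sum(keep),
                                          n_pos = sum(lab$label[keep] == 1))
      for (sys in systems) {
        d <- data.frame(admission_id = lab$admission_id[keep],
                        score = scores[[sys]][keep],
                        label = lab$label[keep])
        point <- tryCatch(auroc(d$score, d$label), error = function(e) NA_real_)
        ci <- if (B > 0 && !is.na(point)) {
          bootstrap_ci(function(dd) auroc(dd$score, dd$label), d,
                       B = B, seed = seed)
        } else c(low = NA_real_, high = NA_real_)
        rows[[length(rows) + 1]] <- data.frame(
          system = sys, horizon = N, endpoint = ep, auroc = point,
          ci_low = ci[["low"]], ci_high = ci[["high"]],
          n_obs = nrow(d), n_pos = sum(d$label == 1))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "audit") <- do.call(rbind, audit)
  out
}

#' Score a cohort's observation sets with every system
#'
#' Computes, for each ward observation set, the four published EWS totals
#' and (when models are supplied) RS1, RS2 and RSI, on identical rows.
#'
#' @param cohort a [cohort_tables()] object.
#' @param rs1_model optional [fit_rs1()] model (with `feature_spec` attribute
#'   or supplied via `spec`).
#' @param novelty_model optional [fit_normality_model()] model.
#' @param fusion optional [fusion_parameters()].
#' @param spec feature spec for RS1 scoring (default
#'   [default_feature_spec()]).
#' @param systems EWS systems to include.
#' @return data.frame `admission_id`, `obs_time`, one column per system.
#' @export
score_cohort_systems <- function(cohort, rs1_model = NULL,
                                 novelty_model = NULL,
                                 fusion = fusion_parameters(),
                                 spec = default_feature_spec(),
                                 systems = c("MEWS", "SEWS", "NEWS", "CEWS")) {
  obs <- cohort$observations
  out <- data.frame(admission_id = obs$admission_id, obs_time = obs$obs_time,
                    stringsAsFactors = FALSE)
  for (sys in systems) {
    tab <- load_scoring_table(sys)
    out[[sys]] <- score_ews_cohort(tab, obs)
  }
  if (!is.null(novelty_model)) {
    out$RS2 <- rs2_score(novelty_model, obs)
  }
  if (!is.null(rs1_model)) {
    X <- extract_feature_matrix(cohort, spec)
    p <- predict_rs1(rs1_model, X)
    out$RS1 <- p[match(obs$admission_id, rownames(X))]
  }
  if (!is.null(rs1_model) && !is.null(novelty_model)) {
    adm <- cohort$admissions
    dis <- adm$icu_discharge_time[match(obs$admission_id, adm$admission_id)]
    t_h <- hours_between(dis, obs$obs_time)
    out$RSI <- compute_rsi(out$RS1, out$RS2, t_h, fusion)
  }
  out
}
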