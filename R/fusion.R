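#' Fusion parameters for the Risk Score Index
#'
#' The Risk Score Index (RSI) blends the static discharge risk RS1 and the
#' dynamic vital-sign risk RS2 with a weight that shifts linearly from RS1 to
#' RS2 as time since ICU discharge elapses:
#' \deqn{RSI(t) = \beta (1 - \tau) \, RS_1 + \tau \, RS_2, \quad
#'       \tau = \min(t, T_{max}) / T_{max}}
#' with `t` in hours. `beta` adjusts the weight of the static score; beyond
#' `t_max` hours the blend is entirely RS2 (tau is clamped at 1).
#'
#' @param beta non-negative weight on the static score (default 1).
#' @param t_max blend horizon in hours (default 72).
#' @return object of class `fusion_parameters`.
#' @export
fusion_parameters <- function(beta = 1, t_max = 72) {
  if (is.na(beta) || beta < 0) stop("beta must be non-negative")
  if (is.na(t_max) || t_max <= 0) stop("t_max must be positive")
  structure(list(beta = beta, t_max = t_max), class = "fusion_parameters")
}

#' @export
print.fusion_parameters <- function(x, ...) {
  cat("fusion_parameters: beta = ", x$beta, ", t_max = ", x$t_max, " h\n",
      sep = "")
  invisible(x)
}

#' Compute the Risk Score Index
#'
#' Vectorised over its first three arguments (recycled to common length).
#'
#' @param rs1 static risk in \[0, 1\].
#' @param rs2 dynamic risk in \[0, 1\].
#' @param t hours since ICU discharge (>= 0).
#' @param params a [fusion_parameters()] object.
#' @return numeric RSI values.
#' @export
compute_rsi <- function(rs1, rs2, t, params = fusion_parameters()) {
  if (any(is.na(rs1)) || any(rs1 < 0 | rs1 > 1)) {
    stop("rs1 must lie in [0, 1]")
  }
  if (any(is.na(rs2)) || any(rs2 < 0 | rs2 > 1)) {
    stop("rs2 must lie in [0, 1]")
  }
  if (any(t < 0, na.rm = TRUE)) stop("t must be non-negative")
  tau <- pmin(t, params$t_max) / params$t_max
  params$beta * (1 - tau) * rs1 + tau * rs2
}

#' Score a full post-ICU risk trajectory for one admission
#'
#' Computes the static risk once at ICU discharge and the dynamic risk at
#' every ward observation set, then blends them with [compute_rsi()]. The
#' result has one row per observation set, ordered by time.
#'
#' @param admission one-row admissions data.frame.
#' @param observations this admission's ward observation sets.
#' @param rs1_value the admission's static risk (a probability), e.g. from
#'   [predict_rs1()].
#' @param novelty_model a fitted [fit_normality_model()].
#' @param params a [fusion_parameters()] object.
#' @return data.frame `admission_id`, `t` (hours since ICU discharge),
#'   `rs1`, `rs2`, `rsi`, of class `risk_trajectory`.
#' @export
score_trajectory <- function(admission, observations, rs1_value,
                             novelty_model, params = fusion_parameters()) {
  admission <- as.data.frame(admission)
  obs <- as.data.frame(observations)
  obs <- obs[obs$admission_id == admission$admission_id, , drop = FALSE]
  if (!nrow(obs)) {
    out <- data.frame(admission_id = character(), t = numeric(),
                      rs1 = numeric(), rs2 = numeric(), rsi = numeric())
    class(out) <- c("risk_trajectory", "data.frame")
    return(out)
  }
  t_h <- hours_between(admission$icu_discharge_time, obs$obs_time)
  if (any(t_h < 0)) {
    stop("observation predates ICU discharge for admission '",
         admission$admission_id, "'")
  }
  o <- order(t_h)
  obs <- obs[o, , drop = FALSE]
  t_h <- t_h[o]
  rs2 <- rs2_score(novelty_model, obs)
  out <- data.frame(admission_id = obs$admission_id, t = t_h,
                    rs1 = rs1_value, rs2 = rs2,
                    rsi = compute_rsi(rs1_value, rs2, t_h, params))
  class(out) <- c("risk_trajectory", "data.frame")
  out
}

#' Optimise the fusion parameters by grid search
#'
#' Exhaustive search over a (beta, t_max) grid maximising the mean
#' patient-grouped cross-validated AUROC of the RSI for the compound outcome
#' within `horizon_hours` of an observation. Folds are assigned at the
#' admission level so no admission's observations span folds. Ties are
#' broken towards smaller beta, then smaller t_max.
#'
#' @param scored data.frame with columns `admission_id`, `t` (hours since
#'   ICU discharge), `rs1`, `rs2`, `label` (binary: event within the
#'   horizon) and `censored` (logical), e.g. from [label_observations()]
#'   joined to scores.
#' @param beta_grid candidate beta values.
#' @param tmax_grid candidate t_max values (hours).
#' @param cv_folds number of admission-level folds (default 5).
#' @param seed integer seed for fold assignment.
#' @return list with `params` (the chosen [fusion_parameters()]) and `grid`
#'   (data.frame beta, t_max, cv_auroc).
#' @export
optimize_fusion_params <- function(scored,
                                   beta_grid = seq(0.25, 2, by = 0.25),
                                   tmax_grid = c(24, 48, 72, 96, 120, 168, 336),
                                   cv_folds = 5, seed = 1) {
  if (!length(beta_grid) || !length(tmax_grid)) {
    stop("beta_grid and tmax_grid must be non-empty")
  }
  scored <- scored[!scored$censored & !is.na(scored$label), , drop = FALSE]
  ids <- unique(scored$admission_id)
  set.seed(seed)
  fold_of <- setNames(sample(rep_len(seq_len(cv_folds), length(ids))), ids)
  fold <- fold_of[scored$admission_id]
  grid <- expand.grid(beta = beta_grid, t_max = tmax_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$cv_auroc <- NA_real_
  for (g in seq_len(nrow(grid))) {
    params <- fusion_parameters(grid$beta[g], grid$t_max[g])
    rsi <- compute_rsi(scored$rs1, scored$rs2, scored$t, params)
    aucs <- vapply(seq_len(cv_folds), function(k) {
      sel <- fold == k
      yk <- scored$label[sel]
      if (length(unique(yk)) < 2) return(NA_real_)
      auroc(rsi[sel], yk)
    }, numeric(1))
    grid$cv_auroc[g] <- mean(aucs, na.rm = TRUE)
  }
  # ties: smaller beta first, then smaller t_max (grid is ordered that way
  # within expand.grid by beta fastest; re-order explicitly to be safe)
  o <- order(-grid$cv_auroc, grid$beta, grid$t_max)
  best <- grid[o[1], ]
  list(params = fusion_parameters(best$beta, best$t_max), grid = grid)
}
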