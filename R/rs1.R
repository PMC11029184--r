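#' Feature specification grammar for ICU-stay summaries
#'
#' The static risk model is built over per-admission summaries of the ICU
#' stay. A feature specification is a data.frame with one row per feature:
#' `name` (unique), `channel` (an ICU channel name, or a static column of the
#' admissions table when `operator = "static"`), `operator` and
#' `window_hours`. Supported operators over a channel's (time, value) series:
#'
#' * `last`, `min`, `max`, `mean`, `slope` — summary over the final
#'   `window_hours` of the ICU stay (`slope` is the least-squares slope per
#'   hour; a single point gives a missing slope, constant values give 0);
#' * `present` — 1 if an intervention channel was active at any point during
#'   the final `window_hours` (step-valued 0/1 channels; the state carried
#'   into the window counts), else 0;
#' * `min`/`max` with `window_hours = NA` — whole-stay extremes;
#' * `static` — the admission-level column named by `channel` (`sex` is coded
#'   female = 1, male = 0; `icu_los_days` derives length of stay in days from
#'   the admission timestamps).
#'
#' @param spec data.frame as above.
#' @return the validated spec, with class `feature_spec`.
#' @export
feature_spec <- function(spec) {
  spec <- as.data.frame(spec)
  needed <- c("name", "channel", "operator", "window_hours")
  if (!all(needed %in% names(spec))) {
    stop("feature spec needs columns: ", paste(needed, collapse = ", "))
  }
  if (anyDuplicated(spec$name)) {
    stop("duplicate feature name: '", spec$name[duplicated(spec$name)][1], "'")
  }
  ok_ops <- c("last", "min", "max", "mean", "slope", "present", "static")
  if (!all(spec$operator %in% ok_ops)) {
    stop("unknown operator: '", setdiff(spec$operator, ok_ops)[1], "'")
  }
  structure(spec, class = c("feature_spec", "data.frame"))
}

#' Default feature specification over the synthetic generator's channels
#'
#' Builds a specification of about 160 candidate features spanning the
#' variable categories a discharge-risk model draws on: cardiorespiratory
#' physiology, renal and hepatic function, plasma electrolytes, haematology
#' and inflammation markers, and treatment intensity (ventilation,
#' vasopressors, renal replacement), plus demographics and length of stay.
#' Continuous channels contribute last/min/max/mean/slope over the final
#' 24 h and whole-stay min/max; interventions contribute presence in the
#' final 24 h and during the whole stay.
#'
#' @param window_hours summary window before ICU discharge (default 24).
#' @return a [feature_spec()].
#' @export
default_feature_spec <- function(window_hours = 24) {
  cont <- c("hr", "sbp", "rr", "temp", "spo2", "fio2",
            "creatinine", "urea", "bilirubin", "albumin", "sodium",
            "potassium", "lactate", "ph", "glucose",
            "crp", "wbc", "hgb", "hct", "platelets")
  interv <- c("ventilation", "vasopressor", "rrt")
  rows <- list()
  for (ch in cont) {
    for (op in c("last", "min", "max", "mean", "slope")) {
      rows[[length(rows) + 1]] <- data.frame(
        name = paste0(ch, "_", op, "_last", window_hours, "h"),
        channel = ch, operator = op, window_hours = window_hours)
    }
    for (op in c("min", "max")) {
      rows[[length(rows) + 1]] <- data.frame(
        name = paste0(ch, "_", op, "_stay"),
        channel = ch, operator = op, window_hours = NA_real_)
    }
  }
  for (ch in interv) {
    rows[[length(rows) + 1]] <- data.frame(
      name = paste0(ch, "_last", window_hours, "h"),
      channel = ch, operator = "present", window_hours = window_hours)
    rows[[length(rows) + 1]] <- data.frame(
      name = paste0(ch, "_stay"),
      channel = ch, operator = "present", window_hours = NA_real_)
  }
  for (st in c("age", "sex", "icu_los_days")) {
    rows[[length(rows) + 1]] <- data.frame(
      name = st, channel = st, operator = "static",
      window_hours = NA_real_)
  }
  feature_spec(do.call(rbind, rows))
}

summarise_series <- function(tt, vv, op) {
  keep <- !is.na(vv)
  tt <- tt[keep]; vv <- vv[keep]
  if (!length(vv)) return(NA_real_)
  switch(op,
         last = vv[which.max(tt)],
         min = min(vv),
         max = max(vv),
         mean = mean(vv),
         slope = {
           if (length(vv) < 2) return(NA_real_)
           th <- tt / 60
           if (sd(vv) == 0) return(0)
           sum((th - mean(th)) * (vv - mean(vv))) / sum((th - mean(th))^2)
         },
         stop("unknown operator '", op, "'"))
}

#' Extract the ICU feature vector for one admission
#'
#' Applies a [feature_spec()] to an admission's channel recordings and static
#' fields, producing one value (or missing flag) per feature together with
#' its provenance.
#'
#' @param admission one-row admissions data.frame (may carry extra static
#'   columns).
#' @param channels channel rows for this admission (`channel`, `time`,
#'   `value`).
#' @param spec a [feature_spec()].
#' @return list with `admission_id`, `values` (named numeric, NA = missing)
#'   and `provenance` (the feature-specification rows, same order).
#' @export
extract_features <- function(admission, channels, spec) {
  admission <- as.data.frame(admission)
  spec <- feature_spec(spec)
  dis <- admission$icu_discharge_time
  vals <- setNames(rep(NA_real_, nrow(spec)), spec$name)
  by_channel <- split(seq_len(nrow(channels)), channels$channel)
  for (i in seq_len(nrow(spec))) {
    op <- spec$operator[i]
    ch <- spec$channel[i]
    if (op == "static") {
      vals[i] <- switch(ch,
        icu_los_days = (admission$icu_discharge_time -
                          admission$icu_admit_time) / 1440,
        sex = {
          s <- admission$sex
          if (is.na(s)) NA_real_ else as.numeric(tolower(s) %in% c("f", "female"))
        },
        {
          if (!ch %in% names(admission)) {
            stop("static feature '", ch, "' not found in admission record")
          }
          v <- admission[[ch]]
          if (is.na(v)) NA_real_ else as.numeric(v)
        })
      next
    }
    rows <- by_channel[[ch]]
    if (is.null(rows) && op != "present") {
      # unseen channel name is a spec error only if no channel table at all
      # mentions it; an admission simply lacking data yields missing
      vals[i] <- NA_real_
      next
    }
    tt <- channels$time[rows]
    vv <- channels$value[rows]
    w <- spec$window_hours[i]
    if (op == "present") {
      if (is.null(rows)) { vals[i] <- 0; next }
      start <- if (is.na(w)) -Inf else dis - w * 60
      in_win <- tt >= start & tt <= dis
      state_in <- {
        before <- which(tt < start)
        if (length(before)) vv[before[which.max(tt[before])]] else 0
      }
      vals[i] <- as.numeric(state_in > 0 || any(vv[in_win] > 0, na.rm = TRUE))
    } else {
      if (!is.na(w)) {
        in_win <- tt >= dis - w * 60 & tt <= dis
        tt <- tt[in_win]; vv <- vv[in_win]
      }
      vals[i] <- summarise_series(tt, vv, op)
    }
  }
  list(admission_id = admission$admission_id, values = vals,
       provenance = spec)
}

#' Extract the ICU feature matrix for a cohort
#'
#' Vectorised companion of [extract_features()]: one row per admission, one
#' column per feature in the specification, `NA` marking missing values.
#'
#' @param cohort a [cohort_tables()] object.
#' @param spec a [feature_spec()] (default [default_feature_spec()]).
#' @return numeric matrix with admission ids as rownames.
#' @export
extract_feature_matrix <- function(cohort, spec = default_feature_spec()) {
  spec <- feature_spec(spec)
  adm <- cohort$admissions
  ch <- data.table::as.data.table(cohort$channels)
  known <- unique(c(ch$channel, "age", "sex", "icu_los_days",
                    names(adm)))
  bad <- setdiff(unique(spec$channel[spec$operator != "present"]), known)
  if (length(bad)) stop("feature spec references unknown channel '", bad[1], "'")
  X <- matrix(NA_real_, nrow(adm), nrow(spec),
              dimnames = list(adm$admission_id, spec$name))
  dis <- setNames(adm$icu_discharge_time, adm$admission_id)
  if (nrow(ch)) ch[, dis_time := dis[admission_id]]
  for (i in seq_len(nrow(spec))) {
    op <- spec$operator[i]
    cname <- spec$channel[i]
    w <- spec$window_hours[i]
    if (op == "static") {
      X[, i] <- switch(cname,
        icu_los_days = (adm$icu_discharge_time - adm$icu_admit_time) / 1440,
        sex = as.numeric(tolower(adm$sex) %in% c("f", "female")),
        as.numeric(adm[[cname]]))
      next
    }
    if (!nrow(ch)) next
    sub <- ch[channel == cname]
    if (!nrow(sub)) { if (op == "present") X[, i] <- 0; next }
    if (op == "present") {
      start <- if (is.na(w)) -Inf else sub$dis_time - w * 60
      agg <- sub[, {
        st <- if (is.na(w)) -Inf else dis_time[1] - w * 60
        before <- time < st
        carried <- if (any(before)) value[before][which.max(time[before])] else 0
        in_win <- time >= st & time <= dis_time[1]
        .(present = as.numeric(carried > 0 ||
                                 any(value[in_win] > 0, na.rm = TRUE)))
      }, by = admission_id]
      X[, i] <- 0
      X[agg$admission_id, i] <- agg$present
    } else {
      if (!is.na(w)) sub <- sub[time >= dis_time - w * 60 & time <= dis_time]
      if (!nrow(sub)) next
      agg <- sub[!is.na(value),
                 .(val = summarise_series(time, value, op)),
                 by = admission_id]
      X[agg$admission_id, i] <- agg$val
    }
  }
  X
}

#' Impute and standardise a feature matrix
#'
#' In fit mode, computes per-feature training medians (used to fill missing
#' values) and post-imputation means and standard deviations (used to
#' z-score); features that are entirely missing or have zero variance are
#' dropped with a warning and recorded. In apply mode the stored parameters
#' are used unchanged, so new data cannot leak into the scaling.
#'
#' @param X numeric matrix (admissions x features) with NA for missing.
#' @param params NULL to fit, or the `params` element of a previous fit to
#'   apply.
#' @return list with `design` (complete, z-scored matrix) and `params`
#'   (medians, centers, scales, kept feature names, dropped feature names).
#' @export
impute_and_standardise <- function(X, params = NULL) {
  X <- as.matrix(X)
  if (is.null(params)) {
    med <- apply(X, 2, median, na.rm = TRUE)
    filled <- X
    for (j in seq_len(ncol(X))) filled[is.na(filled[, j]), j] <- med[j]
    ctr <- colMeans(filled)
    scl <- apply(filled, 2, sd)
    drop <- is.na(med) | is.na(scl) | scl == 0
    if (any(drop)) {
      warning("dropping ", sum(drop),
              " all-missing or zero-variance feature(s): ",
              paste(head(colnames(X)[drop], 5), collapse = ", "),
              if (sum(drop) > 5) ", ...")
    }
    keep <- colnames(X)[!drop]
    params <- list(medians = med[keep], centers = ctr[keep],
                   scales = scl[keep], features = keep,
                   dropped = colnames(X)[drop])
    filled <- filled[, keep, drop = FALSE]
    design <- sweep(sweep(filled, 2, params$centers), 2, params$scales, "/")
  } else {
    missing_cols <- setdiff(params$features, colnames(X))
    if (length(missing_cols)) {
      stop("feature '", missing_cols[1], "' absent from the matrix")
    }
    Xk <- X[, params$features, drop = FALSE]
    for (j in seq_along(params$features)) {
      Xk[is.na(Xk[, j]), j] <- params$medians[j]
    }
    design <- sweep(sweep(Xk, 2, params$centers), 2, params$scales, "/")
  }
  list(design = design, params = params)
}

#' Fit the static discharge-risk model (L1-regularised logistic regression)
#'
#' Fits a lasso-penalised logistic regression of the compound outcome
#' (in-hospital death or ICU readmission at any time after ICU discharge) on
#' ICU-stay features. Missing values are median-imputed and features
#' z-scored ([impute_and_standardise()]); the penalty strength is chosen by
#' stratified k-fold cross-validation maximising the mean held-out AUROC
#' over a log-spaced grid whose largest value yields the null (all-zero)
#' model; the final model is refitted on all data at the chosen strength.
#' Deterministic given `seed`.
#'
#' @param X numeric feature matrix with NAs (admissions x features).
#' @param y binary outcome vector (1 = adverse event).
#' @param lambda_grid decreasing penalty grid, or NULL to derive a 30-point
#'   log-spaced grid from the data.
#' @param cv_folds number of stratified folds (default 5).
#' @param seed integer seed for fold assignment.
#' @param n_lambda grid size when `lambda_grid` is NULL.
#' @return object of class `rs1_model`: intercept, named non-zero
#'   coefficients, chosen `lambda`, preprocessing parameters, CV summary and
#'   metadata.
#' @export
fit_rs1 <- function(X, y, lambda_grid = NULL, cv_folds = 5, seed = 1,
                    n_lambda = 30) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2 || sum(y) < 2 || sum(1 - y) < 2) {
    stop("need at least 2 events and 2 non-events to fit the model")
  }
  prep <- impute_and_standardise(X)
  Z <- prep$design
  if (ncol(Z) == 1) {
    # glmnet requires >= 2 columns; an all-zero pad never enters the model
    Z <- cbind(Z, .pad = 0)
  }
  if (is.null(lambda_grid)) {
    # largest penalty that zeroes every coefficient, then log-space downward
    lmax <- max(abs(crossprod(Z, y - mean(y)))) / nrow(Z)
    lambda_grid <- exp(seq(log(lmax * 1.0001), log(lmax * 1e-4),
                           length.out = n_lambda))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  folds <- stratified_folds(y, cv_folds, seed)
  cv_auc <- matrix(NA_real_, cv_folds, length(lambda_grid))
  for (k in seq_len(cv_folds)) {
    tr <- folds != k
    fit_k <- glmnet::glmnet(Z[tr, , drop = FALSE], y[tr],
                            family = "binomial", alpha = 1,
                            lambda = lambda_grid, standardize = FALSE,
                            maxit = 1e6)
    p <- predict(fit_k, Z[!tr, , drop = FALSE], s = lambda_grid,
                 type = "response", exact = FALSE)
    yk <- y[!tr]
    if (length(unique(yk)) < 2) next
    cv_auc[k, ] <- apply(p, 2, function(s) auroc(s, yk))
  }
  mean_auc <- colMeans(cv_auc, na.rm = TRUE)
  best <- which.max(mean_auc)
  fit <- glmnet::glmnet(Z, y, family = "binomial", alpha = 1,
                        lambda = lambda_grid, standardize = FALSE,
                        maxit = 1e6)
  beta <- as.matrix(coef(fit, s = lambda_grid[best]))[, 1]
  nz <- beta[-1][beta[-1] != 0]
  structure(list(intercept = unname(beta[1]),
                 coefficients = nz,
                 lambda = lambda_grid[best],
                 lambda_grid = lambda_grid,
                 cv_auroc = mean_auc,
                 n_retained_path = colSums(as.matrix(fit$beta) != 0),
                 preprocessing = prep$params,
                 metadata = list(seed = seed, cv_folds = cv_folds,
                                 n = nrow(Z), n_events = sum(y))),
            class = "rs1_model")
}

stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  set.seed(seed)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' @export
print.rs1_model <- function(x, ...) {
  cat("rs1_model:", length(x$coefficients), "of",
      length(x$preprocessing$features),
      "features retained (lambda =", signif(x$lambda, 3), ")\n")
  invisible(x)
}

#' Predict the static discharge risk
#'
#' Applies an [fit_rs1()] model: missing features are filled with the
#' training medians, features are z-scored with the training parameters and
#' the linear predictor is mapped through the logistic function. Returns a
#' probability strictly inside (0, 1).
#'
#' @param model an `rs1_model`.
#' @param X numeric feature matrix (or single named vector) on the raw scale.
#' @return numeric vector of event probabilities.
#' @export
predict_rs1 <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, 1, dimnames = list(NULL, names(X)))
  prep <- impute_and_standardise(X, params = model$preprocessing)
  eta <- rep(model$intercept, nrow(X))
  if (length(model$coefficients)) {
    eta <- eta + as.vector(prep$design[, names(model$coefficients),
                                       drop = FALSE] %*% model$coefficients)
  }
  plogis(eta)
}
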