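#' Run the full risk-scoring pipeline on a cohort
#'
#' The end-to-end procedure the package implements, mirroring a
#' development/validation design: admissions passing the inclusion criteria
#' are split at the patient level into a development and a validation half;
#' the static risk model is fitted to the development admissions (compound
#' outcome at any time after ICU discharge), the vital-sign normality model
#' to development discharge-day observations of event-free admissions, and
#' the fusion parameters are tuned on development observations at the 24 h
#' horizon; every system (MEWS, SEWS, NEWS, CEWS, RS1, RS2, RSI) is then
#' scored on the identical validation observation sets and compared across
#' horizons.
#'
#' @param cohort a [cohort_tables()] object, e.g. from [generate_cohort()].
#' @param seed integer seed (split, CV folds, bootstrap).
#' @param horizons outcome windows in hours for the comparison.
#' @param dev_fraction fraction of admissions assigned to development
#'   (default 0.5).
#' @param B bootstrap resamples for the comparison CIs (0 to skip).
#' @param spec feature specification for the static model.
#' @param endpoints endpoints for the comparison table.
#' @return list: `comparison` (system x horizon x endpoint AUROC table),
#'   `scores` (validation observation scores per system), `rs1_model`,
#'   `novelty_model`, `fusion`, `fusion_grid`, `inclusion_log`, `n_dev`,
#'   `n_val`.
#' @export
run_rsi_pipeline <- function(cohort, seed = 1,
                             horizons = c(12, 24, 36, 48, 72),
                             dev_fraction = 0.5, B = 0,
                             spec = default_feature_spec(),
                             endpoints = "compound") {
  incl <- apply_inclusion_criteria(cohort$admissions)
  adm <- incl$included
  ids <- adm$admission_id
  set.seed(seed)
  dev_ids <- sort(sample(ids, round(length(ids) * dev_fraction)))
  val_ids <- setdiff(ids, dev_ids)

  subset_cohort <- function(keep) {
    cohort_tables(
      cohort$admissions[cohort$admissions$admission_id %in% keep, ,
                        drop = FALSE],
      cohort$channels[cohort$channels$admission_id %in% keep, , drop = FALSE],
      cohort$observations[cohort$observations$admission_id %in% keep, ,
                          drop = FALSE],
      cohort$outcomes[cohort$outcomes$admission_id %in% keep, , drop = FALSE],
      validate = FALSE)
  }
  dev <- subset_cohort(dev_ids)
  val <- subset_cohort(val_ids)

  # static model: compound outcome at any time after ICU discharge
  Xd <- extract_feature_matrix(dev, spec)
  yd <- as.numeric(dev$outcomes$event_type[
    match(rownames(Xd), dev$outcomes$admission_id)] != "none")
  rs1 <- fit_rs1(Xd, yd, seed = seed)

  # normality model: discharge-day vitals of event-free dev admissions
  train <- select_normality_training_set(dev)
  rs2 <- fit_normality_model(train, seed = seed)

  # fusion tuning on dev observations at the 24 h horizon
  dev_scores <- score_cohort_systems(dev, rs1_model = rs1,
                                     novelty_model = rs2, spec = spec,
                                     systems = character(0))
  dis <- dev$admissions$icu_discharge_time[
    match(dev_scores$admission_id, dev$admissions$admission_id)]
  lab24 <- label_observations(dev$observations, dev$outcomes, 24, "compound")
  tune_df <- data.frame(admission_id = dev_scores$admission_id,
                        t = hours_between(dis, dev_scores$obs_time),
                        rs1 = dev_scores$RS1, rs2 = dev_scores$RS2,
                        label = lab24$label, censored = lab24$censored)
  tuned <- optimize_fusion_params(tune_df, seed = seed)

  val_scores <- score_cohort_systems(val, rs1_model = rs1,
                                     novelty_model = rs2,
                                     fusion = tuned$params, spec = spec)
  comparison <- compare_systems(val_scores, val$observations, val$outcomes,
                                systems = setdiff(names(val_scores),
                                                  c("admission_id",
                                                    "obs_time")),
                                horizons = horizons, endpoints = endpoints,
                                B = B, seed = seed)
  list(comparison = comparison, scores = val_scores, rs1_model = rs1,
       novelty_model = rs2, fusion = tuned$params,
       fusion_grid = tuned$grid, inclusion_log = incl$exclusion_log,
       n_dev = length(dev_ids), n_val = length(val_ids))
}
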