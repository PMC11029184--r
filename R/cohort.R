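#' Vital-sign plausibility bounds
#'
#' Inclusive physiological plausibility ranges used to validate ward
#' observations and to define the coverage range that every Early Warning
#' Score band table must span.
#'
#' @return named list of `c(lower, upper)` per continuous vital.
#' @export
vital_bounds <- function() {
  list(heart_rate  = c(10, 300),
       systolic_bp = c(30, 300),
       resp_rate   = c(0, 80),
       temperature = c(30, 43),
       spo2        = c(50, 100))
}

#' Measurement precision per vital
#'
#' Ward charts record heart rate, systolic pressure, respiratory rate and
#' SpO2 as integers and temperature to 0.1 degC; band tables are expressed
#' as closed intervals on this grid.
#' @return named numeric vector of precisions.
#' @export
vital_precision <- function() {
  c(heart_rate = 1, systolic_bp = 1, resp_rate = 1,
    temperature = 0.1, spo2 = 1)
}

avpu_levels <- function() c("A", "V", "P", "U")

#' Follow-up window after ICU discharge, in days
#' @return 14
#' @export
followup_days <- function() 14

#' Assemble and validate a cohort
#'
#' Bundles the four tables that describe a post-ICU cohort: one row per ICU
#' admission, long-format ICU channel recordings, ward vital-sign observation
#' sets and first-event outcomes. All timestamps are numeric minutes since
#' the epoch (see [iso_to_minutes()]).
#'
#' @param admissions data.frame with columns `admission_id`, `age`, `sex`,
#'   `icu_admit_time`, `icu_discharge_time`, `discharge_status` (one of
#'   alive/dead/palliative/transferred_out/unknown) plus optional static
#'   variable columns.
#' @param channels data.frame `admission_id`, `channel`, `time`, `value`;
#'   intervention channels use 0/1 step values.
#' @param observations data.frame `admission_id`, `obs_time`, `heart_rate`,
#'   `systolic_bp`, `resp_rate`, `temperature`, `spo2`, `supplemental_o2`
#'   (logical), `avpu` (A/V/P/U). Missing vitals are `NA`.
#' @param outcomes data.frame `admission_id`, `event_type`
#'   (none/death/readmission), `event_time` (NA when none),
#'   `hospital_discharge_time`.
#' @param validate check invariants (default TRUE).
#' @return object of class `cohort_tables` (a named list of the four tables).
#' @export
cohort_tables <- function(admissions, channels = NULL, observations = NULL,
                          outcomes = NULL, validate = TRUE) {
  empty_channels <- data.frame(admission_id = character(), channel = character(),
                               time = numeric(), value = numeric())
  empty_obs <- data.frame(admission_id = character(), obs_time = numeric(),
                          heart_rate = numeric(), systolic_bp = numeric(),
                          resp_rate = numeric(), temperature = numeric(),
                          spo2 = numeric(), supplemental_o2 = logical(),
                          avpu = character())
  empty_out <- data.frame(admission_id = character(), event_type = character(),
                          event_time = numeric(),
                          hospital_discharge_time = numeric())
  x <- structure(list(admissions  = as.data.frame(admissions),
                      channels     = if (is.null(channels)) empty_channels else as.data.frame(channels),
                      observations = if (is.null(observations)) empty_obs else as.data.frame(observations),
                      outcomes     = if (is.null(outcomes)) empty_out else as.data.frame(outcomes)),
                 class = "cohort_tables")
  if (validate) validate_cohort(x)
  x
}

#' Validate cohort invariants
#'
#' Checks referential integrity (every observation and outcome resolves to an
#' admission), admission time ordering, channel timestamps within the ICU
#' stay, observation timing within the 14-day post-ICU window, vital-sign
#' plausibility bounds and AVPU codes. Errors on the first violation.
#'
#' @param cohort a [cohort_tables()] object.
#' @return the cohort, invisibly.
#' @export
validate_cohort <- function(cohort) {
  adm <- cohort$admissions
  if (anyDuplicated(adm$admission_id)) {
    dup <- adm$admission_id[duplicated(adm$admission_id)][1]
    stop("duplicate admission_id: '", dup, "'")
  }
  bad <- which(!is.na(adm$icu_admit_time) & !is.na(adm$icu_discharge_time) &
                 adm$icu_admit_time >= adm$icu_discharge_time)
  if (length(bad)) {
    stop("icu_admit_time must precede icu_discharge_time (admission '",
         adm$admission_id[bad[1]], "')")
  }
  ok_status <- c("alive", "dead", "palliative", "transferred_out", "unknown")
  if (!all(adm$discharge_status %in% ok_status)) {
    stop("unknown discharge_status value: '",
         setdiff(adm$discharge_status, ok_status)[1], "'")
  }
  for (tab in c("channels", "observations", "outcomes")) {
    ids <- cohort[[tab]]$admission_id
    orphan <- setdiff(unique(ids), adm$admission_id)
    if (length(orphan)) {
      stop(tab, " reference unknown admission_id '", orphan[1], "'")
    }
  }
  ch <- cohort$channels
  if (nrow(ch)) {
    idx <- match(ch$admission_id, adm$admission_id)
    out_of_stay <- which(ch$time < adm$icu_admit_time[idx] - 1e-9 |
                           ch$time > adm$icu_discharge_time[idx] + 1e-9)
    if (length(out_of_stay)) {
      stop("channel timestamp outside ICU stay for admission '",
           ch$admission_id[out_of_stay[1]], "', channel '",
           ch$channel[out_of_stay[1]], "'")
    }
  }
  obs <- cohort$observations
  if (nrow(obs)) {
    idx <- match(obs$admission_id, adm$admission_id)
    dis <- adm$icu_discharge_time[idx]
    late <- which(obs$obs_time < dis - 1e-9 |
                    obs$obs_time > dis + followup_days() * 1440 + 1e-9)
    if (length(late)) {
      stop("observation outside the post-ICU follow-up window for admission '",
           obs$admission_id[late[1]], "'")
    }
    bounds <- vital_bounds()
    for (v in names(bounds)) {
      val <- obs[[v]]
      viol <- which(!is.na(val) & (val < bounds[[v]][1] | val > bounds[[v]][2]))
      if (length(viol)) {
        stop("implausible ", v, " value ", val[viol[1]], " for admission '",
             obs$admission_id[viol[1]], "'")
      }
    }
    bad_avpu <- which(!is.na(obs$avpu) & !obs$avpu %in% avpu_levels())
    if (length(bad_avpu)) {
      stop("unknown AVPU code '", obs$avpu[bad_avpu[1]], "' at observation row ",
           bad_avpu[1])
    }
  }
  oc <- cohort$outcomes
  if (nrow(oc)) {
    ok_ev <- c("none", "death", "readmission")
    if (!all(oc$event_type %in% ok_ev)) {
      stop("unknown event_type: '", setdiff(oc$event_type, ok_ev)[1], "'")
    }
    has_ev <- oc$event_type != "none"
    if (any(has_ev & is.na(oc$event_time))) {
      stop("event_time missing for an adverse event (admission '",
           oc$admission_id[which(has_ev & is.na(oc$event_time))[1]], "')")
    }
    idx <- match(oc$admission_id, adm$admission_id)
    early <- which(has_ev & oc$event_time <= adm$icu_discharge_time[idx])
    if (length(early)) {
      stop("adverse event at or before ICU discharge for admission '",
           oc$admission_id[early[1]], "'")
    }
  }
  invisible(cohort)
}

#' @export
print.cohort_tables <- function(x, ...) {
  cat("cohort_tables:",
      nrow(x$admissions), "admissions,",
      nrow(x$channels), "channel rows,",
      nrow(x$observations), "observation sets,",
      nrow(x$outcomes), "outcomes\n")
  invisible(x)
}

#' Apply cohort inclusion and exclusion criteria
#'
#' Keeps admissions discharged alive from the ICU with a known hospital
#' episode outcome. Admissions that died in the ICU, were discharged for
#' palliative care, were transferred to another organisation, or whose
#' discharge status is unknown are excluded, with reasons tallied in an
#' exclusion log. The operation is idempotent and partitions its input.
#'
#' @param admissions admissions table (see [cohort_tables()]).
#' @return list with `included` (admissions subset) and `exclusion_log`
#'   (data.frame of reason, n).
#' @export
apply_inclusion_criteria <- function(admissions) {
  admissions <- as.data.frame(admissions)
  if (anyDuplicated(admissions$admission_id)) {
    dup <- admissions$admission_id[duplicated(admissions$admission_id)][1]
    stop("duplicate admission_id: '", dup, "'")
  }
  status <- admissions$discharge_status
  reason <- rep(NA_character_, nrow(admissions))
  reason[status %in% c("dead")] <- "not discharged alive"
  reason[status %in% "palliative"] <- "discharged for palliative care"
  reason[status %in% "transferred_out"] <- "transferred to another organisation"
  reason[status %in% "unknown"] <- "hospital episode outcome unknown"
  included <- admissions[is.na(reason), , drop = FALSE]
  excl <- reason[!is.na(reason)]
  log <- if (length(excl)) {
    as.data.frame(table(reason = excl), responseName = "n",
                  stringsAsFactors = FALSE)
  } else {
    data.frame(reason = character(), n = integer())
  }
  list(included = included, exclusion_log = log)
}

#' Link raw adverse events to admissions as first-event outcomes
#'
#' For each admission the earliest adverse event (in-hospital death or ICU
#' readmission) is retained; later events are discarded, in keeping with a
#' first-event analysis. Admissions with no event receive
#' `event_type = "none"`. The result is invariant to the row order of
#' `raw_events`.
#'
#' @param admissions admissions table.
#' @param raw_events data.frame `admission_id`, `type`
#'   (death/readmission), `time` (minutes since epoch).
#' @param hospital_discharge data.frame `admission_id`,
#'   `hospital_discharge_time`, or NULL to leave the column NA.
#' @return outcomes data.frame, one row per admission.
#' @export
link_outcomes <- function(admissions, raw_events,
                          hospital_discharge = NULL) {
  admissions <- as.data.frame(admissions)
  raw_events <- as.data.frame(raw_events)
  if (nrow(raw_events)) {
    if (!all(raw_events$type %in% c("death", "readmission"))) {
      stop("unknown event type: '",
           setdiff(raw_events$type, c("death", "readmission"))[1], "'")
    }
    idx <- match(raw_events$admission_id, admissions$admission_id)
    if (anyNA(idx)) {
      stop("event for unknown admission_id '",
           raw_events$admission_id[which(is.na(idx))[1]], "'")
    }
    early <- which(raw_events$time <= admissions$icu_discharge_time[idx])
    if (length(early)) {
      stop("event at or before ICU discharge for admission '",
           raw_events$admission_id[early[1]], "'")
    }
    # stable earliest-event pick: order by time, keep first per admission
    o <- order(raw_events$time)
    ev <- raw_events[o, , drop = FALSE]
    first <- ev[!duplicated(ev$admission_id), , drop = FALSE]
  } else {
    first <- data.frame(admission_id = character(), type = character(),
                        time = numeric())
  }
  m <- match(admissions$admission_id, first$admission_id)
  out <- data.frame(admission_id = admissions$admission_id,
                    event_type = ifelse(is.na(m), "none", first$type[m]),
                    event_time = ifelse(is.na(m), NA_real_, first$time[m]),
                    hospital_discharge_time = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(hospital_discharge)) {
    hd <- as.data.frame(hospital_discharge)
    mh <- match(out$admission_id, hd$admission_id)
    out$hospital_discharge_time <- hd$hospital_discharge_time[mh]
  }
  out
}

#' Flag observations recorded at or after an admission's first adverse event
#'
#' Post-event observation sets are retained in storage but are excluded from
#' evaluation, which is conditioned on the first event only.
#'
#' @param observations observations table.
#' @param outcomes outcomes table.
#' @return logical vector, TRUE where the observation is post-event.
#' @export
flag_post_event <- function(observations, outcomes) {
  m <- match(observations$admission_id, outcomes$admission_id)
  ev <- outcomes$event_time[m]
  !is.na(ev) & observations$obs_time >= ev
}
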