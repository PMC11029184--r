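#' Read and write a cohort as delimited text tables
#'
#' A cohort directory holds four headered CSV files: `admissions.csv`,
#' `channels.csv`, `observations.csv` and `outcomes.csv` (see
#' [cohort_tables()] for columns). Timestamps are ISO-8601 at minute
#' resolution; an empty cell means missing. A write followed by a read
#' reproduces the cohort exactly.
#'
#' @param dir directory containing (or to receive) the four CSV files.
#' @param validate run [validate_cohort()] after reading (default TRUE).
#' @return `read_cohort()`: a [cohort_tables()] object; `write_cohort()`: the
#'   directory path, invisibly.
#' @export
read_cohort <- function(dir, validate = TRUE) {
  path <- function(f) file.path(dir, f)
  for (f in c("admissions.csv", "observations.csv", "outcomes.csv")) {
    if (!file.exists(path(f))) stop("missing cohort file: ", path(f))
  }
  adm <- read.csv(path("admissions.csv"), stringsAsFactors = FALSE)
  adm$icu_admit_time <- iso_to_minutes(adm$icu_admit_time)
  adm$icu_discharge_time <- iso_to_minutes(adm$icu_discharge_time)
  adm$admission_id <- as.character(adm$admission_id)

  ch <- if (file.exists(path("channels.csv"))) {
    x <- read.csv(path("channels.csv"), stringsAsFactors = FALSE)
    x$admission_id <- as.character(x$admission_id)
    x$time <- iso_to_minutes(x$time)
    x
  } else NULL

  obs <- read.csv(path("observations.csv"), stringsAsFactors = FALSE,
                  colClasses = c(avpu = "character"))
  obs$admission_id <- as.character(obs$admission_id)
  obs$obs_time <- iso_to_minutes(obs$obs_time)
  obs$supplemental_o2 <- parse_bool(obs$supplemental_o2, "supplemental_o2")
  obs$avpu[!is.na(obs$avpu) & !nzchar(trimws(obs$avpu))] <- NA_character_
  bad <- which(!is.na(obs$avpu) & !obs$avpu %in% avpu_levels())
  if (length(bad)) {
    stop("observations.csv row ", bad[1], ": unknown AVPU code '",
         obs$avpu[bad[1]], "'")
  }

  oc <- read.csv(path("outcomes.csv"), stringsAsFactors = FALSE)
  oc$admission_id <- as.character(oc$admission_id)
  oc$event_time <- iso_to_minutes(oc$event_time)
  oc$hospital_discharge_time <- iso_to_minutes(oc$hospital_discharge_time)

  cohort_tables(adm, ch, obs, oc, validate = validate)
}

#' @rdname read_cohort
#' @param cohort a [cohort_tables()] object.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  adm <- cohort$admissions
  adm$icu_admit_time <- minutes_to_iso(adm$icu_admit_time)
  adm$icu_discharge_time <- minutes_to_iso(adm$icu_discharge_time)
  write.csv(adm, file.path(dir, "admissions.csv"), row.names = FALSE,
            na = "")
  ch <- cohort$channels
  ch$time <- minutes_to_iso(ch$time)
  write.csv(ch, file.path(dir, "channels.csv"), row.names = FALSE, na = "")
  obs <- cohort$observations
  obs$obs_time <- minutes_to_iso(obs$obs_time)
  write.csv(obs, file.path(dir, "observations.csv"), row.names = FALSE,
            na = "")
  oc <- cohort$outcomes
  oc$event_time <- minutes_to_iso(oc$event_time)
  oc$hospital_discharge_time <- minutes_to_iso(oc$hospital_discharge_time)
  write.csv(oc, file.path(dir, "outcomes.csv"), row.names = FALSE, na = "")
  invisible(dir)
}

parse_bool <- function(x, what) {
  if (is.logical(x)) return(x)
  xs <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(xs))
  out[xs %in% c("true", "t", "1", "yes")] <- TRUE
  out[xs %in% c("false", "f", "0", "no")] <- FALSE
  bad <- which(!is.na(xs) & nzchar(xs) & is.na(out))
  if (length(bad)) {
    stop(what, ": unparseable boolean '", x[bad[1]], "' at row ", bad[1])
  }
  out
}
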