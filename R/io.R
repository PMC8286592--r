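#' Write and read recordings as CSV + JSON sidecar
#'
#' A recording is stored as a plain-text pair: `<subject>.csv` with columns
#' `time_s, pressure`, and `<subject>.json` holding the schedule(s), profile,
#' artifact events, the ground-truth breath-cycle log and the sampling rate,
#' so a written recording round-trips exactly.
#'
#' @param rec A `resp_recording`.
#' @param dir Output directory (created if needed).
#' @return `write_recording()`: the two file paths, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "resp_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, rec$profile$subject_id)
  csv <- paste0(base, ".csv"); json <- paste0(base, ".json")
  utils::write.csv(rec$signal, csv, row.names = FALSE)
  side <- list(
    subject_id = rec$profile$subject_id,
    kind = rec$kind,
    sampling_rate = rec$sampling_rate,
    profile = unclass(rec$profile),
    schedule = rec$schedule,
    schedule_true = rec$schedule_true,
    events = rec$events,
    cycles = rec$cycles
  )
  jsonlite::write_json(side, json, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(c(csv = csv, json = json))
}

#' @rdname write_recording
#' @param csv,json Paths of the signal CSV and its JSON sidecar.
#' @return `read_recording()`: the reconstructed `resp_recording`.
#' @export
read_recording <- function(csv, json = sub("\\.csv$", ".json", csv)) {
  sig <- as_tibble(utils::read.csv(csv))
  side <- jsonlite::read_json(json, simplifyVector = TRUE)
  profile <- structure(side$profile, class = "subject_profile")
  profile$seed <- as.integer(profile$seed)
  validate_profile(profile)
  structure(list(
    signal = sig,
    sampling_rate = side$sampling_rate,
    schedule = as_tibble(side$schedule),
    schedule_true = as_tibble(side$schedule_true),
    cycles = as_tibble(side$cycles),
    events = as_tibble(side$events),
    profile = profile,
    kind = side$kind
  ), class = "resp_recording")
}

#' Write and read a simulated cohort
#'
#' Writes every recording of a cohort (CSV + JSON sidecar per subject) plus a
#' `manifest.json` listing subjects, cohorts, strategies and files.
#'
#' @param cohort Cohort tibble from [simulate_cohort()].
#' @param dir Output directory.
#' @return `write_cohort()`: the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$recording) write_recording(rec, dir)
  manifest <- dplyr::select(cohort, -"recording") |>
    dplyr::mutate(csv = paste0(.data$subject, ".csv"),
                  json = paste0(.data$subject, ".json"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, dataframe = "rows")
  invisible(path)
}

#' @rdname write_cohort
#' @return `read_cohort()`: the reconstructed cohort tibble.
#' @export
read_cohort <- function(dir) {
  manifest <- as_tibble(jsonlite::read_json(file.path(dir, "manifest.json"),
                                            simplifyVector = TRUE))
  manifest |>
    dplyr::mutate(recording = purrr::map(.data$csv, ~ read_recording(file.path(dir, .x)))) |>
    dplyr::select(-"csv", -"json")
}
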