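# Plain-text interchange formats. Surveys serialize their member sets as a
# semicolon-joined field; timestamps are ISO-8601 UTC.

#' Write a simulated cohort to a directory
#'
#' Writes individuals.csv, surveys.csv, samples.csv, methylation.csv
#' (first column sample_id), probes.csv and truth.json. truth.json holds
#' the injected ground truth and is for validation only — no analysis
#' function reads it.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  utils::write.csv(cohort$individuals, p("individuals.csv"),
                   row.names = FALSE)
  surv <- cohort$surveys
  flat <- data.frame(survey_id = surv$survey_id,
                     timestamp = format(surv$timestamp,
                                        "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                     behaviour = surv$behaviour,
                     member_ids = vapply(surv$members, paste,
                                         "", collapse = ";"),
                     stringsAsFactors = FALSE)
  utils::write.csv(flat, p("surveys.csv"), row.names = FALSE)
  utils::write.csv(cohort$samples[, c("sample_id", "individual_id",
                                      "sampling_date",
                                      "chronological_age")],
                   p("samples.csv"), row.names = FALSE)
  meth <- data.frame(sample_id = rownames(cohort$methylation$values),
                     cohort$methylation$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
  utils::write.csv(meth, p("methylation.csv"), row.names = FALSE)
  utils::write.csv(cohort$methylation$manifest, p("probes.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read surveys from CSV
#'
#' @param path surveys.csv with columns survey_id, timestamp (ISO-8601),
#'   behaviour, member_ids (semicolon-joined).
#' @return survey data.frame with a `members` list-column.
#' @export
read_surveys <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  ts <- as_survey_time(raw$timestamp)
  bad <- which(is.na(ts))
  if (length(bad))
    stop_arg("unparseable timestamp in survey record(s): ",
             paste(raw$survey_id[utils::head(bad, 3)], collapse = ", "))
  out <- data.frame(survey_id = raw$survey_id, timestamp = ts,
                    behaviour = raw$behaviour, stringsAsFactors = FALSE)
  out$members <- strsplit(raw$member_ids, ";", fixed = TRUE)
  out
}

#' Read individual metadata from CSV
#' @param path individuals.csv.
#' @return data.frame with Date columns parsed.
#' @export
read_individuals <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$birth_date <- as.Date(d$birth_date)
  d$first_sighting_date <- as.Date(d$first_sighting_date)
  d
}

#' Read tissue-sample metadata from CSV
#' @param path samples.csv.
#' @return data.frame with `sampling_date` parsed.
#' @export
read_samples <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$sampling_date <- as.Date(d$sampling_date)
  d
}

#' Read a methylation matrix from CSV
#' @param path methylation.csv (first column sample_id, rest probes).
#' @return numeric matrix, rownames = sample ids.
#' @export
read_methylation <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a probe manifest from CSV
#' @param path probes.csv with probe_id and logical/0-1 mapped column.
#' @return data.frame `probe_id`, `mapped`.
#' @export
read_probes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$mapped <- as.logical(d$mapped)
  d
}
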