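#' Survey filtering rules
#'
#' Encodes the survey-inclusion rules used for all social metrics: foraging
#' surveys are dropped (animals aggregating over prey are not necessarily
#' associating), repeated encounters of the same group within a short window
#' (resightings) are dropped to avoid pseudo-replication, and a focal male
#' must have been seen a minimum number of times for his network metrics to
#' be considered reliable.
#'
#' @param exclude_forage drop surveys whose predominant behaviour is forage.
#' @param resight_window_hours window within which a repeated encounter of
#'   the same group counts as a resighting (default 2 h).
#' @param resight_criterion "identical_membership" (default) or
#'   "overlap_fraction" (Jaccard overlap >= `overlap_theta`).
#' @param overlap_theta overlap threshold in (0, 1], used only for the
#'   overlap criterion.
#' @param min_sightings minimum sightings for a male to be analysed and to
#'   enter the normalization maximum (default 15).
#' @return object of class `filter_rules`.
#' @export
filter_rules <- function(exclude_forage = TRUE, resight_window_hours = 2,
                         resight_criterion = c("identical_membership",
                                               "overlap_fraction"),
                         overlap_theta = 0.9, min_sightings = 15) {
  if (resight_window_hours <= 0)
    stop_arg("resight_window_hours must be > 0")
  resight_criterion <- match.arg(resight_criterion)
  if (resight_criterion == "overlap_fraction" &&
      (overlap_theta <= 0 || overlap_theta > 1))
    stop_arg("overlap_theta must be in (0, 1]")
  check_count(min_sightings, "min_sightings")
  structure(list(exclude_forage = isTRUE(exclude_forage),
                 resight_window_hours = resight_window_hours,
                 resight_criterion = resight_criterion,
                 overlap_theta = overlap_theta,
                 min_sightings = as.integer(min_sightings)),
            class = "filter_rules")
}

as_survey_time <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  fmts <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")
  out <- tryCatch(as.POSIXct(x, tz = "UTC", tryFormats = fmts),
                  error = function(e) NULL)
  if (!is.null(out)) return(out)
  # mixed or malformed entries: parse per element, NA marks the bad ones
  as.POSIXct(vapply(as.character(x), function(el) {
    v <- tryCatch(as.POSIXct(el, tz = "UTC", tryFormats = fmts),
                  error = function(e) NA)
    as.numeric(v)
  }, 0, USE.NAMES = FALSE), tz = "UTC", origin = "1970-01-01")
}

check_surveys <- function(surveys) {
  need <- c("survey_id", "timestamp", "behaviour", "members")
  miss <- setdiff(need, names(surveys))
  if (length(miss))
    stop_arg("surveys lack column(s): ", paste(miss, collapse = ", "))
  bad <- which(is.na(as_survey_time(surveys$timestamp)))
  if (length(bad))
    stop_arg("unparseable timestamp in survey record(s): ",
             paste(surveys$survey_id[bad[seq_len(min(3, length(bad)))]],
                   collapse = ", "))
  invisible(surveys)
}

#' Filter surveys for association analysis
#'
#' Applies the behaviour and resighting rules: foraging surveys are removed
#' (if configured), then surveys are scanned in time order and any survey
#' matching a *retained* earlier survey within the resight window — identical
#' membership by default — is dropped. The first encounter of a group is
#' always kept; output preserves input order.
#'
#' @param surveys survey data.frame (`survey_id`, `timestamp`, `behaviour`,
#'   list-column `members`).
#' @param rules a [filter_rules()] object.
#' @return the retained subset of `surveys`.
#' @export
filter_surveys <- function(surveys, rules = filter_rules()) {
  check_surveys(surveys)
  ts <- as_survey_time(surveys$timestamp)
  keep_rows <- seq_len(nrow(surveys))
  if (rules$exclude_forage)
    keep_rows <- keep_rows[surveys$behaviour[keep_rows] != "forage"]
  if (!length(keep_rows)) return(surveys[integer(0), , drop = FALSE])

  ord <- keep_rows[order(ts[keep_rows])]
  window_s <- rules$resight_window_hours * 3600
  members <- lapply(surveys$members[ord], unique)
  keys <- vapply(members, function(m) paste(sort(m), collapse = ";"), "")
  tnum <- as.numeric(ts[ord])
  n <- length(ord)
  retained <- logical(n)
  is_match <- function(i, j) {
    if (rules$resight_criterion == "identical_membership")
      return(keys[i] == keys[j])
    a <- members[[i]]; b <- members[[j]]
    length(intersect(a, b)) / length(union(a, b)) >= rules$overlap_theta
  }
  for (i in seq_len(n)) {
    dup <- FALSE
    j <- i - 1L
    while (j >= 1L && tnum[i] - tnum[j] <= window_s) {
      if (retained[j] && is_match(i, j)) { dup <- TRUE; break }
      j <- j - 1L
    }
    retained[i] <- !dup
  }
  keep <- sort(ord[retained])
  out <- surveys[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict surveys to a focal male's analysis window
#'
#' The window runs from the focal's first sighting (his first survey
#' appearance) up to and including 31 December of the sampling year —
#' association indices accumulate from when a male enters the study until
#' the calendar year his tissue sample was taken.
#'
#' @param surveys (already filtered) survey data.frame.
#' @param focal_id focal individual id.
#' @param sampling_date date of the tissue sample.
#' @return the surveys within the focal's window.
#' @export
window_surveys <- function(surveys, focal_id, sampling_date) {
  check_surveys(surveys)
  sampling_date <- as.Date(sampling_date)
  end <- as.POSIXct(sprintf("%d-12-31 23:59:59",
                            as.integer(format(sampling_date, "%Y"))),
                    tz = "UTC")
  ts <- as_survey_time(surveys$timestamp)
  has_focal <- vapply(surveys$members, function(m) focal_id %in% m, TRUE)
  in_time <- ts <= end
  if (!any(has_focal & in_time))
    stop_arg("empty window: focal '", focal_id,
             "' never sighted on or before ", format(end, "%Y-%m-%d"))
  start <- min(ts[has_focal & in_time])
  out <- surveys[in_time & ts >= start, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dyadic co-occurrence counts
#'
#' Counts, over a set of surveys, how often two individuals were seen
#' together (`x`), and how often each was seen without the other (`y_a`,
#' `y_b`). Surveys containing neither individual do not enter any count.
#'
#' @param a,b distinct individual ids.
#' @param surveys survey data.frame.
#' @return list of class `dyad_counts` with integers `x`, `y_a`, `y_b`.
#' @export
dyad_counts <- function(a, b, surveys) {
  if (identical(a, b)) stop_arg("dyad members must differ")
  in_a <- vapply(surveys$members, function(m) a %in% m, TRUE)
  in_b <- vapply(surveys$members, function(m) b %in% m, TRUE)
  structure(list(x = sum(in_a & in_b), y_a = sum(in_a & !in_b),
                 y_b = sum(in_b & !in_a)),
            class = "dyad_counts")
}

#' Simple Ratio Index
#'
#' SRI = x / (x + y_a + y_b): the proportion of surveys involving either
#' member of a dyad in which both were present. 0 for dyads never seen
#' together (including dyads never observed at all), 1 for dyads never seen
#' apart.
#'
#' @param counts a [dyad_counts()] object (or list with `x`, `y_a`, `y_b`).
#' @return association index in [0, 1].
#' @export
sri <- function(counts) {
  x <- counts$x; ya <- counts$y_a; yb <- counts$y_b
  if (any(c(x, ya, yb) < 0)) stop_arg("dyad counts must be non-negative")
  denom <- x + ya + yb
  if (denom == 0) return(0)
  x / denom
}

# incidence matrix surveys x ids (logical)
incidence_matrix <- function(surveys, ids) {
  m <- matrix(FALSE, nrow(surveys), length(ids),
              dimnames = list(NULL, ids))
  for (i in seq_len(nrow(surveys))) {
    mem <- intersect(surveys$members[[i]], ids)
    if (length(mem)) m[i, mem] <- TRUE
  }
  m
}

# all pairwise SRIs among `ids` in one pass; returns symmetric matrix
sri_matrix <- function(surveys, ids) {
  inc <- incidence_matrix(surveys, ids)
  x <- crossprod(inc)                 # joint counts
  n_i <- diag(x)                      # marginal sighting counts
  denom <- outer(n_i, n_i, "+") - x   # x + y_a + y_b
  s <- ifelse(denom > 0, x / denom, 0)
  diag(s) <- 0
  s
}

#' Node strength (cumulative social bond strength)
#'
#' Sum of a focal's SRI values to a set of partners.
#'
#' @param focal focal id.
#' @param partner_ids partner ids (must not include the focal).
#' @param surveys survey data.frame.
#' @return non-negative real.
#' @export
node_strength <- function(focal, partner_ids, surveys) {
  if (focal %in% partner_ids)
    stop_arg("partner_ids must not contain the focal")
  if (!length(partner_ids)) return(0)
  sum(vapply(partner_ids,
             function(p) sri(dyad_counts(focal, p, surveys)), 0))
}

male_ids <- function(individuals) individuals$id[individuals$sex == "M"]

#' Normalized node strength
#'
#' The focal male's node strength over his analysis window, divided by the
#' maximum node strength across all males seen at least `min_sightings`
#' times in that window. All males contribute to every male's SRI sums
#' regardless of their own sighting counts; the sighting threshold gates
#' only whose maximum is taken (and which focals are analysed at all).
#'
#' @param focal focal male id.
#' @param sampling_date sample date defining the window end.
#' @param surveys raw survey data.frame (filters are applied internally).
#' @param individuals roster (used for sexes).
#' @param rules a [filter_rules()] object.
#' @return value in [0, 1]; 1 when the focal is the maximal male.
#' @export
normalized_node_strength <- function(focal, sampling_date, surveys,
                                     individuals, rules = filter_rules()) {
  w <- window_surveys(filter_surveys(surveys, rules), focal, sampling_date)
  males <- male_ids(individuals)
  s <- sri_matrix(w, males)
  strengths <- rowSums(s)
  n_seen <- colSums(incidence_matrix(w, males))
  eligible <- n_seen >= rules$min_sightings
  if (!any(eligible))
    stop_arg("no eligible male (>= ", rules$min_sightings,
             " sightings) in window")
  max_s <- max(strengths[eligible])
  if (max_s == 0)
    stop_arg("degenerate network: maximum eligible node strength is 0")
  unname(strengths[focal] / max_s)
}

#' Coefficient of variation of a male's bond strengths
#'
#' Sample SD divided by mean of the focal's dyadic SRI values, summarizing
#' whether he spreads his bonds evenly (low CV) or concentrates on a few
#' partners (high CV). By default only realized (nonzero) dyads enter;
#' including the zeros of every never-met male would make the CV a function
#' of population size.
#'
#' @param focal focal id.
#' @param surveys survey data.frame (already filtered/windowed by caller).
#' @param partner_policy "nonzero_only" (default) or "all_males".
#' @param partner_ids candidate partners; defaults to every other id seen
#'   in `surveys`.
#' @return non-negative real, or NA_real_ when fewer than two SRI values
#'   exist or their mean is zero.
#' @export
cv_bond_strength <- function(focal, surveys,
                             partner_policy = c("nonzero_only", "all_males"),
                             partner_ids = NULL) {
  partner_policy <- match.arg(partner_policy)
  if (is.null(partner_ids))
    partner_ids <- setdiff(unique(unlist(surveys$members)), focal)
  partner_ids <- setdiff(partner_ids, focal)
  vals <- vapply(partner_ids,
                 function(p) sri(dyad_counts(focal, p, surveys)), 0)
  if (partner_policy == "nonzero_only") vals <- vals[vals > 0]
  if (length(vals) < 2 || mean(vals) == 0) return(NA_real_)
  stats::sd(vals) / mean(vals)
}

#' Mean male group size
#'
#' Over the focal male's filtered sightings in his window, the mean number
#' of *other* males present. Males below the sighting threshold still count
#' toward group size.
#'
#' @inheritParams normalized_node_strength
#' @return non-negative real.
#' @export
mean_male_group_size <- function(focal, sampling_date, surveys, individuals,
                                 rules = filter_rules()) {
  w <- window_surveys(filter_surveys(surveys, rules), focal, sampling_date)
  males <- male_ids(individuals)
  has_focal <- vapply(w$members, function(m) focal %in% m, TRUE)
  if (!any(has_focal)) stop_arg("focal has no sightings in window")
  other <- vapply(w$members[has_focal],
                  function(m) length(intersect(setdiff(m, focal), males)),
                  0L)
  mean(other)
}

#' Compute social metrics for every sampling point
#'
#' For each tissue sample of a male individual, computes the sighting count,
#' normalized node strength, CV of bond strength, and mean male group size
#' over that sample's window (first sighting through 31 December of the
#' sampling year), with the full survey filters applied. Repeatedly sampled
#' males get one record per sample. Records that cannot be computed (e.g.
#' the focal was never sighted) are returned flagged ineligible with a
#' `note`, never silently dropped; female samples are skipped.
#'
#' @param samples data.frame `sample_id`, `individual_id`, `sampling_date`.
#' @param surveys raw survey data.frame.
#' @param individuals roster with `id`, `sex`.
#' @param rules a [filter_rules()] object.
#' @param cv_policy partner policy for [cv_bond_strength()].
#' @return data.frame, one row per male sample: `sample_id`,
#'   `individual_id`, `window_end_year`, `n_sightings`,
#'   `bond_strength_norm`, `cv_bond`, `mean_male_group_size`, `eligible`,
#'   `note`.
#' @export
compute_social_metrics <- function(samples, surveys, individuals,
                                   rules = filter_rules(),
                                   cv_policy = "nonzero_only") {
  check_surveys(surveys)
  filtered <- filter_surveys(surveys, rules)
  males <- male_ids(individuals)
  is_male <- samples$individual_id %in% males
  out <- lapply(which(is_male), function(i) {
    focal <- samples$individual_id[i]
    sdate <- as.Date(samples$sampling_date[i])
    rec <- data.frame(sample_id = samples$sample_id[i],
                      individual_id = focal,
                      window_end_year = as.integer(format(sdate, "%Y")),
                      n_sightings = 0L, bond_strength_norm = NA_real_,
                      cv_bond = NA_real_, mean_male_group_size = NA_real_,
                      eligible = FALSE, note = "",
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      w <- window_surveys(filtered, focal, sdate)
      s <- sri_matrix(w, males)
      inc <- incidence_matrix(w, males)
      n_seen <- colSums(inc)
      strengths <- rowSums(s)
      elig <- n_seen >= rules$min_sightings
      rec$n_sightings <- as.integer(n_seen[focal])
      if (any(elig) && max(strengths[elig]) > 0)
        rec$bond_strength_norm <-
          unname(strengths[focal] / max(strengths[elig]))
      vals <- s[focal, setdiff(males, focal)]
      if (cv_policy == "nonzero_only") vals <- vals[vals > 0]
      rec$cv_bond <- if (length(vals) >= 2 && mean(vals) > 0)
        stats::sd(vals) / mean(vals) else NA_real_
      has_focal <- inc[, focal]
      rec$mean_male_group_size <-
        mean(rowSums(inc[has_focal, , drop = FALSE]) - 1)
      rec$eligible <- unname(elig[focal])
      rec
    }, error = function(e) {
      rec$note <- conditionMessage(e)
      rec
    })
    res
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "rules") <- rules
  attr(res, "cv_policy") <- cv_policy
  res
}
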