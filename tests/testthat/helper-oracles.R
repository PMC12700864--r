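# Independent brute-force reimplementations of the social metrics,
# written as plain double loops with no shared code with the package.
# They are deliberately slow and obvious.

oracle_filter <- function(surveys, exclude_forage = TRUE,
                          window_hours = 2) {
  ts <- as.POSIXct(surveys$timestamp, tz = "UTC")
  ord <- order(ts)
  keep <- rep(TRUE, nrow(surveys))
  if (exclude_forage) keep[surveys$behaviour == "forage"] <- FALSE
  retained <- character(0) # keys "time|members" of retained, in time order
  ret_time <- numeric(0)
  ret_key <- character(0)
  for (i in ord) {
    if (!keep[i]) next
    key <- paste(sort(unique(surveys$members[[i]])), collapse = "|")
    dup <- any(ret_key == key &
                 as.numeric(ts[i]) - ret_time <= window_hours * 3600)
    if (dup) keep[i] <- FALSE
    else {
      ret_key <- c(ret_key, key)
      ret_time <- c(ret_time, as.numeric(ts[i]))
    }
  }
  surveys[keep, , drop = FALSE]
}

oracle_window <- function(surveys, focal, sampling_date) {
  ts <- as.POSIXct(surveys$timestamp, tz = "UTC")
  yr <- as.integer(format(as.Date(sampling_date), "%Y"))
  end <- as.POSIXct(sprintf("%d-12-31 23:59:59", yr), tz = "UTC")
  has <- sapply(surveys$members, function(m) focal %in% m)
  stopifnot(any(has & ts <= end))
  start <- min(ts[has & ts <= end])
  surveys[ts >= start & ts <= end, , drop = FALSE]
}

oracle_dyad <- function(a, b, surveys) {
  x <- ya <- yb <- 0L
  for (m in surveys$members) {
    ia <- a %in% m; ib <- b %in% m
    if (ia && ib) x <- x + 1L
    else if (ia) ya <- ya + 1L
    else if (ib) yb <- yb + 1L
  }
  c(x = x, y_a = ya, y_b = yb)
}

oracle_sri <- function(a, b, surveys) {
  cnt <- oracle_dyad(a, b, surveys)
  d <- sum(cnt)
  if (d == 0) 0 else cnt[["x"]] / d
}

oracle_strength <- function(focal, males, surveys) {
  s <- 0
  for (p in setdiff(males, focal)) s <- s + oracle_sri(focal, p, surveys)
  s
}

oracle_metrics <- function(focal, sampling_date, surveys, individuals,
                           min_sightings, cv_policy = "nonzero_only") {
  males <- individuals$id[individuals$sex == "M"]
  f <- oracle_filter(surveys)
  w <- oracle_window(f, focal, sampling_date)
  n_seen <- sapply(males, function(i)
    sum(sapply(w$members, function(m) i %in% m)))
  strengths <- sapply(males, function(i) oracle_strength(i, males, w))
  elig <- males[n_seen >= min_sightings]
  bond <- if (length(elig) && max(strengths[elig]) > 0)
    strengths[[focal]] / max(strengths[elig]) else NA_real_
  sris <- sapply(setdiff(males, focal),
                 function(p) oracle_sri(focal, p, w))
  if (cv_policy == "nonzero_only") sris <- sris[sris > 0]
  cv <- if (length(sris) >= 2 && mean(sris) > 0)
    sd(sris) / mean(sris) else NA_real_
  in_focal <- sapply(w$members, function(m) focal %in% m)
  gs <- mean(sapply(w$members[in_focal], function(m)
    length(intersect(setdiff(m, focal), males))))
  list(n_sightings = n_seen[[focal]], bond = bond, cv = cv,
       group_size = gs)
}

# compact hand-built survey table
make_surveys <- function(member_sets, times, behaviours = NULL) {
  n <- length(member_sets)
  if (is.null(behaviours)) behaviours <- rep("social", n)
  out <- data.frame(survey_id = sprintf("T%03d", seq_len(n)),
                    timestamp = as.POSIXct(times, tz = "UTC"),
                    behaviour = behaviours, stringsAsFactors = FALSE)
  out$members <- member_sets
  out
}

# small random cohort for oracle-equivalence sweeps
random_cohort <- function(seed) {
  set.seed(seed)
  n_ind <- sample(8:20, 1)
  inds <- simulate_individuals(n_ind, male_fraction = 0.7,
                               study_span_years = 12, seed = seed)
  survs <- simulate_surveys(
    inds, list(n_clusters = sample(2:3, 1), within_p = 0.6,
               between_p = 0.1),
    surveys_per_year = sample(8:16, 1), forage_fraction = 0.2,
    resight_fraction = 0.15, seed = seed + 1, study_span_years = 12)
  samples <- simulate_samples(inds, n_ind + 4, 4,
                              study_span_years = 12,
                              sampling_start_year = 5, seed = seed + 2)
  list(individuals = inds, surveys = survs, samples = samples)
}
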