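#' Simulate study individuals
#'
#' Generates a roster of individuals for a long-term observational study:
#' ids, sexes, birth dates spanning the study window (so that ages at
#' sampling cover roughly 0--30 years), a first-sighting date shortly after
#' birth, and a birth-date accuracy flag of +/-0.5 or +/-1 year used by the
#' robustness-subset analyses.
#'
#' @param n_individuals number of individuals (>= 2).
#' @param male_fraction fraction of individuals that are male, in [0, 1].
#' @param study_span_years length of the observation window in years.
#' @param seed integer seed; output is byte-identical for identical inputs.
#' @param study_start calendar date of the first field season.
#' @return data.frame with columns `id`, `sex` ("M"/"F"), `birth_date`,
#'   `birth_accuracy_years`, `first_sighting_date`.
#' @export
simulate_individuals <- function(n_individuals, male_fraction = 0.5,
                                 study_span_years = 40, seed = 1,
                                 study_start = as.Date("1984-01-01")) {
  n <- check_count(n_individuals, "n_individuals", min = 2L)
  check_prob(male_fraction, "male_fraction")
  span <- check_count(study_span_years, "study_span_years")
  with_seed(seed, {
    ids <- sprintf("ID%03d", seq_len(n))
    n_male <- round(n * male_fraction)
    sex <- rep("F", n)
    sex[sample.int(n, n_male)] <- "M"
    # births from just before the study start through most of the window,
    # so individuals sampled in the later field seasons are 0-30ish years old
    birth <- study_start + round(stats::runif(n, -2, span - 2) * 365.25)
    first_seen <- pmax(study_start, birth + round(stats::runif(n, 30, 730)))
    accuracy <- sample(c(0.5, 1.0), n, replace = TRUE)
    data.frame(id = ids, sex = sex, birth_date = birth,
               birth_accuracy_years = accuracy,
               first_sighting_date = first_seen,
               stringsAsFactors = FALSE)
  })
}

#' Simulate group-encounter surveys with alliance structure
#'
#' Males are partitioned into alliance clusters by a stochastic block model:
#' for each survey a cluster is drawn, its members join with probability
#' `within_p` and males of other clusters with probability `between_p`, so
#' same-cluster males co-occur much more often than males across clusters.
#' Females join at a low background rate. A fraction of surveys is labelled
#' foraging, and a fraction receives an identical-membership twin within two
#' hours to exercise the resighting filter downstream.
#'
#' @param individuals roster from [simulate_individuals()].
#' @param alliance_config list with `n_clusters`, `within_p`, `between_p`.
#' @param surveys_per_year surveys generated per study year.
#' @param forage_fraction fraction of surveys whose predominant behaviour is
#'   foraging.
#' @param resight_fraction fraction of surveys duplicated within 2 h with
#'   identical membership.
#' @param seed integer seed.
#' @param study_span_years years of surveying, starting at the earliest
#'   first-sighting date in `individuals`.
#' @param female_p background probability that a given female is present.
#' @return data.frame with `survey_id`, `timestamp` (POSIXct, UTC),
#'   `behaviour`, and list-column `members` of individual ids.
#' @export
simulate_surveys <- function(individuals,
                             alliance_config = list(n_clusters = 6,
                                                    within_p = 0.55,
                                                    between_p = 0.02),
                             surveys_per_year = 60,
                             forage_fraction = 0.2,
                             resight_fraction = 0.1,
                             seed = 1,
                             study_span_years = 40,
                             female_p = 0.04) {
  check_prob(forage_fraction, "forage_fraction")
  check_prob(resight_fraction, "resight_fraction")
  check_prob(female_p, "female_p")
  within_p <- alliance_config$within_p
  between_p <- alliance_config$between_p
  n_clusters <- check_count(alliance_config$n_clusters, "n_clusters")
  check_prob(within_p, "within_p")
  check_prob(between_p, "between_p")
  if (within_p < between_p)
    warning("within_p < between_p: alliance clusters will be anti-assortative")
  check_count(surveys_per_year, "surveys_per_year")

  males <- individuals$id[individuals$sex == "M"]
  females <- individuals$id[individuals$sex == "F"]
  cluster <- stats::setNames(
    rep(seq_len(n_clusters), length.out = max(length(males), 1L)), males)

  start <- min(individuals$first_sighting_date)
  n_surv <- surveys_per_year * study_span_years

  with_seed(seed, {
    if (length(males)) # shuffle cluster assignment
      cluster[] <- sample(cluster)
    day <- sort(stats::runif(n_surv, 0, study_span_years * 365.25))
    ts <- as.POSIXct(start, tz = "UTC") + day * 86400 +
      stats::runif(n_surv, 7 * 3600, 17 * 3600)
    behaviours <- ifelse(
      stats::runif(n_surv) < forage_fraction, "forage",
      sample(c("social", "travel", "rest", "other"), n_surv, replace = TRUE))
    first_seen <- stats::setNames(individuals$first_sighting_date,
                                  individuals$id)
    members <- vector("list", n_surv)
    for (i in seq_len(n_surv)) {
      date_i <- as.Date(ts[i])
      elig_m <- males[first_seen[males] <= date_i]
      elig_f <- females[first_seen[females] <= date_i]
      focal_cl <- sample.int(n_clusters, 1L)
      p <- ifelse(cluster[elig_m] == focal_cl, within_p, between_p)
      mem <- elig_m[stats::runif(length(elig_m)) < p]
      mem <- c(mem, elig_f[stats::runif(length(elig_f)) < female_p])
      if (!length(mem)) { # anchor: surveys are of encountered (non-empty) groups
        pool <- if (length(elig_m)) elig_m else c(elig_m, elig_f)
        if (!length(pool)) pool <- individuals$id
        mem <- sample(pool, 1L)
      }
      members[[i]] <- sort(unname(mem))
    }
    out <- data.frame(survey_id = sprintf("S%05d", seq_len(n_surv)),
                      timestamp = ts, behaviour = behaviours,
                      stringsAsFactors = FALSE)
    out$members <- members
    # identical-membership twins within 2 h (resightings of the same group)
    is_twin <- stats::runif(n_surv) < resight_fraction
    if (any(is_twin)) {
      twins <- out[is_twin, , drop = FALSE]
      twins$survey_id <- paste0(twins$survey_id, "R")
      twins$timestamp <- twins$timestamp +
        stats::runif(nrow(twins), 10 * 60, 110 * 60)
      out <- rbind(out, twins)
    }
    out <- out[order(out$timestamp), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "alliance_cluster") <- cluster
    out
  })
}

#' Simulate per-sample biological-age offsets
#'
#' Draws the offset between biological and chronological age as a linear
#' function of centred social predictors plus crossed individual and year
#' random intercepts and residual noise:
#' `delta = beta_bond * (z - mean(z)) + beta_group * (g - mean(g)) +
#'  u[individual] + v[year] + eps`.
#' Samples with missing social metrics receive only the random components
#' (their centred fixed contribution is zero).
#'
#' @param social_metrics data.frame with one row per sample:
#'   `sample_id`, `individual_id`, `year`, `z` (bond strength), `g`
#'   (group size). `z`/`g` may be NA.
#' @param beta_bond,beta_group fixed-effect slopes (years per unit).
#' @param sigma_id,sigma_year,sigma_resid random-intercept and residual SDs
#'   (years, >= 0).
#' @param seed integer seed.
#' @return the input data.frame with columns `delta`, `u_id`, `v_year`,
#'   `eps` appended.
#' @export
simulate_offsets <- function(social_metrics, beta_bond, beta_group,
                             sigma_id, sigma_year, sigma_resid, seed = 1) {
  check_nonneg(sigma_id, "sigma_id")
  check_nonneg(sigma_year, "sigma_year")
  check_nonneg(sigma_resid, "sigma_resid")
  sm <- social_metrics
  zc <- sm$z - mean(sm$z, na.rm = TRUE)
  gc <- sm$g - mean(sm$g, na.rm = TRUE)
  zc[is.na(zc)] <- 0
  gc[is.na(gc)] <- 0
  with_seed(seed, {
    ids <- unique(sm$individual_id)
    yrs <- unique(sm$year)
    u <- stats::setNames(stats::rnorm(length(ids), 0, sigma_id), ids)
    v <- stats::setNames(stats::rnorm(length(yrs), 0, sigma_year), yrs)
    eps <- stats::rnorm(nrow(sm), 0, sigma_resid)
    sm$u_id <- unname(u[as.character(sm$individual_id)])
    sm$v_year <- unname(v[as.character(sm$year)])
    sm$eps <- eps
    sm$delta <- beta_bond * zc + beta_group * gc + sm$u_id + sm$v_year + eps
    sm
  })
}

# probe-level ground truth: intercepts, signed slopes, noise SDs
make_probe_truth <- function(n_probes, n_clock_probes, tau = 0.01,
                             mapped_fraction = 0.8, seed = 1) {
  n_probes <- check_count(n_probes, "n_probes")
  n_clock <- check_count(n_clock_probes, "n_clock_probes", min = 0L)
  if (n_clock > n_probes)
    stop_arg("n_clock_probes must not exceed n_probes")
  with_seed(seed, {
    probe_id <- sprintf("cg%06d", seq_len(n_probes))
    is_clock <- seq_len(n_probes) <= n_clock
    intercept <- stats::runif(n_probes, 0.15, 0.85)
    slope <- ifelse(is_clock,
                    sample(c(-1, 1), n_probes, replace = TRUE) *
                      stats::runif(n_probes, 0.004, 0.012),
                    0)
    noise_sd <- ifelse(is_clock, tau, 0.05)
    # clock probes are always genome-mapped; background probes make up the rest
    n_mapped_bg <- max(0L, round(mapped_fraction * n_probes) - n_clock)
    mapped <- is_clock
    bg <- which(!is_clock)
    if (length(bg) && n_mapped_bg > 0)
      mapped[sample(bg, min(n_mapped_bg, length(bg)))] <- TRUE
    data.frame(probe_id = probe_id, is_clock = is_clock,
               intercept = intercept, slope = slope, noise_sd = noise_sd,
               mapped = mapped, stringsAsFactors = FALSE)
  })
}

#' Simulate a methylation beta-value matrix
#'
#' Clock probes track biological age linearly (with clipping into [0, 1]);
#' background probes are age-independent noise around their baseline.
#' Probes both gain and lose methylation with age (signed slopes).
#'
#' @param samples data.frame with `sample_id` and `biological_age`.
#' @param truth probe truth from [make_probe_truth()], or NULL to draw one.
#' @param n_probes,n_clock_probes,tau,seed used only when `truth` is NULL.
#' @return list of class `methylation_matrix`: `values` (samples x probes,
#'   in [0, 1], dimnames set), `manifest` (probe_id, mapped), and the probe
#'   `truth` used.
#' @export
simulate_methylation <- function(samples, truth = NULL, n_probes = 30000,
                                 n_clock_probes = 1500, tau = 0.01,
                                 seed = 1) {
  if (is.null(truth))
    truth <- make_probe_truth(n_probes, n_clock_probes, tau = tau,
                              seed = derive_seed(seed, 101L))
  age <- samples$biological_age
  if (is.null(age)) stop_arg("`samples` must have a biological_age column")
  with_seed(derive_seed(seed, 102L), {
    n_s <- nrow(samples)
    n_p <- nrow(truth)
    mu <- outer(age, truth$slope) +
      matrix(truth$intercept, n_s, n_p, byrow = TRUE)
    noise <- matrix(stats::rnorm(n_s * n_p), n_s, n_p) *
      matrix(truth$noise_sd, n_s, n_p, byrow = TRUE)
    values <- clip01(mu + noise)
    dimnames(values) <- list(samples$sample_id, truth$probe_id)
    structure(list(values = values,
                   manifest = truth[, c("probe_id", "mapped")],
                   truth = truth),
              class = "methylation_matrix")
  })
}

#' Simulate a full synthetic cohort with known ground truth
#'
#' Chains the individual, survey, sampling, social-offset and methylation
#' generators so that the biological-age offset of each sample depends
#' (negatively) on the male's normalized social bond strength and
#' (positively) on his mean male group size, with crossed individual and
#' year random intercepts — the data-generating process the downstream
#' analysis assumes. Social predictors are computed from the simulated
#' surveys with the same filters the analysis applies.
#'
#' @param n_individuals cohort size (default 68).
#' @param n_samples total tissue samples (default 90); a subset of
#'   individuals is sampled at 2-3 distinct ages.
#' @param n_repeat number of individuals with more than one sample.
#' @param beta_bond,beta_group slopes of the offset model (years per unit).
#' @param sigma_id,sigma_year,sigma_resid random-effect and residual SDs.
#' @param n_probes,n_clock_probes,tau methylation dimensions and clock-probe
#'   noise SD.
#' @param surveys_per_year,study_span_years,alliance_config survey process.
#' @param rules [filter_rules()] used when computing the true social metrics.
#' @param seed integer master seed; every stage derives its own stream.
#' @return list with `individuals`, `surveys`, `samples` (incl.
#'   `chronological_age`, `biological_age`), `social_truth`, `methylation`,
#'   and `truth` (all injected parameters). `truth` is for validation only
#'   and is never an input to the analysis modules.
#' @export
simulate_cohort <- function(n_individuals = 68, n_samples = 90,
                            n_repeat = 18,
                            beta_bond = -9.75, beta_group = 0.90,
                            sigma_id = 1.5, sigma_year = 0.5,
                            sigma_resid = 1.5,
                            n_probes = 30000, n_clock_probes = 1500,
                            tau = 0.01,
                            surveys_per_year = 60, study_span_years = 40,
                            alliance_config = list(n_clusters = 6,
                                                   within_p = 0.55,
                                                   between_p = 0.02),
                            rules = filter_rules(), seed = 1) {
  inds <- simulate_individuals(n_individuals, 0.5, study_span_years,
                               seed = derive_seed(seed, 1L))
  survs <- simulate_surveys(inds, alliance_config, surveys_per_year,
                            seed = derive_seed(seed, 2L),
                            study_span_years = study_span_years)
  samples <- simulate_samples(inds, n_samples, n_repeat,
                              study_span_years = study_span_years,
                              seed = derive_seed(seed, 3L))
  # true social predictors, via the same metric definitions the analysis uses
  sm <- compute_social_metrics(samples, survs, inds, rules)
  # offsets are drawn for every sample. Social metrics drive the offset
  # only for eligible males: below the sighting threshold the normalized
  # strength is not even bounded by 1 (the normalizing maximum is taken
  # over eligible males) and group-size estimates from a handful of
  # sightings are noise, so such samples get only the random components —
  # mirroring the analysis, which models eligible males alone.
  j <- match(samples$sample_id, sm$sample_id)
  use <- !is.na(j) & sm$eligible[j]
  smt <- data.frame(sample_id = samples$sample_id,
                    individual_id = samples$individual_id,
                    year = as.integer(format(samples$sampling_date, "%Y")),
                    z = ifelse(use, sm$bond_strength_norm[j], NA_real_),
                    g = ifelse(use, sm$mean_male_group_size[j], NA_real_),
                    stringsAsFactors = FALSE)
  off <- simulate_offsets(smt, beta_bond, beta_group,
                          sigma_id, sigma_year, sigma_resid,
                          seed = derive_seed(seed, 4L))
  samples$delta <- off$delta[match(samples$sample_id, off$sample_id)]
  samples$biological_age <- samples$chronological_age + samples$delta
  meth <- simulate_methylation(samples, n_probes = n_probes,
                               n_clock_probes = n_clock_probes, tau = tau,
                               seed = derive_seed(seed, 5L))
  truth <- list(beta_bond_true = beta_bond, beta_group_true = beta_group,
                sigma_id_true = sigma_id, sigma_year_true = sigma_year,
                sigma_resid_true = sigma_resid, tau = tau,
                delta = stats::setNames(samples$delta, samples$sample_id))
  list(individuals = inds, surveys = survs, samples = samples,
       social_truth = off, methylation = meth, truth = truth)
}

#' Simulate tissue-sampling events
#'
#' Every individual receives one sample at a uniformly drawn date after both
#' its birth and the start of sampling effort; `n_repeat` individuals get a
#' second (and, as needed to reach `n_samples`, a third) sample at a
#' distinct age.
#'
#' @inheritParams simulate_cohort
#' @param individuals roster from [simulate_individuals()].
#' @param sampling_start_year first study year with tissue sampling.
#' @return data.frame `sample_id`, `individual_id`, `sampling_date`,
#'   `chronological_age` (years).
#' @export
simulate_samples <- function(individuals, n_samples = 90, n_repeat = 18,
                             study_span_years = 40, sampling_start_year = 10,
                             seed = 1) {
  n_ind <- nrow(individuals)
  if (n_samples < n_ind)
    stop_arg("n_samples must be >= number of individuals (one sample each)")
  if (n_repeat > n_ind) stop_arg("n_repeat must be <= number of individuals")
  study_start <- min(individuals$first_sighting_date)
  study_end <- study_start + round(study_span_years * 365.25)
  samp_start <- study_start + round(sampling_start_year * 365.25)
  with_seed(seed, {
    draw_date <- function(birth) {
      lo <- as.numeric(pmax(birth + 90, samp_start))
      hi <- as.numeric(study_end)
      as.Date(round(stats::runif(length(lo), lo, hi)), origin = "1970-01-01")
    }
    ind_id <- individuals$id
    dates <- draw_date(individuals$birth_date)
    extra_ids <- sample(ind_id, n_repeat)
    n_third <- n_samples - n_ind - n_repeat
    if (n_third < 0) {
      extra_ids <- extra_ids[seq_len(n_samples - n_ind)]
      n_third <- 0
    }
    third_ids <- if (n_third > 0) sample(extra_ids, n_third) else character()
    all_ids <- c(ind_id, extra_ids, third_ids)
    birth <- individuals$birth_date[match(all_ids, ind_id)]
    all_dates <- c(dates, draw_date(birth[-seq_len(n_ind)]))
    out <- data.frame(individual_id = all_ids, sampling_date = all_dates,
                      stringsAsFactors = FALSE)
    out <- out[order(out$individual_id, out$sampling_date), , drop = FALSE]
    out$sample_id <- sprintf("SMP%03d", seq_len(nrow(out)))
    birth <- individuals$birth_date[match(out$individual_id, ind_id)]
    out$chronological_age <-
      as.numeric(out$sampling_date - birth) / 365.25
    rownames(out) <- NULL
    out[, c("sample_id", "individual_id", "sampling_date",
            "chronological_age")]
  })
}
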