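# build the fixed design for a vector of term names, from the analysis table
build_design <- function(data, terms) {
  X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  for (t in terms) {
    col <- if (t == "bond_group_interaction") {
      data$bond_strength_norm * data$mean_male_group_size
    } else {
      if (is.null(data[[t]])) stop_arg("analysis table lacks column '", t, "'")
      data[[t]]
    }
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- t
  }
  X
}

fit_or_reason <- function(y, X, random, method = "ML") {
  tryCatch(fit_lmm(y, X, random, method = method),
           error = function(e) conditionMessage(e))
}

#' Select the random-effects structure by AIC
#'
#' Fits, by maximum likelihood and with the full fixed design, four
#' candidate models — no random effect (plain regression), individual only,
#' year only, and crossed individual + year — and selects the lowest AIC.
#'
#' @param y response.
#' @param X full fixed-effects design matrix.
#' @param individual_id,year grouping vectors.
#' @return data.frame (class `selection_table`) with one row per candidate:
#'   `model`, `aic`, `delta_aic`, `selected`, `note`; fitted models in
#'   `attr(, "fits")`.
#' @export
select_random_structure <- function(y, X, individual_id, year) {
  cands <- list(none = list(),
                ID = list(individual = individual_id),
                year = list(year = year),
                `ID+year` = list(individual = individual_id, year = year))
  fits <- lapply(cands, function(r) fit_or_reason(y, X, r, "ML"))
  selection_table(names(cands), fits)
}

#' Select fixed effects by AIC over a nested sequence
#'
#' Starting from the intercept-only model, terms are added in a fixed
#' order — bond strength, group size, chronological age, CV of bond
#' strength, bond x group interaction — giving six nested candidates. All
#' are fitted by ML with the supplied random structure; the lowest-AIC
#' model wins and is refit by REML for reporting (`attr(, "final_reml")`).
#' Rows with missing values in any sequence term are dropped once, so every
#' candidate sees identical data.
#'
#' @param y response (same length as `nrow(data)`).
#' @param data analysis table providing the predictor columns.
#' @param random named list of grouping vectors.
#' @param terms_sequence term names added one at a time.
#' @return a `selection_table` (six rows).
#' @export
select_fixed_effects <- function(y, data, random,
                                 terms_sequence = c(
                                   "bond_strength_norm",
                                   "mean_male_group_size",
                                   "chronological_age",
                                   "cv_bond",
                                   "bond_group_interaction")) {
  base_terms <- setdiff(unique(unlist(
    lapply(terms_sequence, function(t)
      if (t == "bond_group_interaction")
        c("bond_strength_norm", "mean_male_group_size") else t))), NULL)
  ok <- stats::complete.cases(data[, base_terms, drop = FALSE]) & !is.na(y)
  data <- data[ok, , drop = FALSE]
  y <- y[ok]
  random <- lapply(random, function(g) g[ok])
  labels <- c("null", vapply(seq_along(terms_sequence), function(i)
    paste(terms_sequence[seq_len(i)], collapse = " + "), ""))
  fits <- lapply(0:length(terms_sequence), function(i) {
    X <- build_design(data, terms_sequence[seq_len(i)])
    fit_or_reason(y, X, random, "ML")
  })
  tab <- selection_table(labels, fits)
  sel <- which(tab$selected)
  n_terms <- sel - 1L
  X_sel <- build_design(data, terms_sequence[seq_len(n_terms)])
  attr(tab, "final_reml") <- fit_or_reason(y, X_sel, random, "REML")
  attr(tab, "selected_terms") <- terms_sequence[seq_len(n_terms)]
  attr(tab, "rows_used") <- which(ok)
  tab
}

selection_table <- function(labels, fits) {
  ok <- vapply(fits, inherits, TRUE, what = "lmm_fit")
  if (!any(ok)) stop_arg("every candidate model failed to fit")
  aics <- ifelse(ok, vapply(fits, function(f)
    if (inherits(f, "lmm_fit")) f$aic else NA_real_, 0), NA_real_)
  best <- which.min(aics)
  tab <- data.frame(model = labels, aic = aics,
                    delta_aic = aics - aics[best],
                    selected = seq_along(labels) == best,
                    note = ifelse(ok, "", vapply(fits, function(f)
                      if (is.character(f)) f else "", "")),
                    stringsAsFactors = FALSE)
  attr(tab, "fits") <- fits
  class(tab) <- c("selection_table", "data.frame")
  tab
}

#' Refit the selected model on robustness subsets
#'
#' Refits a chosen fixed-effect structure (REML) on: the full data; adult
#' males only (chronological age >= `adult_age_min`); males with
#' birth dates known to +/- `accuracy_max` years; and, on the full data,
#' with age acceleration as the response. Subsets too small to fit are
#' reported as skipped with a reason, not dropped silently.
#'
#' @param data analysis table with `epigenetic_age`, `age_accel`,
#'   `chronological_age`, `birth_accuracy_years`, `individual_id`,
#'   `year_sampled` and the predictor columns.
#' @param terms fixed-effect term names (default: the three-term structure).
#' @param adult_age_min,accuracy_max subset thresholds (years).
#' @return named list; each element is an `lmm_fit` or a character skip
#'   reason.
#' @export
robustness_subsets <- function(data,
                               terms = c("bond_strength_norm",
                                         "mean_male_group_size",
                                         "chronological_age"),
                               adult_age_min = 14, accuracy_max = 0.5) {
  subsets <- list(
    full = rep(TRUE, nrow(data)),
    adults = data$chronological_age >= adult_age_min,
    high_accuracy = data$birth_accuracy_years <= accuracy_max)
  fit_subset <- function(rows, response) {
    d <- data[rows, , drop = FALSE]
    y <- d[[response]]
    ok <- stats::complete.cases(d[, terms, drop = FALSE]) & !is.na(y)
    d <- d[ok, , drop = FALSE]; y <- y[ok]
    X <- if (nrow(d)) build_design(d, terms) else
      matrix(1, 0, length(terms) + 1)
    if (nrow(d) <= ncol(X))
      return(sprintf("skipped: n = %d <= p = %d", nrow(d), ncol(X)))
    fit_or_reason(y, X, list(individual = d$individual_id,
                             year = d$year_sampled), "REML")
  }
  out <- lapply(subsets, fit_subset, response = "epigenetic_age")
  out$age_accel_response <- fit_subset(subsets$full, "age_accel")
  out
}
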