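# Known configuration schema: section -> field -> default (NULL = required
# at use time, NA = optional). Unknown keys are rejected by validate_config.
config_schema <- function() list(
  out_dir = "socioclock_run",
  seed = 42L,
  inputs = list(individuals = NA, surveys = NA, samples = NA,
                methylation = NA, probes = NA),
  simulate = list(n_individuals = 68L, n_samples = 90L, n_repeat = 18L,
                  n_probes = 30000L, n_clock_probes = 1500L, tau = 0.01,
                  surveys_per_year = 60L, study_span_years = 40L,
                  beta_bond = -9.75, beta_group = 0.90,
                  sigma_id = 1.5, sigma_year = 0.5, sigma_resid = 1.5),
  filters = list(min_sightings = 15L, resight_hours = 2,
                 exclude_forage = TRUE),
  clock = list(alpha = 0.5, scheme = "loiocv", k_folds = 10L),
  inference = list(df_method = "satterthwaite", n_sims = 1000L,
                   adult_age_min = 14, accuracy_max = 0.5))

#' Validate and default a pipeline configuration
#'
#' Reads a YAML configuration, fills in defaults (e.g. min_sightings 15,
#' alpha 0.5), rejects unknown keys by name, and resolves relative paths
#' against the configuration file's directory.
#'
#' @param path YAML file.
#' @return a fully defaulted configuration list (class `pipeline_config`).
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop_arg("config file not found: ", path)
  user <- yaml::read_yaml(path)
  schema <- config_schema()
  base_dir <- dirname(normalizePath(path))
  merge_level <- function(user, schema, prefix = "") {
    unknown <- setdiff(names(user), names(schema))
    if (length(unknown))
      stop_arg("unknown config key(s): ",
               paste0(prefix, unknown, collapse = ", "))
    out <- schema
    for (k in names(user)) {
      if (is.list(schema[[k]]) && !is.null(names(schema[[k]]))) {
        out[[k]] <- merge_level(user[[k]] %||% list(), schema[[k]],
                                paste0(prefix, k, "."))
      } else out[[k]] <- user[[k]]
    }
    out
  }
  cfg <- merge_level(user, schema)
  resolve <- function(p) {
    if (is.null(p) || (length(p) == 1 && is.na(p))) return(p)
    if (substr(p, 1, 1) %in% c("/", "~")) p else file.path(base_dir, p)
  }
  cfg$inputs <- lapply(cfg$inputs, resolve)
  cfg$out_dir <- resolve(cfg$out_dir)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

default_config <- function(out_dir = tempfile("socioclock_run"),
                           seed = 42L, ...) {
  cfg <- config_schema()
  cfg$out_dir <- out_dir
  cfg$seed <- as.integer(seed)
  dots <- list(...)
  for (k in names(dots)) cfg[[k]] <- utils::modifyList(cfg[[k]], dots[[k]])
  structure(cfg, class = "pipeline_config")
}

cfg_rules <- function(cfg)
  filter_rules(exclude_forage = cfg$filters$exclude_forage,
               resight_window_hours = cfg$filters$resight_hours,
               min_sightings = cfg$filters$min_sightings)

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> social metrics -> epigenetic clock ->
#' mixed-model inference -> mediation -> report, writing every stage's
#' artifact under `cfg$out_dir` and a machine-readable run report at the
#' end. A stage failure halts the run; the partial report (with the failed
#' stage's error) is still written. The whole run is reproducible from
#' `cfg$seed`.
#'
#' @param cfg a `pipeline_config` (see [validate_config()]).
#' @return the run report (list), invisibly on failure-free completion.
#' @export
run_all <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package_version =
                   as.character(utils::packageVersion("socioclock")),
                 seed = cfg$seed, stages = list())
  state <- new.env()
  stages <- list(
    simulate = stage_simulate, `social-metrics` = stage_social,
    clock = stage_clock, infer = stage_infer, mediate = stage_mediate,
    report = stage_report)
  for (nm in names(stages)) {
    res <- tryCatch(
      list(ok = TRUE, info = stages[[nm]](cfg, state)),
      error = function(e) list(ok = FALSE,
                               info = list(error = conditionMessage(e))))
    report$stages[[nm]] <- c(list(status = if (res$ok) "ok" else "failed"),
                             res$info)
    if (!res$ok) {
      jsonlite::write_json(report, file.path(cfg$out_dir, "run_report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           force = TRUE)
      stop_arg("pipeline stage '", nm, "' failed: ", res$info$error)
    }
  }
  report$summary <- state$summary
  jsonlite::write_json(report, file.path(cfg$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

stage_simulate <- function(cfg, state) {
  have_inputs <- !vapply(cfg$inputs, function(p)
    is.null(p) || (length(p) == 1 && is.na(p)), TRUE)
  if (all(have_inputs)) {
    state$individuals <- read_individuals(cfg$inputs$individuals)
    state$surveys <- read_surveys(cfg$inputs$surveys)
    state$samples <- read_samples(cfg$inputs$samples)
    state$meth_values <- read_methylation(cfg$inputs$methylation)
    state$manifest <- read_probes(cfg$inputs$probes)
    return(list(source = "files",
                n_individuals = nrow(state$individuals),
                n_surveys = nrow(state$surveys),
                n_samples = nrow(state$samples)))
  }
  s <- cfg$simulate
  cohort <- simulate_cohort(
    n_individuals = s$n_individuals, n_samples = s$n_samples,
    n_repeat = s$n_repeat, beta_bond = s$beta_bond,
    beta_group = s$beta_group, sigma_id = s$sigma_id,
    sigma_year = s$sigma_year, sigma_resid = s$sigma_resid,
    n_probes = s$n_probes, n_clock_probes = s$n_clock_probes, tau = s$tau,
    surveys_per_year = s$surveys_per_year,
    study_span_years = s$study_span_years,
    rules = cfg_rules(cfg), seed = cfg$seed)
  write_cohort(cohort, file.path(cfg$out_dir, "data"))
  state$individuals <- cohort$individuals
  state$surveys <- cohort$surveys
  state$samples <- cohort$samples
  state$meth_values <- cohort$methylation$values
  state$manifest <- cohort$methylation$manifest
  list(source = "simulated", n_individuals = nrow(cohort$individuals),
       n_surveys = nrow(cohort$surveys), n_samples = nrow(cohort$samples))
}

stage_social <- function(cfg, state) {
  sm <- compute_social_metrics(state$samples, state$surveys,
                               state$individuals, cfg_rules(cfg))
  utils::write.csv(sm, file.path(cfg$out_dir, "social_metrics.csv"),
                   row.names = FALSE)
  state$social <- sm
  list(n_records = nrow(sm), n_eligible = sum(sm$eligible))
}

stage_clock <- function(cfg, state) {
  X <- mask_probes(state$meth_values, state$manifest)
  samp <- state$samples[match(rownames(X), state$samples$sample_id), ]
  y <- samp$chronological_age
  ev <- loiocv_predict(X, y, samp$individual_id, alpha = cfg$clock$alpha,
                       seed = derive_seed(cfg$seed, 11L),
                       k_folds = cfg$clock$k_folds,
                       scheme = cfg$clock$scheme)
  aa <- age_accel(ev$predictions$epigenetic_age, y,
                  sample_ids = ev$predictions$sample_id)
  pred <- ev$predictions
  pred$age_accel <- aa$age_accel
  utils::write.csv(pred, file.path(cfg$out_dir, "clock_predictions.csv"),
                   row.names = FALSE)
  # final model trained on all samples at a grouped-CV-selected penalty
  imp <- impute_train_test(X)
  lam <- select_lambda(imp$train, y, alpha = cfg$clock$alpha,
                       group_ids = samp$individual_id,
                       k_folds = cfg$clock$k_folds,
                       seed = derive_seed(cfg$seed, 12L))
  model <- fit_elastic_net(imp$train, y, alpha = cfg$clock$alpha,
                           lambda = lam)
  jsonlite::write_json(list(intercept = model$intercept,
                            weights = as.list(model$weights),
                            alpha = model$alpha, lambda = model$lambda),
                       file.path(cfg$out_dir, "clock_model.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(cv_scheme = ev$cv_scheme,
                            median_abs_error = ev$median_abs_error,
                            pearson_r = ev$pearson_r,
                            n_samples = nrow(pred),
                            n_probes_mapped = ncol(X)),
                       file.path(cfg$out_dir, "clock_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  state$clock <- ev
  state$clock_pred <- pred
  list(median_abs_error = ev$median_abs_error, pearson_r = ev$pearson_r,
       n_probes_mapped = ncol(X))
}

# merged per-sample analysis table: eligible male samples with clock output
analysis_table <- function(state) {
  sm <- state$social
  pred <- state$clock_pred
  d <- merge(sm[sm$eligible & !is.na(sm$bond_strength_norm), ],
             pred[, c("sample_id", "chronological_age", "epigenetic_age",
                      "age_accel")],
             by = "sample_id")
  d$year_sampled <- d$window_end_year
  d$birth_accuracy_years <- state$individuals$birth_accuracy_years[
    match(d$individual_id, state$individuals$id)]
  d
}

stage_infer <- function(cfg, state) {
  d <- analysis_table(state)
  if (nrow(d) < 10) stop_arg("too few eligible samples for inference (",
                             nrow(d), ")")
  X_full <- build_design(d, c("bond_strength_norm", "mean_male_group_size",
                              "chronological_age"))
  rand_tab <- select_random_structure(d$epigenetic_age, X_full,
                                      d$individual_id, d$year_sampled)
  fix_tab <- select_fixed_effects(d$epigenetic_age, d,
                                  list(individual = d$individual_id,
                                       year = d$year_sampled))
  sel_tab <- rbind(
    data.frame(step = "random", rand_tab, stringsAsFactors = FALSE),
    data.frame(step = "fixed", fix_tab, stringsAsFactors = FALSE))
  utils::write.csv(sel_tab, file.path(cfg$out_dir, "model_selection.csv"),
                   row.names = FALSE)
  final <- attr(fix_tab, "final_reml")
  if (!inherits(final, "lmm_fit"))
    stop_arg("final REML refit failed: ", final)
  pv <- fixed_effect_pvalues(final, cfg$inference$df_method)
  std <- standardized_coefficients(final)
  coll <- collinearity_check(final$X)
  rob <- robustness_subsets(d, attr(fix_tab, "selected_terms"),
                            adult_age_min = cfg$inference$adult_age_min,
                            accuracy_max = cfg$inference$accuracy_max)
  rob_out <- lapply(rob, function(f) {
    if (is.character(f)) return(f)
    list(n = f$n, beta = as.list(f$beta),
         p_bond = tryCatch(
           fixed_effect_pvalues(f, cfg$inference$df_method)$p_value[
             match("bond_strength_norm", names(f$beta))],
           error = function(e) NA_real_))
  })
  final_json <- list(
    selected_terms = attr(fix_tab, "selected_terms"),
    n = final$n, method = final$method,
    estimates = as.list(final$beta),
    std_estimates = stats::setNames(as.list(std$std_estimate), std$term),
    ci = stats::setNames(Map(c, std$ci_low, std$ci_high), std$term),
    p_values = stats::setNames(as.list(pv$p_value), pv$term),
    df_method = cfg$inference$df_method,
    variance_components = as.list(final$sigma2),
    vif = as.list(coll$vif),
    robustness = rob_out)
  jsonlite::write_json(final_json, file.path(cfg$out_dir,
                                             "final_model.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  pr <- do.call(rbind, lapply(attr(fix_tab, "selected_terms"),
                              function(t) {
    data.frame(term = t, sample_id =
                 d$sample_id[attr(fix_tab, "rows_used")],
               partial_residuals(final, t), stringsAsFactors = FALSE)
  }))
  utils::write.csv(pr, file.path(cfg$out_dir, "partial_residuals.csv"),
                   row.names = FALSE)
  state$analysis <- d
  state$final <- final
  state$selection <- list(random = rand_tab, fixed = fix_tab)
  list(n_analysis = nrow(d),
       selected = fix_tab$model[fix_tab$selected],
       p_values = stats::setNames(as.list(pv$p_value), pv$term))
}

stage_mediate <- function(cfg, state) {
  med <- mediate(state$analysis, n_sims = cfg$inference$n_sims,
                 seed = derive_seed(cfg$seed, 21L))
  jsonlite::write_json(
    list(acme = med$acme, ade = med$ade, total_effect = med$total_effect,
         prop_mediated = med$prop_mediated$estimate,
         n_sims = med$n_sims, n = med$n),
    file.path(cfg$out_dir, "mediation.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE)
  state$mediation <- med
  list(acme = med$acme$estimate,
       acme_ci = c(med$acme$ci_low, med$acme$ci_high))
}

stage_report <- function(cfg, state) {
  state$summary <- make_report(cfg$out_dir)
  list(artifacts = names(state$summary$artifacts))
}

#' Summarize pipeline artifacts into a run report
#'
#' Collects the stage outputs present in an artifact directory (clock
#' metrics, selection tables, final coefficients, mediation intervals) into
#' one machine-readable summary; artifacts that are missing are listed as
#' absent rather than raising an error. If a `data/truth.json` ground-truth
#' file exists (synthetic runs), a truth-versus-estimate recovery table is
#' appended.
#'
#' @param dir artifact directory of a pipeline run.
#' @return list with `artifacts` (each present artifact summarized) and
#'   `absent`.
#' @export
make_report <- function(dir) {
  out <- list(artifacts = list(), absent = character())
  grab <- function(file, reader) {
    path <- file.path(dir, file)
    if (file.exists(path)) out$artifacts[[file]] <<- reader(path)
    else out$absent <<- c(out$absent, file)
  }
  grab("clock_metrics.json", function(p) jsonlite::read_json(p))
  grab("model_selection.csv", function(p) {
    tab <- utils::read.csv(p, stringsAsFactors = FALSE)
    list(n_random_candidates = sum(tab$step == "random"),
         n_fixed_candidates = sum(tab$step == "fixed"),
         selected = tab$model[tab$selected][2] %||%
           tab$model[tab$selected])
  })
  grab("final_model.json", function(p) jsonlite::read_json(p))
  grab("mediation.json", function(p) jsonlite::read_json(p))
  truth_path <- file.path(dir, "data", "truth.json")
  if (file.exists(truth_path) &&
      !is.null(out$artifacts[["final_model.json"]])) {
    truth <- jsonlite::read_json(truth_path)
    est <- out$artifacts[["final_model.json"]]$estimates
    out$recovery <- list(
      beta_bond = list(truth = truth$beta_bond_true,
                       estimate = est$bond_strength_norm),
      beta_group = list(truth = truth$beta_group_true,
                        estimate = est$mean_male_group_size))
  }
  out
}
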