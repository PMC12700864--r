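# draws from N(mu, Sigma); eigendecomposition tolerates the near-singular
# covariances that arise under collinear predictors
rmvn <- function(n, mu, Sigma) {
  e <- eigen(Sigma, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), length(mu))
  out <- matrix(stats::rnorm(n * length(mu)), n) %*% t(L) +
    matrix(mu, n, length(mu), byrow = TRUE)
  colnames(out) <- names(mu)
  out
}

#' Quasi-Bayesian causal mediation analysis
#'
#' Asks how much of the treatment's total effect on the outcome flows
#' through the mediator. Fits a mediator model
#' (`mediator ~ treatment + covariates`) and an outcome model
#' (`outcome ~ treatment + mediator + covariates`) by OLS, then draws the
#' two coefficient vectors from their asymptotic normal distributions and
#' forms, per draw, the average causal mediation effect
#' `ACME = a * b` (treatment->mediator path times mediator->outcome path),
#' the average direct effect `ADE`, and `total = ACME + ADE` (exact per
#' draw for linear models without interaction). Point estimates are draw
#' means; intervals are percentile.
#'
#' @param data analysis table.
#' @param treatment,mediator,outcome column names.
#' @param covariates character vector of adjustment columns (default
#'   chronological age).
#' @param n_sims number of quasi-Bayesian draws (>= 100).
#' @param seed integer seed.
#' @param level confidence level for the intervals.
#' @return list of class `mediation_result`: `acme`, `ade`, `total_effect`,
#'   `prop_mediated`, each with `estimate`, `ci_low`, `ci_high`; plus
#'   `n_sims`, `seed`, `n`, and a collinearity `condition_warning` flag.
#' @export
mediate <- function(data, treatment = "mean_male_group_size",
                    mediator = "bond_strength_norm", outcome = "age_accel",
                    covariates = "chronological_age",
                    n_sims = 1000, seed = 1, level = 0.95) {
  n_sims <- check_count(n_sims, "n_sims", min = 100L)
  cols <- c(treatment, mediator, outcome, covariates)
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop_arg("data lacks column(s): ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  names(d) <- c("trt", "med", "out", if (length(covariates))
    paste0("cov", seq_along(covariates)))
  covs <- if (length(covariates))
    paste("+", paste0("cov", seq_along(covariates), collapse = " + ")) else ""
  f_med <- stats::as.formula(paste("med ~ trt", covs))
  f_out <- stats::as.formula(paste("out ~ trt + med", covs))
  m_med <- stats::lm(f_med, data = d)
  m_out <- stats::lm(f_out, data = d)
  cond <- kappa(stats::model.matrix(m_out), exact = TRUE)
  cond_warn <- cond > 1e6
  if (cond_warn)
    warning("treatment and mediator are near-collinear (condition number ",
            format(cond, digits = 3), ")")
  # aliased coefficients (exact collinearity) contribute nothing rather
  # than poisoning the draws; the condition warning above flags the case
  clean <- function(m) {
    mu <- stats::coef(m); vc <- stats::vcov(m)
    bad <- is.na(mu)
    mu[bad] <- 0
    vc[is.na(vc) | !is.finite(vc)] <- 0
    list(mu = mu, vc = vc)
  }
  cm <- clean(m_med); co <- clean(m_out)
  draws <- with_seed(seed, {
    a_draw <- rmvn(n_sims, cm$mu, cm$vc)
    b_draw <- rmvn(n_sims, co$mu, co$vc)
    acme <- a_draw[, "trt"] * b_draw[, "med"]
    ade <- b_draw[, "trt"]
    data.frame(acme = acme, ade = ade, total = acme + ade)
  })
  alpha2 <- (1 - level) / 2
  summ <- function(v) list(estimate = mean(v),
                           ci_low = unname(stats::quantile(v, alpha2)),
                           ci_high = unname(stats::quantile(v, 1 - alpha2)))
  tot <- summ(draws$total)
  structure(list(acme = summ(draws$acme), ade = summ(draws$ade),
                 total_effect = tot,
                 prop_mediated = list(
                   estimate = stats::median(draws$acme / draws$total),
                   ci_low = NA_real_, ci_high = NA_real_),
                 draws = draws, n_sims = n_sims, seed = seed, n = nrow(d),
                 condition_warning = cond_warn),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  row <- function(lbl, s)
    cat(sprintf("  %-14s %8.4f  [%8.4f, %8.4f]\n",
                lbl, s$estimate, s$ci_low, s$ci_high))
  cat(sprintf("Causal mediation analysis (quasi-Bayesian, %d sims, n = %d)\n",
              x$n_sims, x$n))
  row("ACME", x$acme); row("ADE", x$ade); row("Total", x$total_effect)
  cat(sprintf("  prop. mediated %.3f\n", x$prop_mediated$estimate))
  invisible(x)
}
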