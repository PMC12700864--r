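#' Fit a linear mixed model with crossed random intercepts
#'
#' Direct (restricted) maximum likelihood for
#' `y ~ N(X beta, sigma2_1 Z1 Z1' + ... + sigma2_e I)` with any number of
#' crossed random-intercept factors. The marginal covariance is formed
#' densely (the intended regime is a few hundred observations), the
#' residual variance is profiled out, and the variance *ratios* are
#' optimized on the log scale, with the fixed effects profiled by
#' generalized least squares at every evaluation. Variance components are
#' floored at 1e-10 times the residual variance; boundary estimates are
#' flagged.
#'
#' @param y numeric response.
#' @param X fixed-effects design matrix (include the intercept column).
#' @param random named list of grouping vectors (length n), one per random
#'   intercept factor; may be empty (plain linear regression).
#' @param method "ML" or "REML".
#' @return object of class `lmm_fit` with elements `beta`, `se_beta`,
#'   `vcov_beta`, `sigma2` (named: one per factor plus `"resid"`),
#'   `loglik`, `aic`, `method`, `n`, `p`, `k`, `boundary`, plus the data
#'   needed by downstream operations.
#' @export
fit_lmm <- function(y, X, random = list(), method = c("ML", "REML")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop_arg("nrow(X) must equal length(y)")
  if (n <= p) stop_arg("need n > p observations")
  if (qr(X)$rank < p) stop_arg("fixed-effects design is rank deficient")
  random <- random[!vapply(random, is.null, TRUE)]
  m <- length(random)
  Zs <- lapply(random, function(g) {
    g <- factor(as.character(g))
    if (nlevels(g) < 2) stop_arg("a random factor has fewer than 2 levels")
    stats::model.matrix(~ g - 1)
  })
  ZZt <- lapply(Zs, tcrossprod)

  profile_eval <- function(loggamma) {
    gam <- exp(loggamma)
    V0 <- diag(n)
    for (j in seq_len(m)) V0 <- V0 + gam[j] * ZZt[[j]]
    R <- tryCatch(chol(V0), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    logdetV0 <- 2 * sum(log(diag(R)))
    Xi <- backsolve(R, X, transpose = TRUE)   # R^-T X
    yi <- backsolve(R, y, transpose = TRUE)
    XtViX <- crossprod(Xi)
    XtViy <- crossprod(Xi, yi)
    cXtViX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(cXtViX)) return(NULL)
    beta <- drop(chol2inv(cXtViX) %*% XtViy)
    ri <- yi - Xi %*% beta
    q <- drop(crossprod(ri))
    if (method == "ML") {
      s2 <- q / n
      ll <- -0.5 * (n * (log(2 * pi) + log(s2) + 1) + logdetV0)
    } else {
      s2 <- q / (n - p)
      ll <- -0.5 * ((n - p) * (log(2 * pi) + log(s2) + 1) + logdetV0 +
                      2 * sum(log(diag(cXtViX))))
    }
    list(ll = ll, beta = beta, s2 = s2, XtViX = XtViX, gam = gam)
  }

  if (m == 0) {
    sol <- profile_eval(numeric(0))
    loggamma_hat <- numeric(0)
  } else {
    objective <- function(lg) {
      e <- profile_eval(lg)
      if (is.null(e) || !is.finite(e$ll)) return(1e10)
      -e$ll
    }
    lower <- rep(log(1e-10), m)
    upper <- rep(log(1e6), m)
    starts <- list(rep(-1, m), rep(1.5, m), rep(log(1e-8), m))
    best <- NULL
    for (st in starts) {
      opt <- tryCatch(
        stats::nlminb(st, objective, lower = lower, upper = upper,
                      control = list(iter.max = 300)),
        error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$objective < best$objective))
        best <- opt
    }
    if (is.null(best))
      stop_arg("LMM optimization failed: non-finite likelihood everywhere")
    loggamma_hat <- best$par
    sol <- profile_eval(loggamma_hat)
    if (is.null(sol) || !is.finite(sol$ll))
      stop_arg("LMM optimization failed: non-finite likelihood at optimum")
  }

  sigma2_e <- sol$s2
  sigma2 <- c(sol$gam * sigma2_e, resid = sigma2_e)
  if (m) names(sigma2)[seq_len(m)] <- names(random)
  vcov_beta <- sigma2_e * chol2inv(chol(sol$XtViX))
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  beta <- stats::setNames(sol$beta, colnames(X))
  k <- p + m + 1L  # fixed effects + variance components incl. residual
  boundary <- if (m) sol$gam <= 1e-9 else logical(0)
  structure(list(beta = beta, se_beta = sqrt(diag(vcov_beta)),
                 vcov_beta = vcov_beta, sigma2 = sigma2,
                 loglik = sol$ll, aic = 2 * k - 2 * sol$ll,
                 method = method, n = n, p = p, k = k,
                 boundary = boundary, gamma = sol$gam,
                 y = y, X = X, random = random, Zs = Zs, ZZt = ZZt),
            class = "lmm_fit")
}

#' Akaike information criterion of a mixed-model fit
#'
#' `2k - 2 logLik` with `k` = number of fixed effects + number of variance
#' components (residual included). For model comparison across different
#' fixed-effect structures the fits must be ML; REML criteria are only
#' comparable between identical fixed designs.
#'
#' @param fit an `lmm_fit`.
#' @return AIC value.
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  fit$aic
}

#' @export
logLik.lmm_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n,
            class = "logLik")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Linear mixed model (%s), n = %d\n", x$method, x$n))
  cat("Fixed effects:\n")
  print(round(cbind(estimate = x$beta, se = x$se_beta), 4))
  cat("Variance components (SD):\n")
  print(round(sqrt(x$sigma2), 4))
  cat(sprintf("logLik = %.3f, AIC = %.3f\n", x$loglik, x$aic))
  invisible(x)
}

# (RE)ML log-likelihood as a function of the variance components
# theta = c(sigma2 per factor, sigma2_resid), beta profiled by GLS.
loglik_theta <- function(fit, theta) {
  n <- fit$n; p <- fit$p; m <- length(fit$ZZt)
  V <- diag(n) * theta[m + 1]
  for (j in seq_len(m)) V <- V + theta[j] * fit$ZZt[[j]]
  R <- chol(V)
  logdetV <- 2 * sum(log(diag(R)))
  Xi <- backsolve(R, fit$X, transpose = TRUE)
  yi <- backsolve(R, fit$y, transpose = TRUE)
  XtViX <- crossprod(Xi)
  cX <- chol(XtViX)
  beta <- drop(chol2inv(cX) %*% crossprod(Xi, yi))
  q <- drop(crossprod(yi - Xi %*% beta))
  if (fit$method == "ML")
    -0.5 * (n * log(2 * pi) + logdetV + q)
  else
    -0.5 * ((n - p) * log(2 * pi) + logdetV + 2 * sum(log(diag(cX))) + q)
}

# Var(beta_hat)(theta) = (X' V(theta)^-1 X)^-1
vcov_beta_theta <- function(fit, theta) {
  n <- fit$n; m <- length(fit$ZZt)
  V <- diag(n) * theta[m + 1]
  for (j in seq_len(m)) V <- V + theta[j] * fit$ZZt[[j]]
  R <- chol(V)
  Xi <- backsolve(R, fit$X, transpose = TRUE)
  chol2inv(chol(crossprod(Xi)))
}

#' Fixed-effect p-values
#'
#' Wald t-statistics `b / se` with either Satterthwaite denominator degrees
#' of freedom (default; computed from the numerical gradient of each
#' coefficient's sampling variance with respect to the variance components
#' and the inverse curvature of the (RE)ML surface) or a normal
#' approximation.
#'
#' @param fit an `lmm_fit` (REML recommended for Satterthwaite).
#' @param df_method "satterthwaite" or "normal".
#' @return data.frame `term`, `estimate`, `se`, `df`, `t`, `p_value`.
#' @export
fixed_effect_pvalues <- function(fit,
                                 df_method = c("satterthwaite", "normal")) {
  df_method <- match.arg(df_method)
  tval <- fit$beta / fit$se_beta
  m <- length(fit$ZZt)
  if (df_method == "normal" || m == 0) {
    if (df_method == "normal") {
      df <- rep(Inf, fit$p)
      p <- 2 * stats::pnorm(-abs(tval))
    } else { # plain regression: exact residual df
      df <- rep(fit$n - fit$p, fit$p)
      p <- 2 * stats::pt(-abs(tval), df)
    }
    return(data.frame(term = names(fit$beta), estimate = unname(fit$beta),
                      se = unname(fit$se_beta), df = df, t = unname(tval),
                      p_value = unname(p), stringsAsFactors = FALSE))
  }
  theta <- unname(fit$sigma2)
  nt <- length(theta)
  h <- pmax(abs(theta) * 1e-4, 1e-8)
  # curvature of the (RE)ML log-likelihood in theta
  H <- matrix(NA_real_, nt, nt)
  ll0 <- loglik_theta(fit, theta)
  safe_ll <- function(th) {
    th <- pmax(th, 1e-12)
    tryCatch(loglik_theta(fit, th), error = function(e) NA_real_)
  }
  for (i in seq_len(nt)) for (j in i:nt) {
    ei <- ej <- rep(0, nt); ei[i] <- h[i]; ej[j] <- h[j]
    if (i == j) {
      H[i, i] <- (safe_ll(theta + ei) - 2 * ll0 + safe_ll(theta - ei)) /
        h[i]^2
    } else {
      H[i, j] <- H[j, i] <-
        (safe_ll(theta + ei + ej) - safe_ll(theta + ei - ej) -
           safe_ll(theta - ei + ej) + safe_ll(theta - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  A <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(A) || anyNA(A) || any(diag(A) < 0)) {
    warning("variance-component information not invertible; ",
            "falling back to normal approximation")
    return(fixed_effect_pvalues(fit, "normal"))
  }
  df <- vapply(seq_len(fit$p), function(j) {
    g <- vapply(seq_len(nt), function(i) {
      ei <- rep(0, nt); ei[i] <- h[i]
      up <- vcov_beta_theta(fit, pmax(theta + ei, 1e-12))[j, j]
      dn <- vcov_beta_theta(fit, pmax(theta - ei, 1e-12))[j, j]
      (up - dn) / (2 * h[i])
    }, 0)
    denom <- drop(t(g) %*% A %*% g)
    if (denom <= 0) return(Inf)
    2 * fit$vcov_beta[j, j]^2 / denom
  }, 0)
  p <- 2 * stats::pt(-abs(tval), pmin(df, 1e8))
  data.frame(term = names(fit$beta), estimate = unname(fit$beta),
             se = unname(fit$se_beta), df = df, t = unname(tval),
             p_value = unname(p), stringsAsFactors = FALSE)
}

#' Standardized fixed-effect estimates
#'
#' Scales each coefficient (and its Wald 95% CI) by the sample standard
#' deviation of its predictor over the analysis rows, so estimates read as
#' "years of epigenetic age per 1 SD of predictor". The intercept is not
#' standardized.
#'
#' @param fit an `lmm_fit`.
#' @param level confidence level.
#' @return data.frame `term`, `sd_x`, `estimate`, `ci_low`, `ci_high` (raw
#'   scale) and `std_estimate`, `std_ci_low`, `std_ci_high`.
#' @export
standardized_coefficients <- function(fit, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  terms <- colnames(fit$X)
  sds <- apply(fit$X, 2, stats::sd)
  is_const <- sds == 0
  if (any(is_const & !(terms %in% c("(Intercept)", "intercept"))))
    stop_arg("zero-variance predictor cannot be standardized")
  out <- lapply(which(!is_const), function(j) {
    sdx <- stats::sd(fit$X[, j])
    b <- fit$beta[j]; se <- fit$se_beta[j]
    data.frame(term = terms[j], sd_x = sdx, estimate = unname(b),
               ci_low = unname(b - z * se), ci_high = unname(b + z * se),
               std_estimate = unname(b * sdx),
               std_ci_low = unname((b - z * se) * sdx),
               std_ci_high = unname((b + z * se) * sdx),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Partial residuals for one fixed-effect term
#'
#' Component-plus-residual values `x_j * b_j + e`, where `e` are the
#' conditional residuals (fixed effects and best linear unbiased
#' predictions of the random intercepts both removed). The OLS slope of the
#' partial residuals on `x_j` equals the model coefficient exactly, so
#' plotted points and fitted line show the same adjusted relationship.
#'
#' @param fit an `lmm_fit`.
#' @param term name of a column of the fixed design.
#' @return data.frame `x`, `partial_residual`.
#' @export
partial_residuals <- function(fit, term) {
  j <- match(term, colnames(fit$X))
  if (is.na(j)) stop_arg("term '", term, "' is not in the model")
  r <- fit$y - drop(fit$X %*% fit$beta)
  m <- length(fit$ZZt)
  if (m) {
    V <- diag(fit$n) * fit$sigma2[["resid"]]
    for (i in seq_len(m)) V <- V + fit$sigma2[[i]] * fit$ZZt[[i]]
    Vir <- solve(V, r)
    # conditional residuals: subtract each factor's BLUP contribution
    for (i in seq_len(m))
      r <- r - fit$sigma2[[i]] * drop(fit$ZZt[[i]] %*% Vir)
  }
  data.frame(x = fit$X[, j],
             partial_residual = fit$X[, j] * fit$beta[j] + r)
}

#' Variance inflation factors and predictor correlations
#'
#' @param X design matrix (intercept column ignored if present).
#' @return list with `vif` (named; `Inf` flags perfect collinearity) and
#'   `correlations` matrix.
#' @export
collinearity_check <- function(X) {
  X <- as.matrix(X)
  ic <- which(apply(X, 2, function(c) all(c == c[1])))
  if (length(ic)) X <- X[, -ic, drop = FALSE]
  if (nrow(X) <= ncol(X)) stop_arg("need n > p for VIFs")
  vif <- vapply(seq_len(ncol(X)), function(j) {
    # perfect fits are the expected sentinel case, not a user problem
    r2 <- suppressWarnings(
      summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  names(vif) <- colnames(X)
  list(vif = vif, correlations = stats::cor(X))
}
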