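#' Retain genome-mapped probes
#'
#' Epigenetic clocks for non-model species are trained only on array probes
#' whose sequence maps to the target genome; the mapping itself is done
#' upstream and arrives here as a per-probe flag.
#'
#' @param values samples x probes matrix of beta values (colnames = probe
#'   ids), or a `methylation_matrix`.
#' @param manifest data.frame with `probe_id` and logical `mapped`; must
#'   cover every probe in `values`.
#' @return the matrix restricted to mapped probes, column order preserved.
#' @export
mask_probes <- function(values, manifest) {
  if (inherits(values, "methylation_matrix")) {
    if (missing(manifest)) manifest <- values$manifest
    values <- values$values
  }
  probes <- colnames(values)
  idx <- match(probes, manifest$probe_id)
  if (anyNA(idx))
    stop_arg("probe(s) absent from manifest: ",
             paste(utils::head(probes[is.na(idx)], 3), collapse = ", "))
  values[, manifest$mapped[idx], drop = FALSE]
}

# median imputation per probe; parameters from the training rows only
impute_train_test <- function(X_train, X_test = NULL) {
  if (!anyNA(X_train) && (is.null(X_test) || !anyNA(X_test)))
    return(list(train = X_train, test = X_test))
  med <- apply(X_train, 2, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0.5
  fill <- function(X) {
    na <- which(is.na(X), arr.ind = TRUE)
    if (nrow(na)) X[na] <- med[na[, 2]]
    X
  }
  list(train = fill(X_train), test = if (!is.null(X_test)) fill(X_test))
}

#' Fit an elastic-net age model at a fixed penalty
#'
#' Penalized least squares of chronological age on methylation with mixing
#' parameter `alpha` (0.5 = equal lasso/ridge weight, the convention for
#' mammalian epigenetic clocks). Predictors are standardized internally and
#' coefficients returned on the original beta-value scale.
#'
#' @param X samples x probes matrix, no missing values.
#' @param y chronological ages (years).
#' @param alpha elastic-net mixing in [0, 1].
#' @param lambda positive penalty.
#' @return list of class `clock_model`: `intercept`, sparse named `weights`
#'   (nonzero only), `alpha`, `lambda`, `training_sample_ids`.
#' @export
fit_elastic_net <- function(X, y, alpha = 0.5, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop_arg("lambda must be a single positive number")
  check_prob(alpha, "alpha")
  if (nrow(X) < 3) stop_arg("need at least 3 training samples")
  if (stats::sd(y) == 0) {
    warning("constant response: returning intercept-only model")
    return(new_clock_model(mean(y), numeric(0), alpha, lambda, rownames(X)))
  }
  # decreasing warm-start path ending exactly at the requested penalty:
  # the stable way to obtain a single-lambda elastic-net solution
  path <- lambda * c(32, 16, 8, 4, 2, 1)
  fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = alpha,
                        lambda = path, standardize = TRUE)
  cf <- as.matrix(stats::coef(fit))
  cf <- cf[, ncol(cf)]
  w <- cf[-1]
  new_clock_model(cf[1], w[w != 0], alpha, lambda, rownames(X))
}

new_clock_model <- function(intercept, weights, alpha, lambda, ids) {
  structure(list(intercept = unname(intercept), weights = weights,
                 alpha = alpha, lambda = lambda,
                 training_sample_ids = ids),
            class = "clock_model")
}

#' Predict epigenetic age
#'
#' @param object a `clock_model`.
#' @param newdata samples x probes matrix containing at least the model's
#'   probes.
#' @param ... unused.
#' @return numeric vector of predicted ages (years); may be negative.
#' @export
predict.clock_model <- function(object, newdata, ...) {
  w <- object$weights
  if (!length(w)) return(rep(object$intercept, nrow(newdata)))
  miss <- setdiff(names(w), colnames(newdata))
  if (length(miss))
    stop_arg("newdata lacks model probe(s): ",
             paste(utils::head(miss, 3), collapse = ", "))
  drop(newdata[, names(w), drop = FALSE] %*% w) + object$intercept
}

#' Select the elastic-net penalty by grouped cross-validation
#'
#' Grid search over glmnet's log-spaced penalty path, choosing the lambda
#' that minimizes cross-validated squared error with folds grouped by
#' individual, so repeated samples of one animal never straddle a fold
#' boundary.
#'
#' @param X,y training matrix and ages.
#' @param alpha elastic-net mixing.
#' @param group_ids individual id per row of `X`.
#' @param k_folds number of folds (reduced, with a warning, if there are
#'   fewer groups).
#' @param seed integer seed controlling the group-to-fold assignment.
#' @param nlambda path length.
#' @return the selected lambda (positive scalar).
#' @export
select_lambda <- function(X, y, alpha = 0.5, group_ids = rownames(X),
                          k_folds = 10, seed = 1, nlambda = 100) {
  k_folds <- check_count(k_folds, "k_folds", min = 2L)
  groups <- unique(group_ids)
  if (length(groups) < k_folds) {
    k_folds <- max(2L, length(groups))
    warning("fewer groups than folds; using ", k_folds, " folds")
  }
  foldid <- with_seed(seed, {
    g <- sample(groups)
    fold_of_group <- stats::setNames(rep(seq_len(k_folds),
                                         length.out = length(g)), g)
    unname(fold_of_group[as.character(group_ids)])
  })
  # master penalty path from the full training data, then per-fold path
  # fits accumulated into a pooled CV squared error (the cv.glmnet
  # algorithm, without its per-lambda bookkeeping overhead)
  path <- glmnet::glmnet(X, y, family = "gaussian", alpha = alpha,
                         nlambda = nlambda, standardize = TRUE)$lambda
  sq_err <- matrix(NA_real_, nrow(X), length(path))
  for (k in seq_len(k_folds)) {
    test <- which(foldid == k)
    # looser convergence tolerance: these fits only rank penalties, the
    # model actually used is refit at full precision afterwards
    fit <- glmnet::glmnet(X[-test, , drop = FALSE], y[-test],
                          family = "gaussian", alpha = alpha,
                          lambda = path, standardize = TRUE,
                          thresh = 1e-5)
    pred <- stats::predict(fit, X[test, , drop = FALSE])
    # supplied-lambda fits keep the path order (values only round-trip
    # through single precision), so the mapping is positional
    sq_err[test, seq_len(ncol(pred))] <- (pred - y[test])^2
  }
  cvm <- colMeans(sq_err)
  cvm[is.na(cvm)] <- Inf  # lambdas some fold did not reach
  path[which.min(cvm)]
}

#' Leave-one-individual-out cross-validated clock predictions
#'
#' For each individual in turn, an elastic-net clock is trained on all
#' samples of all *other* individuals (with the penalty re-selected inside
#' that training set by grouped cross-validation) and predicts the held-out
#' individual's samples. With one sample per individual this reduces to
#' ordinary leave-one-out CV. Out-of-fold predictions are never informed by
#' any sample of the predicted animal.
#'
#' @param X samples x probes matrix (rownames = sample ids).
#' @param y chronological ages.
#' @param individual_ids individual id per row.
#' @param alpha elastic-net mixing (0.5 by default).
#' @param seed integer seed for fold assignment in the inner penalty search.
#' @param k_folds inner folds for penalty selection.
#' @param scheme "loiocv" (folds = individuals) or "loocv" (folds =
#'   samples, ignoring individual identity).
#' @param nlambda length of the inner penalty path; 50 log-spaced values
#'   is ample resolution at these sample sizes and halves the runtime of
#'   the default 100.
#' @return list of class `clock_evaluation`: `predictions` data.frame
#'   (`sample_id`, `individual_id`, `chronological_age`, `epigenetic_age`,
#'   `fold_id`), `median_abs_error`, `pearson_r`, `cv_scheme`, `alpha`.
#' @export
loiocv_predict <- function(X, y, individual_ids, alpha = 0.5, seed = 1,
                           k_folds = 10, scheme = c("loiocv", "loocv"),
                           nlambda = 50) {
  scheme <- match.arg(scheme)
  if (length(y) != nrow(X) || length(individual_ids) != nrow(X))
    stop_arg("X, y and individual_ids must agree in length")
  fold_of <- if (scheme == "loiocv") as.character(individual_ids)
             else as.character(seq_len(nrow(X)))
  folds <- unique(fold_of)
  if (length(folds) < 2)
    stop_arg("need samples from at least 2 individuals")
  pred <- rep(NA_real_, nrow(X))
  for (f in folds) {
    test <- which(fold_of == f)
    train <- which(fold_of != f)
    imp <- impute_train_test(X[train, , drop = FALSE],
                             X[test, , drop = FALSE])
    lam <- select_lambda(imp$train, y[train], alpha = alpha,
                         group_ids = individual_ids[train],
                         k_folds = k_folds, nlambda = nlambda,
                         seed = derive_seed(seed, match(f, folds)))
    model <- fit_elastic_net(imp$train, y[train], alpha = alpha,
                             lambda = lam)
    pred[test] <- predict(model, imp$test)
  }
  ev <- evaluate_clock(pred, y)
  structure(list(predictions = data.frame(
    sample_id = rownames(X) %||% sprintf("s%d", seq_len(nrow(X))),
    individual_id = as.character(individual_ids),
    chronological_age = y, epigenetic_age = pred,
    fold_id = fold_of, stringsAsFactors = FALSE),
    median_abs_error = ev$median_abs_error, pearson_r = ev$pearson_r,
    cv_scheme = toupper(scheme), alpha = alpha),
    class = "clock_evaluation")
}

#' Clock accuracy metrics
#'
#' Median absolute error (years) and Pearson correlation between predicted
#' and chronological age.
#'
#' @param predicted,chronological equal-length age vectors (n >= 2).
#' @return list with `median_abs_error` and `pearson_r` (NA with a warning
#'   if either vector has zero variance).
#' @export
evaluate_clock <- function(predicted, chronological) {
  if (length(predicted) != length(chronological) || length(predicted) < 2)
    stop_arg("need equal-length vectors of at least 2 samples")
  mae <- stats::median(abs(predicted - chronological))
  r <- if (stats::sd(predicted) == 0 || stats::sd(chronological) == 0) {
    warning("zero variance: Pearson r undefined")
    NA_real_
  } else stats::cor(predicted, chronological)
  list(median_abs_error = mae, pearson_r = r)
}

#' Epigenetic age acceleration (AgeAccel)
#'
#' Residuals of the ordinary least-squares regression of epigenetic age on
#' chronological age: positive values mean epigenetically older than
#' expected for the animal's chronological age. By construction the
#' residuals have mean zero and are uncorrelated with chronological age.
#'
#' @param predicted epigenetic ages.
#' @param chronological chronological ages (must vary; n >= 3).
#' @param sample_ids optional ids for the output.
#' @return data.frame `sample_id`, `age_accel`.
#' @export
age_accel <- function(predicted, chronological, sample_ids = NULL) {
  if (length(predicted) != length(chronological) || length(predicted) < 3)
    stop_arg("need equal-length vectors of at least 3 samples")
  if (stats::sd(chronological) == 0)
    stop_arg("constant chronological age: AgeAccel regression is degenerate")
  res <- stats::resid(stats::lm(predicted ~ chronological))
  data.frame(sample_id = sample_ids %||%
               (names(predicted) %||% sprintf("s%d", seq_along(predicted))),
             age_accel = unname(res), stringsAsFactors = FALSE)
}

#' @export
print.clock_evaluation <- function(x, ...) {
  cat(sprintf("Epigenetic clock (%s, alpha = %.2f): n = %d samples, %d individuals\n",
              x$cv_scheme, x$alpha, nrow(x$predictions),
              length(unique(x$predictions$individual_id))))
  cat(sprintf("  median absolute error = %.2f years, Pearson r = %.3f\n",
              x$median_abs_error, x$pearson_r))
  invisible(x)
}
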