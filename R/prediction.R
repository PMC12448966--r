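#' Fit the cross-validated lasso model and summarize it
#'
#' Runs leave-one-out penalty selection, refits the whole sample at the
#' selected penalty, and assembles the model report: selected penalty,
#' coefficients, correlation of the refit predictions with the observed
#' phenotype, and the held-out (LOO) prediction correlation obtained by
#' refitting unpenalized least squares on the selected support.
#'
#' @param X Feature matrix (participants x edge features, named columns).
#' @param y Observed phenotype (speed of forgetting) per participant.
#' @param nlambda,lambda_min_ratio Penalty grid, see
#'   \code{\link{select_lambda_loo}}.
#' @param rule Penalty-selection rule (\code{"1se"} or \code{"min"}).
#' @param loo Whether to run the held-out validation loop. Default TRUE.
#' @return An object of class \code{lasso_report}: \code{lambda_selected},
#'   \code{beta}, \code{intercept}, \code{n_selected}, \code{support},
#'   \code{fitted}, \code{fitted_r}, \code{loo_pred}, \code{loo_r},
#'   \code{cv} (selection curve). \code{fitted_r} is \code{NA} for an
#'   intercept-only (null) model.
#' @export
final_fit_and_report <- function(X, y, nlambda = 100L,
                                 lambda_min_ratio = 1e-4,
                                 rule = c("1se", "min"), loo = TRUE) {
  cv <- select_lambda_loo(X, y, nlambda, lambda_min_ratio, rule)
  fit <- lasso_fit(X, y, cv$lambda)
  fitted <- as.numeric(X %*% fit$beta) + fit$intercept
  support <- names(fit$beta)[fit$beta != 0]
  fitted_r <- if (length(support)) stats::cor(fitted, y) else NA_real_
  val <- if (loo) loo_validate(X, y, support) else
    list(pred = NULL, loo_r = NA_real_, undefined = TRUE)
  structure(list(lambda_selected = cv$lambda, beta = fit$beta,
                 intercept = fit$intercept, n_selected = fit$n_selected,
                 support = support, fitted = fitted, fitted_r = fitted_r,
                 loo_pred = val$pred, loo_r = val$loo_r,
                 loo_undefined = isTRUE(val$undefined), cv = cv),
            class = "lasso_report")
}

#' @export
print.lasso_report <- function(x, ...) {
  cat(sprintf("<lasso_report> lambda=%.5g  %d/%d features selected\n",
              x$lambda_selected, x$n_selected, length(x$beta)))
  cat(sprintf("  fitted r=%.3f  LOO r=%.3f\n",
              x$fitted_r, ifelse(is.na(x$loo_r), NA, x$loo_r)))
  if (x$n_selected) {
    sel <- x$beta[x$beta != 0]
    print(round(sel[order(-abs(sel))], 6))
  }
  invisible(x)
}

#' Leave-one-out validation on a fixed feature support
#'
#' With the selected feature set held fixed, each participant is predicted
#' from unpenalized least-squares weights refit on the remaining n - 1
#' participants. The held-out correlation is the generalization estimate;
#' it is flagged undefined when the support is empty or the predictions are
#' constant.
#'
#' @param X Feature matrix.
#' @param y Phenotype vector.
#' @param support Character vector of selected feature names.
#' @return List with \code{pred} (held-out predictions), \code{loo_r}, and
#'   \code{undefined} flag.
#' @export
loo_validate <- function(X, y, support) {
  n <- nrow(X)
  if (length(support) == 0L)
    return(list(pred = rep(mean(y), n), loo_r = NA_real_, undefined = TRUE))
  Xi <- cbind(1, X[, support, drop = FALSE])
  pred <- vapply(seq_len(n), function(i) {
    fit <- stats::lm.fit(Xi[-i, , drop = FALSE], y[-i])
    coefs <- fit$coefficients
    coefs[is.na(coefs)] <- 0      # rank-deficient refit: drop aliased terms
    sum(Xi[i, ] * coefs)
  }, numeric(1))
  if (stats::sd(pred) == 0)
    return(list(pred = pred, loo_r = NA_real_, undefined = TRUE))
  list(pred = pred, loo_r = stats::cor(pred, y), undefined = FALSE)
}

#' Refit after removing features
#'
#' Collinearity probe: drops the given features from the design and re-runs
#' the full penalty selection and refit. If the removed set carried all of
#' the usable signal, cross-validation settles on the all-zero
#' (intercept-only) solution.
#'
#' @param X Feature matrix.
#' @param y Phenotype vector.
#' @param removed Character vector of feature names to drop (may be empty).
#' @param ... Passed to \code{\link{final_fit_and_report}}.
#' @return A \code{lasso_report} with extra fields \code{removed} and
#'   \code{is_null} (TRUE when no feature survives selection).
#' @export
feature_removal_test <- function(X, y, removed = character(0), ...) {
  stopifnot(all(removed %in% colnames(X)))
  keep <- setdiff(colnames(X), removed)
  if (length(keep) == 0L) stop("cannot remove every feature")
  rep <- final_fit_and_report(X[, keep, drop = FALSE], y, ...)
  rep$removed <- removed
  rep$is_null <- rep$n_selected == 0L
  rep
}

#' Variance inflation factors of the selected features
#'
#' \eqn{VIF_j = 1 / (1 - R^2_j)} where \eqn{R^2_j} comes from regressing
#' feature j on the other selected features. Perfectly collinear features
#' report \code{Inf} rather than raising an error.
#'
#' @param X_selected Matrix of the selected features only (at least two
#'   columns, more rows than columns plus one).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(X_selected) {
  p <- ncol(X_selected)
  stopifnot(p >= 2L, nrow(X_selected) > p + 1L)
  vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, X_selected[, -j, drop = FALSE]),
                         X_selected[, j])
    r2 <- 1 - sum(fit$residuals^2) /
      sum((X_selected[, j] - mean(X_selected[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(colnames(X_selected))
}

#' Permutation-null calibration of the prediction pipeline
#'
#' Shuffles the phenotype vector and re-runs the entire penalty-selection
#' and refit procedure on each shuffle. Shuffles whose cross-validated model
#' is intercept-only count as failed to converge (null models); among the
#' converged ones, a shuffle is comparable when its refit correlation
#' reaches the unpermuted model's. The empirical p-value uses the add-one
#' correction (1 + #comparable) / (1 + #shuffles).
#'
#' @param X Feature matrix.
#' @param y Phenotype vector.
#' @param n_shuffles Number of permutations. Default 1000.
#' @param seed Optional RNG seed for reproducible shuffles.
#' @param nlambda,lambda_min_ratio Penalty grid.
#' @param rule Penalty-selection rule, as in \code{\link{select_lambda_loo}}.
#' @return An object of class \code{permutation_report}:
#'   \code{n_shuffles}, \code{observed_fitted_r}, \code{frac_null_models},
#'   \code{frac_converged}, \code{frac_comparable}, \code{empirical_p}.
#' @export
permutation_test <- function(X, y, n_shuffles = 1000L, seed = NULL,
                             nlambda = 100L, lambda_min_ratio = 1e-4,
                             rule = c("1se", "min")) {
  rule <- match.arg(rule)
  if (!is.null(seed)) set.seed(seed)
  obs <- final_fit_and_report(X, y, nlambda, lambda_min_ratio, rule,
                              loo = FALSE)
  n_null <- 0L; n_comp <- 0L
  for (s in seq_len(n_shuffles)) {
    yp <- sample(y)
    cv <- select_lambda_loo(X, yp, nlambda, lambda_min_ratio, rule)
    fit <- lasso_fit(X, yp, cv$lambda)
    if (fit$n_selected == 0L) {
      n_null <- n_null + 1L
    } else {
      r <- stats::cor(as.numeric(X %*% fit$beta) + fit$intercept, yp)
      if (!is.na(obs$fitted_r) && !is.na(r) && r >= obs$fitted_r)
        n_comp <- n_comp + 1L
    }
  }
  structure(list(n_shuffles = n_shuffles, observed_fitted_r = obs$fitted_r,
                 frac_null_models = n_null / n_shuffles,
                 frac_converged = 1 - n_null / n_shuffles,
                 frac_comparable = n_comp / n_shuffles,
                 empirical_p = (1 + n_comp) / (1 + n_shuffles)),
            class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf(paste0("<permutation_report> %d shuffles: %.1f%% null, ",
                     "%.1f%% comparable, p = %.4f\n"),
              x$n_shuffles, 100 * x$frac_null_models,
              100 * x$frac_comparable, x$empirical_p))
  invisible(x)
}

#' Predict the phenotype from a fitted report
#'
#' @param object A \code{lasso_report}.
#' @param newdata Feature matrix with the same columns the model was fit on.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.lasso_report <- function(object, newdata, ...) {
  as.numeric(newdata[, names(object$beta), drop = FALSE] %*% object$beta) +
    object$intercept
}
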