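# L1-penalized least squares by cyclic coordinate descent on the Gram
# matrix. Objective: (1/2n) * ||y - b0 - X beta||^2 + lambda * ||beta||_1,
# with features standardized to unit (1/n) variance and y centered
# internally; coefficients are reported back on the original scale and the
# intercept is unpenalized. With p <= 45 the Gram formulation makes each
# coordinate update O(p).

soft_threshold <- function(z, lambda) sign(z) * pmax(abs(z) - lambda, 0)

lasso_standardize <- function(X, y) {
  stopifnot(is.matrix(X), nrow(X) == length(y), all(is.finite(X)),
            all(is.finite(y)))
  xm <- colMeans(X)
  xs <- sqrt(colMeans(X^2) - xm^2)
  if (any(xs == 0)) stop("constant feature column: ",
                         paste(colnames(X)[xs == 0], collapse = ", "))
  Xs <- sweep(sweep(X, 2, xm, "-"), 2, xs, "/")
  list(Xs = Xs, xm = xm, xs = xs, ym = mean(y), yc = y - mean(y))
}

# Coordinate descent at one lambda. G = crossprod(Xs)/n (unit diagonal),
# b = crossprod(Xs, yc)/n. Converges when no coefficient moves more than tol.
lasso_cd <- function(G, b, lambda, beta = NULL, tol = 1e-7, max_iter = 1e5L) {
  p <- length(b)
  if (is.null(beta)) beta <- numeric(p)
  as.numeric(cd_path_cpp(G, b, lambda, beta, tol, as.integer(max_iter)))
}

# KKT stationarity check for a solved lasso system (standardized scale).
kkt_ok <- function(G, b, lambda, beta, tol = 1e-5) {
  g <- b - as.numeric(G %*% beta)
  nz <- beta != 0
  all(abs(g[!nz]) <= lambda + tol) &&
    all(abs(g[nz] - lambda * sign(beta[nz])) <= tol)
}

#' Smallest penalty that zeroes every coefficient
#'
#' The KKT threshold \eqn{\lambda_{max} = \max_j |x_j' (y - \bar y)| / n}
#' over internally standardized features; at or above it the lasso solution
#' is the intercept-only model.
#'
#' @param X Numeric feature matrix (observations x features).
#' @param y Numeric response.
#' @return Scalar lambda.
#' @export
lambda_max <- function(X, y) {
  st <- lasso_standardize(X, y)
  max(abs(crossprod(st$Xs, st$yc))) / nrow(X)
}

#' Fit the lasso at a fixed penalty
#'
#' Solves \eqn{(1/2n)\,||y - \beta_0 - X\beta||_2^2 + \lambda ||\beta||_1}
#' by cyclic coordinate descent (tolerance 1e-7 on coefficient changes),
#' standardizing features to unit variance internally and reporting
#' coefficients on the original scale; the intercept is unpenalized.
#'
#' @param X Numeric matrix, observations x features (named columns
#'   recommended).
#' @param y Numeric response vector.
#' @param lambda Non-negative penalty.
#' @param tol Convergence tolerance on standardized coefficients.
#' @return List with \code{beta} (named, original scale), \code{intercept},
#'   \code{lambda}, and \code{n_selected}.
#' @export
lasso_fit <- function(X, y, lambda, tol = 1e-7) {
  stopifnot(nrow(X) >= 3L, lambda >= 0)
  st <- lasso_standardize(X, y)
  n <- nrow(X)
  G <- crossprod(st$Xs) / n
  b <- as.numeric(crossprod(st$Xs, st$yc)) / n
  beta_s <- lasso_cd(G, b, lambda, tol = tol)
  beta_s[abs(beta_s) < 1e-12] <- 0   # clip float dust from thresholding at z ~ lambda
  if (!kkt_ok(G, b, lambda, beta_s))
    warning("KKT conditions not satisfied at the returned solution")
  beta <- beta_s / st$xs
  names(beta) <- colnames(X)
  list(beta = beta, intercept = st$ym - sum(beta * st$xm),
       lambda = lambda, n_selected = sum(beta != 0))
}

# Warm-started solution path over a decreasing lambda grid; returns a
# p x length(grid) matrix of standardized coefficients.
# The path is selection machinery: its tolerance trades precision in the
# saturated (p > n) tail for speed; the model actually reported is always
# re-solved at the selected penalty by lasso_fit at tol 1e-7.
lasso_path_std <- function(G, b, grid, var_y, tol = 1e-4) {
  cd_path_cpp(G, b, grid, numeric(length(b)), tol, 2000L, var_y)
}

default_lambda_grid <- function(lmax, nlambda = 100L, min_ratio = 1e-4) {
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = nlambda))
}

#' Select the lasso penalty by leave-one-out cross-validation
#'
#' For each of 100 log-spaced penalties spanning four decades below the
#' all-zero threshold, every observation is predicted from a model fit to
#' the remaining n - 1, giving a held-out error curve over the grid. Two
#' selection rules are available: \code{"min"} takes the penalty minimizing
#' the mean squared held-out error (exact ties toward the larger penalty),
#' while the default \code{"1se"} takes the largest penalty whose error is
#' within one standard error of that minimum -- the usual sparsity-favoring
#' rule, which keeps the pure-noise response from admitting spurious
#' features through cross-validation noise.
#'
#' @param X Feature matrix (observations x features).
#' @param y Response vector (must have positive variance).
#' @param nlambda Grid size. Default 100.
#' @param lambda_min_ratio Ratio of the smallest to the largest grid value.
#'   Default 1e-4.
#' @param rule Selection rule, \code{"1se"} (default) or \code{"min"}.
#' @return List with \code{lambda} (selected by \code{rule}),
#'   \code{lambda_min}, \code{lambda_1se}, \code{grid}, \code{cv_mse} (one
#'   value per grid point), and \code{cv_se} (standard error at the
#'   minimum).
#' @export
select_lambda_loo <- function(X, y, nlambda = 100L, lambda_min_ratio = 1e-4,
                              rule = c("1se", "min")) {
  rule <- match.arg(rule)
  n <- nrow(X)
  stopifnot(n >= 5L)
  if (stats::var(y) == 0) stop("response has zero variance")
  grid <- default_lambda_grid(lambda_max(X, y), nlambda, lambda_min_ratio)
  err <- matrix(NA_real_, n, length(grid))
  for (i in seq_len(n)) {
    st <- lasso_standardize(X[-i, , drop = FALSE], y[-i])
    m <- n - 1L
    G <- crossprod(st$Xs) / m
    bb <- as.numeric(crossprod(st$Xs, st$yc)) / m
    B <- lasso_path_std(G, bb, grid, mean(st$yc^2))
    beta <- B / st$xs                       # original scale, p x nlambda
    icpt <- st$ym - as.numeric(st$xm %*% beta)
    pred <- as.numeric(X[i, ] %*% beta) + icpt
    err[i, ] <- (y[i] - pred)^2
  }
  cv <- colMeans(err)
  k_min <- min(which(cv <= min(cv)))        # exact ties toward larger lambda
  se <- stats::sd(err[, k_min]) / sqrt(n)
  k_1se <- min(which(cv <= cv[k_min] + se))
  lam <- if (rule == "min") grid[k_min] else grid[k_1se]
  list(lambda = lam, lambda_min = grid[k_min], lambda_1se = grid[k_1se],
       grid = grid, cv_mse = cv, cv_se = se, rule = rule)
}
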