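#' Univariate penalized least-squares threshold operators
#'
#' Solves `argmin_b  (v/2) b^2 - z b + pen(|b|)` — equivalently, for
#' `v = 1`, the univariate penalized least-squares problem
#' `argmin_b 0.5 (z - b)^2 + pen(|b|)` — in closed form for the LASSO,
#' SCAD and MCP penalties. These operators are the elementary step of the
#' coordinate-descent solvers. SCAD leaves `|z| > a*lambda` untouched and
#' MCP `|z| > gamma*lambda` (for `v = 1`), the defining "unbiasedness"
#' regions of the folded-concave penalties. When the quadratic curvature
#' `v` is too small for a concave branch to be convex, the minimizer is
#' found by comparing the finitely many branch candidates, so the result
#' is the global univariate minimizer in every regime.
#'
#' @param z Linear term of the univariate objective (vectorised).
#' @param lambda Penalty level, >= 0.
#' @param family `"lasso"`, `"scad"` or `"mcp"`.
#' @param a SCAD shape, > 2 (default 3.7).
#' @param gamma MCP shape, > 1 (default 3).
#' @param v Quadratic curvature, > 0 (default 1).
#' @return The minimizing coefficient(s).
#' @export
penalty_threshold <- function(z, lambda, family = c("lasso", "scad", "mcp"),
                              a = 3.7, gamma = 3, v = 1) {
  family <- match.arg(family)
  if (lambda < 0 || v <= 0) stop("`lambda` must be >= 0 and `v` > 0")
  if (family == "scad" && a <= 2) stop("SCAD shape `a` must be > 2")
  if (family == "mcp" && gamma <= 1) stop("MCP shape `gamma` must be > 1")
  fam <- match(family, c("lasso", "scad", "mcp")) - 1L
  vapply(z, .uni_threshold_cpp, numeric(1),
         lambda = lambda, fam = fam, a = a, gamma = gamma, v = v)
}

.family_code <- function(family) {
  match(family, c("lasso", "scad", "mcp")) - 1L
}

.soft <- function(z, lambda) sign(z) * pmax(abs(z) - lambda, 0)

.pen_value <- function(b, lambda, family, a, gamma) {
  b <- abs(b)
  switch(family,
    lasso = lambda * b,
    scad = ifelse(b <= lambda, lambda * b,
           ifelse(b <= a * lambda,
                  (2 * a * lambda * b - b^2 - lambda^2) / (2 * (a - 1)),
                  lambda^2 * (a + 1) / 2)),
    mcp = ifelse(b <= gamma * lambda, lambda * b - b^2 / (2 * gamma),
                 gamma * lambda^2 / 2))
}

# one coordinate-descent solve on standardized X for squared-error loss
# with curvature v_j = mean(w * x_j^2); w = 1 for linear models. Cycles the
# active set between full sweeps. Returns the coefficients (intercept
# separate) and the objective trace (one entry per full sweep).
.cd_wls <- function(Xs, u, w, b, b0, lambda, family, a, gamma,
                    max_sweeps = 100, tol = 1e-7, keep_trace = FALSE) {
  .cd_wls_cpp(Xs, u, w, b, b0, lambda, .family_code(family), a, gamma,
              as.integer(max_sweeps), tol, keep_trace)
}

.standardize <- function(X) {
  ctr <- colMeans(X)
  Xs <- sweep(X, 2, ctr)
  scl <- sqrt(colSums(Xs^2) / nrow(X))
  scl[scl < 1e-12] <- 1
  list(Xs = sweep(Xs, 2, scl, "/"), center = ctr, scale = scl)
}

.lambda_path <- function(Xs, y, n_lambda = 100, min_ratio = 0.001) {
  n <- nrow(Xs)
  lmax <- max(abs(crossprod(Xs, y - mean(y))) / n)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

# penalized logistic solve at one lambda via IRLS + coordinate descent;
# returns standardized-scale coefficients
.pls_logistic_one <- function(Xs, y, lambda, family, a, gamma, b, b0,
                              max_irls = 12, tol = 1e-9) {
  .pls_logistic_cpp(Xs, as.numeric(y), lambda, .family_code(family), a,
                    gamma, b, b0, as.integer(max_irls), tol)
}

.fit_penalized_path <- function(X, y, family, response, lambda, a, gamma,
                                max_sweeps = 60) {
  std <- .standardize(X)
  Xs <- std$Xs
  p <- ncol(Xs)
  nb <- matrix(0, p, length(lambda))
  b0s <- numeric(length(lambda))
  sep_any <- FALSE
  w1 <- rep(1, length(y))
  solve_one <- function(lam, fam, b, b0) {
    if (response == "binomial") {
      .pls_logistic_one(Xs, y, lam, fam, a, gamma, b, b0)
    } else {
      .cd_wls(Xs, y, w1, b, b0, lam, fam, a, gamma,
              max_sweeps = max_sweeps)
    }
  }
  b_init <- rep(0, p)
  b0_init <- if (response == "binomial") {
    stats::qlogis(min(max(mean(y), 1e-6), 1 - 1e-6))
  } else mean(y)
  # warm-started lasso path; for folded-concave penalties it doubles as
  # the warm start at each lambda (mitigating local minima)
  b <- b_init; b0 <- b0_init
  lasso_b <- matrix(0, p, length(lambda)); lasso_b0 <- numeric(length(lambda))
  for (k in seq_along(lambda)) {
    fit <- solve_one(lambda[k], "lasso", b, b0)
    b <- fit$b; b0 <- fit$b0
    if (isTRUE(fit$separation)) sep_any <- TRUE
    lasso_b[, k] <- b; lasso_b0[k] <- b0
  }
  if (family == "lasso") {
    nb <- lasso_b; b0s <- lasso_b0
  } else {
    for (k in seq_along(lambda)) {
      fit <- solve_one(lambda[k], family, lasso_b[, k], lasso_b0[k])
      if (isTRUE(fit$separation)) sep_any <- TRUE
      nb[, k] <- fit$b; b0s[k] <- fit$b0
    }
  }
  if (sep_any) warning("possible complete separation in penalized logistic fit")
  # back-transform to the original covariate scale
  beta <- nb / std$scale
  intercept <- b0s - colSums(nb * (std$center / std$scale))
  list(beta = beta, intercept = intercept, std = std)
}

.cv_deviance <- function(X, y, family, response, lambda, a, gamma,
                         n_folds, seed) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  folds <- integer(length(y))
  if (response == "binomial") {
    for (cls in unique(y)) {
      k <- which(y == cls)
      folds[k] <- sample(rep_len(seq_len(n_folds), length(k)))
    }
  } else {
    folds <- sample(rep_len(seq_len(n_folds), length(y)))
  }
  dev <- matrix(NA_real_, n_folds, length(lambda))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    if (response == "binomial" && length(unique(y[tr])) < 2) next
    path <- .fit_penalized_path(X[tr, , drop = FALSE], y[tr], family,
                                response, lambda, a, gamma)
    if (FALSE) NULL
    eta <- sweep(X[!tr, , drop = FALSE] %*% path$beta, 2, -path$intercept)
    if (response == "binomial") {
      pr <- stats::plogis(eta)
      pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
      dev[f, ] <- -2 * colSums(y[!tr] * log(pr) + (1 - y[!tr]) * log(1 - pr))
    } else {
      dev[f, ] <- colSums((y[!tr] - eta)^2)
    }
  }
  colMeans(dev, na.rm = TRUE)
}

.fit_penalized <- function(X, y, family, response, lambda, n_folds, seed,
                           a, gamma, n_lambda = 100, min_ratio = 0.001) {
  X <- as.matrix(X)
  if (is.logical(y)) y <- as.numeric(y)
  if (response == "binomial" && length(unique(y)) < 2) {
    stop("`y` must contain both classes")
  }
  std0 <- .standardize(X)
  fixed_lambda <- !is.null(lambda)
  if (!fixed_lambda) lambda <- .lambda_path(std0$Xs, y, n_lambda, min_ratio)
  path <- .fit_penalized_path(X, y, family, response, lambda, a, gamma)
  cv <- NULL
  if (!fixed_lambda && length(lambda) > 1) {
    cv <- .cv_deviance(X, y, family, response, lambda, a, gamma,
                       n_folds, seed)
    k <- which.min(cv)
  } else {
    k <- length(lambda)
  }
  coefs <- path$beta[, k]
  names(coefs) <- colnames(X)
  structure(list(
    family = family, response = response,
    intercept = path$intercept[k], coefficients = coefs,
    active_set = which(coefs != 0),
    lambda_path = lambda, cv_curve = cv, chosen_lambda = lambda[k],
    a = a, gamma = gamma
  ), class = "penalized_fit")
}

#' Penalized logistic regression (LASSO / SCAD / MCP)
#'
#' Coordinate descent over IRLS-weighted least squares along a decreasing
#' lambda path (100 log-spaced values from the all-zero `lambda_max` down
#' to `0.001 * lambda_max`), with columns standardized internally and
#' coefficients returned on the original scale. `lambda` is chosen by
#' stratified K-fold cross-validated deviance (minimum rule) unless given
#' explicitly (`lambda = 0` gives the unpenalized maximum-likelihood fit).
#' Folded-concave solves (SCAD/MCP) use lasso warm starts.
#'
#' @param X Numeric design matrix (no intercept column).
#' @param y Binary response (0/1 or logical), both classes present.
#' @param family Penalty family: `"lasso"`, `"scad"` or `"mcp"`.
#' @param lambda Optional fixed penalty level; `NULL` (default) selects by
#'   cross-validation over the path.
#' @param n_folds Number of CV folds (default 10).
#' @param seed Seed for the CV fold assignment.
#' @param a,gamma SCAD and MCP shape parameters.
#' @param n_lambda Number of path values (default 100).
#' @param min_ratio Smallest path value as a fraction of `lambda_max`
#'   (default 0.001).
#' @return A `penalized_fit`: `intercept`, `coefficients`, `active_set`,
#'   `lambda_path`, `cv_curve`, `chosen_lambda`.
#' @export
fit_penalized_logistic <- function(X, y, family = c("lasso", "scad", "mcp"),
                                   lambda = NULL, n_folds = 10, seed = 1L,
                                   a = 3.7, gamma = 3, n_lambda = 100,
                                   min_ratio = 0.001) {
  family <- match.arg(family)
  .fit_penalized(X, y, family, "binomial", lambda, n_folds, seed, a, gamma,
                 n_lambda, min_ratio)
}

#' Penalized linear regression (LASSO / SCAD / MCP)
#'
#' The squared-error-loss counterpart of [fit_penalized_logistic()]; used
#' for the stacking meta-learner on continuous predicted birth weights.
#'
#' @inheritParams fit_penalized_logistic
#' @param y Numeric response.
#' @return A `penalized_fit`.
#' @export
fit_penalized_linear <- function(X, y, family = c("lasso", "scad", "mcp"),
                                 lambda = NULL, n_folds = 10, seed = 1L,
                                 a = 3.7, gamma = 3, n_lambda = 100,
                                 min_ratio = 0.001) {
  family <- match.arg(family)
  .fit_penalized(X, y, family, "gaussian", lambda, n_folds, seed, a, gamma,
                 n_lambda, min_ratio)
}

#' @export
print.penalized_fit <- function(x, ...) {
  cat("<penalized_fit> ", x$family, " ", x$response,
      "; chosen lambda = ", signif(x$chosen_lambda, 4),
      "; active set size = ", length(x$active_set), "\n", sep = "")
  invisible(x)
}

#' Predict from a penalized fit
#' @param object A `penalized_fit`.
#' @param newdata Numeric matrix with the training columns.
#' @param type `"link"`, `"response"` or `"class"`.
#' @param ... Unused.
#' @return Numeric (or logical for `"class"`) vector.
#' @export
predict.penalized_fit <- function(object, newdata,
                                  type = c("link", "response", "class"),
                                  ...) {
  type <- match.arg(type)
  eta <- object$intercept + drop(as.matrix(newdata) %*% object$coefficients)
  if (object$response == "gaussian" || type == "link") return(eta)
  p <- stats::plogis(eta)
  if (type == "response") p else p > 0.5
}

#' Positivity-constrained logistic regression
#'
#' Maximizes the logistic log-likelihood subject to non-negative slope
#' coefficients (the intercept is unconstrained) — the classical
#' combination rule for a stacking meta-learner over classifiers, where a
#' negative weight on a first-level learner is not interpretable. Solved
#' by box-constrained quasi-Newton (L-BFGS-B); at the solution every
#' strictly positive coefficient has a zero likelihood gradient and every
#' zero coefficient a non-positive one (KKT).
#'
#' @param X Numeric design matrix (no intercept column).
#' @param y Binary response with both classes.
#' @return List with `intercept`, `coefficients` (>= 0), `kkt` (max KKT
#'   violation), `converged`.
#' @export
fit_positive_logistic <- function(X, y) {
  X <- as.matrix(X)
  if (is.logical(y)) y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("`y` must contain both classes")
  n <- nrow(X); p <- ncol(X)
  nll <- function(par) {
    eta <- par[1] + drop(X %*% par[-1])
    -sum(y * eta - log1p(exp(eta))) / n
  }
  grad <- function(par) {
    eta <- par[1] + drop(X %*% par[-1])
    r <- stats::plogis(eta) - y
    c(mean(r), drop(crossprod(X, r)) / n)
  }
  opt <- stats::optim(rep(0, p + 1), nll, grad, method = "L-BFGS-B",
                      lower = c(-Inf, rep(0, p)),
                      control = list(maxit = 1000, factr = 1e4))
  g <- grad(opt$par)
  beta <- opt$par[-1]
  kkt <- max(abs(g[1]),
             max(abs(g[-1][beta > 1e-8]), 0),     # interior: gradient ~ 0
             max(-g[-1][beta <= 1e-8], 0))        # boundary: gradient >= 0
  list(intercept = opt$par[1],
       coefficients = stats::setNames(pmax(beta, 0), colnames(X)),
       kkt = kkt, converged = opt$convergence == 0)
}
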