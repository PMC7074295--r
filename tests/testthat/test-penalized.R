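# brute-force minimizer of the univariate penalized objective on a fine grid
grid_threshold <- function(z, lambda, family, a = 3.7, gamma = 3, v = 1) {
  span <- 3 * max(abs(z) / min(v, 1), 1)
  bs <- seq(-span, span, length.out = 400001)
  pen <- fetalens:::.pen_value(bs, lambda, family, a, gamma)
  bs[which.min((v / 2) * bs^2 - z * bs + pen)]
}

test_that("threshold operators match their closed forms", {
  expect_equal(penalty_threshold(3, 1, "lasso"), 2)
  expect_equal(penalty_threshold(-3, 1, "lasso"), -2)
  expect_equal(penalty_threshold(0.5, 1, "lasso"), 0)
  # SCAD leaves the unpenalized region untouched: |z| > a*lambda
  expect_equal(penalty_threshold(4, 1, "scad"), 4)
  expect_equal(penalty_threshold(-5, 1.2, "scad"), -5)
  # MCP beyond gamma*lambda is unshrunk
  expect_equal(penalty_threshold(4, 1, "mcp", gamma = 3), 4)
  expect_error(penalty_threshold(1, -1, "lasso"))
  expect_error(penalty_threshold(1, 1, "scad", a = 1.5))
  expect_error(penalty_threshold(1, 1, "mcp", gamma = 0.5))
})

test_that("threshold operators equal grid minimization everywhere tested", {
  expect_equal(penalty_threshold(1.5, 1, "mcp", gamma = 3),
               grid_threshold(1.5, 1, "mcp"), tolerance = 1e-4)
  set.seed(2)
  for (fam in c("lasso", "scad", "mcp")) {
    for (i in 1:40) {
      z <- runif(1, -4, 4)
      l <- runif(1, 0, 2)
      v <- sample(c(0.25, 0.4, 0.7, 1, 1.8), 1)
      expect_lt(abs(penalty_threshold(z, l, fam, v = v) -
                      grid_threshold(z, l, fam, v = v)), 3e-4,
                label = sprintf("%s z=%.3f l=%.3f v=%.2f", fam, z, l, v))
    }
  }
})

test_that("lambda = 0 reproduces the unpenalized logistic MLE", {
  set.seed(1)
  n <- 200
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("x", 1:6)))
  y <- rbinom(n, 1, plogis(X[, 1] - 0.8 * X[, 2]))
  fit <- fit_penalized_logistic(X, y, "lasso", lambda = 0)
  mle <- coef(glm(y ~ X, family = binomial))
  expect_equal(unname(c(fit$intercept, fit$coefficients)), unname(mle),
               tolerance = 1e-6)
})

test_that("large lambda shrinks everything to the null model", {
  set.seed(3)
  X <- matrix(rnorm(300), 100, 3)
  y <- rbinom(100, 1, 0.3)
  for (fam in c("lasso", "scad", "mcp")) {
    fit <- fit_penalized_logistic(X, y, fam, lambda = 10)
    expect_true(all(fit$coefficients == 0))
    expect_equal(fit$intercept, qlogis(mean(y)), tolerance = 1e-6)
  }
  expect_error(fit_penalized_logistic(X, rep(1, 100), "lasso"),
               "both classes")
})

test_that("the lasso path agrees with glmnet", {
  set.seed(4)
  n <- 150
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("x", 1:8)))
  y <- drop(X[, 1:2] %*% c(2, -1)) + rnorm(n)
  lam <- 0.2
  ours <- fit_penalized_linear(X, y, "lasso", lambda = lam)
  gn <- glmnet::glmnet(X, y, lambda = lam, standardize = TRUE,
                       thresh = 1e-12)
  expect_equal(unname(ours$coefficients),
               unname(as.numeric(coef(gn))[-1]), tolerance = 1e-3)
  yb <- rbinom(n, 1, plogis(drop(X[, 1:2] %*% c(1.5, -1))))
  oursb <- fit_penalized_logistic(X, yb, "lasso", lambda = 0.05)
  gnb <- glmnet::glmnet(X, yb, family = "binomial", lambda = 0.05,
                        standardize = TRUE, thresh = 1e-12)
  expect_equal(unname(oursb$coefficients),
               unname(as.numeric(coef(gnb))[-1]), tolerance = 5e-3)
})

test_that("penalized linear closed forms hold on orthonormal designs", {
  set.seed(5)
  n <- 64
  M <- scale(matrix(rnorm(n * 4), n, 4), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(M)) * sqrt(n) # exactly orthonormal, mean-zero columns
  y <- drop(Q %*% c(3, -2, 1, 0)) + rnorm(n, 0, 0.3)
  ols <- drop(crossprod(Q, y - mean(y)) / n)
  f0 <- fit_penalized_linear(Q, y, "lasso", lambda = 0)
  expect_equal(unname(f0$coefficients), ols, tolerance = 1e-5)
  lam <- 0.5
  f1 <- fit_penalized_linear(Q, y, "lasso", lambda = lam)
  expect_equal(unname(f1$coefficients),
               sign(ols) * pmax(abs(ols) - lam, 0), tolerance = 1e-4)
})

test_that("coordinate descent never increases the penalized objective", {
  set.seed(6)
  n <- 120
  X <- matrix(rnorm(n * 10), n, 10)
  Xs <- fetalens:::.standardize(X)$Xs
  y <- drop(Xs[, 1:3] %*% c(1, -2, 1.5)) + rnorm(n)
  for (fam in c("lasso", "scad", "mcp")) {
    sol <- fetalens:::.cd_wls(Xs, y, rep(1, n), rep(0, 10), mean(y),
                              lambda = 0.3, fam, a = 3.7, gamma = 3,
                              keep_trace = TRUE)
    expect_true(all(diff(sol$trace) <= 1e-10),
                label = paste(fam, "objective monotone"))
  }
})

test_that("SCAD and MCP approach the lasso as their shapes diverge", {
  set.seed(7)
  n <- 100
  X <- matrix(rnorm(n * 5), n, 5)
  y <- drop(X[, 1:2] %*% c(1.5, -1)) + rnorm(n)
  lam <- 0.3
  base <- fit_penalized_linear(X, y, "lasso", lambda = lam)
  near_s <- fit_penalized_linear(X, y, "scad", lambda = lam, a = 1e6)
  near_m <- fit_penalized_linear(X, y, "mcp", lambda = lam, gamma = 1e6)
  expect_equal(near_s$coefficients, base$coefficients, tolerance = 1e-4)
  expect_equal(near_m$coefficients, base$coefficients, tolerance = 1e-4)
})

test_that("SCAD path solutions match a 2-D grid oracle", {
  set.seed(8)
  n <- 80
  X <- matrix(rnorm(n * 2), n, 2)
  Xs <- fetalens:::.standardize(X)$Xs
  y <- drop(Xs %*% c(1.2, -0.6)) + rnorm(n, 0, 0.5)
  yc <- y - mean(y)
  for (lam in c(0.1, 0.4, 0.8)) {
    sol <- fetalens:::.cd_wls(Xs, y, rep(1, n), c(0, 0), mean(y), lam,
                              "scad", 3.7, 3)
    grid <- seq(-2, 2, length.out = 401)
    obj <- outer(grid, grid, Vectorize(function(b1, b2) {
      sum((yc - Xs[, 1] * b1 - Xs[, 2] * b2)^2) / (2 * n) +
        sum(fetalens:::.pen_value(c(b1, b2), lam, "scad", 3.7, 3))
    }))
    k <- arrayInd(which.min(obj), dim(obj))
    expect_equal(unname(sol$b), c(grid[k[1]], grid[k[2]]), tolerance = 0.02,
                 label = sprintf("scad lambda %.1f", lam))
  }
})

test_that("folded-concave selection recovers a sparse support", {
  # scaled-down selection-consistency study
  hits <- c(scad = 0, mcp = 0)
  nrep <- 5
  for (r in 1:nrep) {
    set.seed(300 + r)
    n <- 300; p <- 30
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
    y <- rbinom(n, 1, plogis(drop(X[, 1:5] %*% rep(1.2, 5))))
    for (fam in c("scad", "mcp")) {
      fit <- suppressWarnings(
        fit_penalized_logistic(X, y, fam, n_folds = 5, seed = r))
      act <- fit$active_set
      if (all(1:5 %in% act) && length(act) <= 12) {
        hits[fam] <- hits[fam] + 1
      }
    }
  }
  expect_gte(hits[["scad"]] / nrep, 0.8)
  expect_gte(hits[["mcp"]] / nrep, 0.8)
})

test_that("positivity-constrained logistic regression satisfies the KKT rules", {
  set.seed(9)
  n <- 300
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("p1", "p2", "neg")))
  y <- rbinom(n, 1, plogis(X[, 1] + 0.5 * X[, 2] - X[, 3]))
  fit <- fit_positive_logistic(X, y)
  expect_true(all(fit$coefficients >= 0))
  expect_equal(unname(fit$coefficients[["neg"]]), 0)
  expect_lt(fit$kkt, 1e-4)
  # inactive constraints: all-positive associations match the MLE
  y2 <- rbinom(n, 1, plogis(X[, 1] + 0.5 * X[, 2] + 0.8 * X[, 3]))
  fit2 <- fit_positive_logistic(X, y2)
  mle <- coef(glm(y2 ~ X, family = binomial))
  expect_equal(unname(c(fit2$intercept, fit2$coefficients)), unname(mle),
               tolerance = 1e-3)
})

test_that("positive logistic matches a projected-gradient oracle", {
  set.seed(10)
  n <- 200
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rbinom(n, 1, plogis(X[, 1] - 0.5 * X[, 2]))
  fit <- fit_positive_logistic(X, y)
  nll <- function(par) {
    eta <- par[1] + drop(X %*% par[-1])
    -sum(y * eta - log1p(exp(eta))) / n
  }
  # projected gradient descent with backtracking, independent of optim
  par <- rep(0, 4)
  for (it in 1:5000) {
    eta <- par[1] + drop(X %*% par[-1])
    r <- plogis(eta) - y
    g <- c(mean(r), drop(crossprod(X, r)) / n)
    step <- 1
    repeat {
      cand <- par - step * g
      cand[-1] <- pmax(cand[-1], 0)
      if (nll(cand) <= nll(par) - 1e-12 || step < 1e-10) break
      step <- step / 2
    }
    if (sum((cand - par)^2) < 1e-16) { par <- cand; break }
    par <- cand
  }
  expect_equal(nll(c(fit$intercept, fit$coefficients)), nll(par),
               tolerance = 1e-6)
})
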