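# Bespoke Lindstrom-Bates-style fitter for the two growth models.
#
# Both models share one structure: subject i has a 3-vector of curve
# parameters theta_i = T_i beta + b_i with b_i ~ MVN(0, Sigma), and the
# response mean is mu_ij = g(theta_i, t_ij) with within-subject errors
# Var(e_ij) = sigma^2 |mu_ij|^(2 delta).
#   logistic : g = theta1 / (1 + exp(-(t - theta2)/theta3))
#   quadratic: g = theta1 + theta2 ts + theta3 ts^2, ts = (t-210)/35
# Covariates (centred) enter only the first curve parameter.
#
# The fit alternates: (1) penalized Gauss-Newton updates of the
# empirical-Bayes modes b_i (vectorized 3x3 solves across subjects);
# (2) a weighted GLS step for beta on the linearized working response;
# (3) profiled update of (sigma^2, delta) and an EM/Laplace update of
# Sigma. The reported log-likelihood is the Laplace approximation
#   sum_i [ log p(y_i | b_i) + log p(b_i) - 1/2 log det(M_i) + 3/2 log 2pi ]
# with M_i the penalized GN curvature, and a step-halving safeguard keeps
# it non-decreasing over outer iterations.

# vectorized symmetric 3x3 inverse and determinant over n stacked matrices
# stored as columns (m11, m21, m31, m22, m32, m33)
.sym3_inv <- function(M) {
  a <- M[, 1]; b <- M[, 2]; c <- M[, 3]
  d <- M[, 4]; e <- M[, 5]; f <- M[, 6]
  co11 <- d * f - e * e
  co12 <- -(b * f - e * c)
  co13 <- b * e - d * c
  co22 <- a * f - c * c
  co23 <- -(a * e - b * c)
  co33 <- a * d - b * b
  det <- a * co11 + b * co12 + c * co13
  det <- ifelse(abs(det) < 1e-300, 1e-300, det)
  list(inv = cbind(co11, co12, co13, co22, co23, co33) / det, det = det)
}

# y = Minv %*% v for stacked symmetric 3x3 inverses and 3-vectors
.sym3_mv <- function(Minv, v) {
  cbind(Minv[, 1] * v[, 1] + Minv[, 2] * v[, 2] + Minv[, 3] * v[, 3],
        Minv[, 2] * v[, 1] + Minv[, 4] * v[, 2] + Minv[, 5] * v[, 3],
        Minv[, 3] * v[, 1] + Minv[, 5] * v[, 2] + Minv[, 6] * v[, 3])
}

.lb_mu_jac <- function(model, theta_row, tt) {
  if (model == "logistic") {
    p1 <- theta_row[, 1]; p2 <- theta_row[, 2]; p3 <- theta_row[, 3]
    L <- 1 / (1 + exp(-(tt - p2) / p3))
    mu <- p1 * L
    J2 <- -p1 * L * (1 - L) / p3
    list(mu = mu, J = cbind(L, J2, J2 * (tt - p2) / p3))
  } else {
    ts <- (tt - 210) / 35
    mu <- theta_row[, 1] + theta_row[, 2] * ts + theta_row[, 3] * ts^2
    list(mu = mu, J = cbind(1, ts, ts^2))
  }
}

.lb_fit <- function(dat, X, model, heteroscedastic, delta_fixed, ranef_diag,
                    max_outer = 200, tol = 1e-8) {
  idx <- as.integer(dat$id)           # subject index 1..n
  n <- max(idx)
  tt <- dat$t
  y <- dat$y
  q <- ncol(X)                        # amplitude design (incl. intercept)
  Xrow <- X[idx, , drop = FALSE]      # per-row amplitude design

  # -- starting values ------------------------------------------------
  if (model == "logistic") {
    st <- .logistic_starts(tt, y, idx)
    beta <- c(st[["A"]], rep(0, q - 1), st[["m"]], st[["s"]])
  } else {
    ts <- (tt - 210) / 35
    cf <- stats::coef(stats::lm(y ~ ts + I(ts^2)))
    beta <- c(cf[1], rep(0, q - 1), cf[2], cf[3])
  }
  b <- matrix(0, n, 3)
  delta <- if (!heteroscedastic) 0 else if (!is.null(delta_fixed)) delta_fixed else 0.5
  theta_of <- function(beta, b) {
    cbind(drop(Xrow %*% beta[seq_len(q)]) + b[idx, 1],
          beta[q + 1] + b[idx, 2],
          beta[q + 2] + b[idx, 3])
  }
  gj <- .lb_mu_jac(model, theta_of(beta, b), tt)
  sigma2 <- stats::var(y - gj$mu) / 4
  amp_scale <- abs(beta[1])
  Sig <- diag(c((0.12 * amp_scale)^2,
                if (model == "logistic") 36 else (0.1 * abs(beta[q + 1]) + 1)^2,
                if (model == "logistic") 4 else (0.1 * abs(beta[q + 2]) + 1)^2))

  mfloor <- 1 # |mu| floor inside the variance function
  sym6 <- function(S) S[cbind(c(1, 2, 3, 2, 3, 3), c(1, 1, 1, 2, 2, 3))]
  Minv_last <- NULL

  laplace_ll <- function(beta, b, Sig, sigma2, delta) {
    th <- theta_of(beta, b)
    gj <- .lb_mu_jac(model, th, tt)
    m <- pmax(abs(gj$mu), mfloor)
    wvar <- sigma2 * m^(2 * delta)
    e <- y - gj$mu
    Sinv <- solve(Sig + diag(1e-10, 3))
    J <- gj$J
    wi <- 1 / wvar
    JW <- J * wi
    Mstack <- cbind(rowsum(JW[, 1] * J[, 1], idx), rowsum(JW[, 1] * J[, 2], idx),
                    rowsum(JW[, 1] * J[, 3], idx), rowsum(JW[, 2] * J[, 2], idx),
                    rowsum(JW[, 2] * J[, 3], idx), rowsum(JW[, 3] * J[, 3], idx))
    Mstack <- Mstack + matrix(sym6(Sinv), n, 6, byrow = TRUE)
    dets <- .sym3_inv(Mstack)$det
    quad_b <- rowSums((b %*% Sinv) * b)
    ll_rows <- -0.5 * sum(log(2 * pi * wvar) + e^2 / wvar)
    ll_b <- -0.5 * sum(quad_b) - n / 2 * determinant(Sig)$modulus[1] -
      n * 3 / 2 * log(2 * pi)
    ll_lap <- -0.5 * sum(log(pmax(dets, 1e-300))) + n * 3 / 2 * log(2 * pi)
    as.numeric(ll_rows + ll_b + ll_lap)
  }

  ll_old <- -Inf
  info_last <- diag(length(beta))
  par_prev <- rep(Inf, length(beta) + 5)
  n_revert <- 0L
  n_plateau <- 0L
  trace <- numeric(0)
  converged <- FALSE
  for (outer in seq_len(max_outer)) {
    # ---- (1) empirical-Bayes modes: penalized Gauss-Newton ----------
    Sinv <- solve(Sig + diag(1e-10, 3))
    for (gn in 1:3) {
      th <- theta_of(beta, b)
      gj <- .lb_mu_jac(model, th, tt)
      m <- pmax(abs(gj$mu), mfloor)
      wvar <- sigma2 * m^(2 * delta)
      e <- y - gj$mu
      J <- gj$J
      wi <- 1 / wvar
      JW <- J * wi
      Mstack <- cbind(rowsum(JW[, 1] * J[, 1], idx), rowsum(JW[, 1] * J[, 2], idx),
                      rowsum(JW[, 1] * J[, 3], idx), rowsum(JW[, 2] * J[, 2], idx),
                      rowsum(JW[, 2] * J[, 3], idx), rowsum(JW[, 3] * J[, 3], idx))
      Mstack <- Mstack + matrix(sym6(Sinv), n, 6, byrow = TRUE)
      v <- cbind(rowsum(JW[, 1] * e, idx), rowsum(JW[, 2] * e, idx),
                 rowsum(JW[, 3] * e, idx)) - b %*% Sinv
      si <- .sym3_inv(Mstack)
      db <- .sym3_mv(si$inv, v)
      # step-halving where the penalized objective worsens
      pen_obj <- function(bmat) {
        th2 <- theta_of(beta, bmat)
        mu2 <- .lb_mu_jac(model, th2, tt)$mu
        sse <- rowsum((y - mu2)^2 / wvar, idx)
        drop(sse) + rowSums((bmat %*% Sinv) * bmat)
      }
      obj0 <- pen_obj(b)
      step <- rep(1, n)
      for (h in 1:4) {
        bnew <- b + db * step
        obj1 <- pen_obj(bnew)
        bad <- obj1 > obj0 + 1e-10
        if (!any(bad)) break
        step[bad] <- step[bad] / 2
      }
      b <- b + db * step
      if (model == "logistic") { # stretch must stay positive
        b[, 3] <- pmax(b[, 3], 1 - beta[q + 2])
      }
      Minv_last <- si
    }
    # ---- (2) fixed effects: marginal GLS on the linearization -------
    # Lindstrom-Bates LME step: working response w = y - mu + A beta + J b,
    # marginal covariance V_i = J_i Sigma J_i' + R_i, inverted by Woodbury
    # through the stacked per-subject 3x3 curvatures M_i.
    th <- theta_of(beta, b)
    gj <- .lb_mu_jac(model, th, tt)
    m <- pmax(abs(gj$mu), mfloor)
    wvar <- sigma2 * m^(2 * delta)
    J <- gj$J
    A <- cbind(J[, 1] * Xrow, J[, 2], J[, 3])
    p <- ncol(A)
    wresp <- y - gj$mu + drop(A %*% beta) + rowSums(J * b[idx, , drop = FALSE])
    wi <- 1 / wvar
    JW <- J * wi
    Mstack <- cbind(rowsum(JW[, 1] * J[, 1], idx), rowsum(JW[, 1] * J[, 2], idx),
                    rowsum(JW[, 1] * J[, 3], idx), rowsum(JW[, 2] * J[, 2], idx),
                    rowsum(JW[, 2] * J[, 3], idx), rowsum(JW[, 3] * J[, 3], idx))
    Mstack <- Mstack + matrix(sym6(Sinv), n, 6, byrow = TRUE)
    Minv <- .sym3_inv(Mstack)$inv
    # C_i = J_i' R_i^-1 A_i (3 x p per subject), stacked as n x (3p)
    Cstack <- matrix(0, n, 3L * p)
    for (k in seq_len(p)) {
      Cstack[, k] <- rowsum(JW[, 1] * A[, k], idx)
      Cstack[, p + k] <- rowsum(JW[, 2] * A[, k], idx)
      Cstack[, 2L * p + k] <- rowsum(JW[, 3] * A[, k], idx)
    }
    dvec <- cbind(rowsum(JW[, 1] * wresp, idx), rowsum(JW[, 2] * wresp, idx),
                  rowsum(JW[, 3] * wresp, idx))
    info <- crossprod(A * wi, A)
    rhs <- drop(crossprod(A * wi, wresp))
    Md <- .sym3_mv(Minv, dvec) # M^-1 (J'R^-1 w) per subject
    for (i in seq_len(n)) {
      Ci <- matrix(Cstack[i, ], 3L, p, byrow = TRUE)
      Mi <- matrix(Minv[i, c(1, 2, 3, 2, 4, 5, 3, 5, 6)], 3, 3)
      info <- info - crossprod(Ci, Mi %*% Ci)
      rhs <- rhs - drop(crossprod(Ci, Md[i, ]))
    }
    beta_new <- tryCatch(
      drop(solve(info + diag(1e-10 * max(diag(info)), p), rhs)),
      error = function(err) beta)
    if (model == "logistic") {
      beta_new[q + 2] <- max(beta_new[q + 2], 2) # stretch > 0
    }
    beta <- beta_new
    info_last <- info

    # ---- (3) variance parameters ------------------------------------
    th <- theta_of(beta, b)
    gj <- .lb_mu_jac(model, th, tt)
    m <- pmax(abs(gj$mu), mfloor)
    e <- y - gj$mu
    # EM correction: E[(y - mu(b))^2 | y] = e^2 + J' Cov(b|y) J, with the
    # conditional covariance from the penalized GN curvature; without it
    # sigma^2 is computed from shrunken residuals and is biased low
    J <- gj$J
    Iv <- Minv_last$inv[idx, , drop = FALSE]
    qform <- Iv[, 1] * J[, 1]^2 + Iv[, 4] * J[, 2]^2 + Iv[, 6] * J[, 3]^2 +
      2 * (Iv[, 2] * J[, 1] * J[, 2] + Iv[, 3] * J[, 1] * J[, 3] +
           Iv[, 5] * J[, 2] * J[, 3])
    e2c <- e^2 + qform
    Sig_old <- Sig; s2_old <- sigma2; d_old <- delta
    if (heteroscedastic && is.null(delta_fixed)) {
      lm2 <- log(m)
      prof <- function(d) {
        s2 <- mean(e2c * m^(-2 * d))
        length(e) * log(s2) + 2 * d * sum(lm2)
      }
      delta <- stats::optimize(prof, c(0, 3))$minimum
    }
    sigma2 <- mean(e2c * m^(-2 * delta))
    # EM/Laplace update of Sigma from modes + conditional curvature
    Iv <- Minv_last$inv
    Smat <- matrix(0, 3, 3)
    Smat[1, 1] <- mean(b[, 1]^2 + Iv[, 1])
    Smat[2, 2] <- mean(b[, 2]^2 + Iv[, 4])
    Smat[3, 3] <- mean(b[, 3]^2 + Iv[, 6])
    Smat[1, 2] <- Smat[2, 1] <- mean(b[, 1] * b[, 2] + Iv[, 2])
    Smat[1, 3] <- Smat[3, 1] <- mean(b[, 1] * b[, 3] + Iv[, 3])
    Smat[2, 3] <- Smat[3, 2] <- mean(b[, 2] * b[, 3] + Iv[, 5])
    if (ranef_diag) Smat <- diag(diag(Smat))
    eg <- eigen(Smat, symmetric = TRUE)
    Sig <- eg$vectors %*% diag(pmax(eg$values, 1e-8)) %*% t(eg$vectors)

    # ---- ascent safeguard on the Laplace log-likelihood -------------
    ll <- laplace_ll(beta, b, Sig, sigma2, delta)
    reverted <- FALSE
    if (is.finite(ll_old) && ll < ll_old - 1e-8 * (abs(ll_old) + 1)) {
      for (h in 1:5) {
        Sig <- (Sig + Sig_old) / 2
        sigma2 <- (sigma2 + s2_old) / 2
        delta <- (delta + d_old) / 2
        ll <- laplace_ll(beta, b, Sig, sigma2, delta)
        if (ll >= ll_old - 1e-8 * (abs(ll_old) + 1)) break
      }
      if (ll < ll_old) {
        Sig <- Sig_old; sigma2 <- s2_old; delta <- d_old
        ll <- ll_old
        reverted <- TRUE
      }
    }
    n_revert <- if (reverted) n_revert + 1L else 0L
    trace <- c(trace, ll)
    par_now <- c(beta, diag(Sig), sigma2, delta)
    small_gain <- is.finite(ll_old) &&
      abs(ll - ll_old) < 1e-6 * (abs(ll_old) + 1)
    n_plateau <- if (small_gain) n_plateau + 1L else 0L
    done <- (is.finite(ll_old) &&
             abs(ll - ll_old) < tol * (abs(ll_old) + 1)) ||
            (outer > 1 &&
             max(abs(par_now - par_prev) / (abs(par_prev) + 1)) < 1e-6) ||
            n_revert >= 2L ||  # the safeguard pinned the likelihood
            n_plateau >= 3L    # relative gains < 1e-6 three times running
    par_prev <- par_now
    ll_old <- ll
    if (done) {
      converged <- TRUE
      break
    }
  }

  # Wald covariance of the fixed effects: inverse of the marginal GLS
  # information accumulated in the last Lindstrom-Bates LME step
  beta_cov <- tryCatch(solve(info_last), error = function(err)
    matrix(NA_real_, length(beta), length(beta)))

  list(beta = beta, b = b, Sigma = Sig, delta = delta, sigma2 = sigma2,
       loglik = ll_old, loglik_trace = trace, converged = converged,
       beta_cov = beta_cov, q = q)
}
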