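# Poisson mixed-model engine: log-link GLMM with a single random intercept
# per group, fitted by maximizing the Laplace-approximated marginal
# likelihood (adaptive Gauss-Hermite quadrature available as a cross-check
# mode). The random intercept is one-dimensional per group, so the inner
# profiling step is an exact per-group Newton iteration and a full fit costs
# a few milliseconds -- which is what makes parametric-bootstrap inference
# with hundreds of refits per test practical.

# Gauss-Hermite nodes and weights via the Golub-Welsch eigen decomposition
# of the Jacobi matrix (weight function exp(-x^2)).
gh_nodes <- function(n) {
  if (n == 1) return(list(x = 0, w = sqrt(pi)))
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

# Inner step: posterior modes of the group intercepts given (beta, sigma).
# h_i(b) = sum_j y_ij eta_ij + S_i b - e^b T_i - b^2 / (2 sigma^2);
# solved by vectorized Newton across groups.
pglmm_modes <- function(s_grp, t_grp, sigma2) {
  b <- log((s_grp + 0.1) / (t_grp + 0.1)) # moment start
  b <- pmin(pmax(b, -5), 5)
  for (it in 1:50) {
    eb <- exp(b)
    grad <- s_grp - t_grp * eb - b / sigma2
    hess <- -(t_grp * eb + 1 / sigma2)
    step <- grad / hess
    b <- b - pmin(pmax(step, -2), 2)
    if (max(abs(step)) < 1e-12) break
  }
  b
}

#' Fit a Poisson GLMM with one random intercept per group
#'
#' Maximizes the marginal likelihood of `y ~ Poisson(exp(X beta + b_g))`,
#' `b_g ~ N(0, sigma^2)`, integrating the group intercepts out by the Laplace
#' approximation (default) or by adaptive Gauss-Hermite quadrature
#' (`method = "agq"`, `nodes` points) as an accuracy cross-check. `sigma` is
#' profiled on `[0, Inf)`; at the boundary the model collapses exactly to an
#' ordinary Poisson GLM.
#'
#' @param y Non-negative integer response vector.
#' @param x Fixed-effects design matrix (with intercept column).
#' @param group Factor of group (site) memberships.
#' @param method `"laplace"` or `"agq"`.
#' @param nodes Quadrature nodes for `"agq"` (default 10).
#' @param start Optional start values `c(beta, sigma)`.
#' @param hessian Compute the observed information for `vcov_beta`
#'   (skipped in bootstrap refits, where only the likelihood is needed).
#' @param fix_sigma Optional fixed value for `sigma`; `fix_sigma = 0` reduces
#'   the model to an ordinary Poisson GLM.
#' @return Object of class `pglmm`: coefficients, `sigma`, `logLik` (includes
#'   the full Poisson constant, so comparable with [lme4::glmer()]),
#'   conditional modes `ranef`, fitted means, `vcov_beta`, convergence info.
#' @export
pglmm <- function(y, x, group, method = c("laplace", "agq"), nodes = 10,
                  start = NULL, hessian = TRUE, fix_sigma = NULL) {
  method <- match.arg(method)
  x <- as.matrix(x)
  group <- droplevels(as.factor(group))
  stopifnot(length(y) == nrow(x), length(group) == length(y),
            all(y >= 0), all(y == round(y)))
  p <- ncol(x)
  g <- as.integer(group)
  n_g <- nlevels(group)
  s_grp <- as.vector(rowsum(y, g))
  const <- -sum(lgamma(y + 1))
  gh <- if (method == "agq") gh_nodes(nodes) else NULL

  # analytic gradient of the Laplace objective (envelope theorem for the
  # modes; the log-determinant's dependence on the modes handled implicitly)
  grad_laplace <- function(par) {
    beta <- par[seq_len(p)]
    sigma <- par[p + 1]
    eta0 <- as.vector(x %*% beta)
    mu0 <- exp(eta0)
    t_grp <- as.vector(rowsum(mu0, g))
    if (sigma < 1e-8) {
      return(c(crossprod(x, y - mu0), 0))
    }
    sigma2 <- sigma^2
    b <- pglmm_modes(s_grp, t_grp, sigma2)
    d_i <- t_grp * exp(b)
    w_i <- 1 + sigma2 * d_i
    m_obs <- (1 + sigma2 / (2 * w_i^2))[g] * mu0 * exp(b)[g]
    g_beta <- crossprod(x, y - m_obs)
    g_sigma <- sum(b^2 / sigma^3 - sigma * d_i / w_i -
                     sigma * b * d_i / w_i^2)
    c(g_beta, g_sigma)
  }

  loglik <- function(par) {
    beta <- par[seq_len(p)]
    sigma <- par[p + 1]
    eta0 <- as.vector(x %*% beta)
    if (max(abs(eta0)) > 30) return(-1e10)
    yeta <- sum(y * eta0)
    t_grp <- as.vector(rowsum(exp(eta0), g))
    if (sigma < 1e-8) {
      return(yeta - sum(t_grp) + const)
    }
    sigma2 <- sigma^2
    b <- pglmm_modes(s_grp, t_grp, sigma2)
    eb <- exp(b)
    h_hat <- s_grp * b - t_grp * eb - b^2 / (2 * sigma2)
    if (method == "laplace") {
      ll_g <- h_hat - 0.5 * log1p(sigma2 * t_grp * eb)
    } else {
      s_i <- 1 / sqrt(t_grp * eb + 1 / sigma2)
      contrib <- vapply(seq_along(gh$x), function(k) {
        bk <- b + sqrt(2) * s_i * gh$x[k]
        gh$w[k] * exp(s_grp * bk - t_grp * exp(bk) - bk^2 / (2 * sigma2) -
                        h_hat + gh$x[k]^2)
      }, numeric(n_g))
      ll_g <- h_hat + log(sqrt(2) * s_i * rowSums(contrib)) -
        0.5 * log(2 * pi * sigma2)
    }
    out <- yeta + sum(ll_g) + const
    if (!is.finite(out)) -1e10 else out
  }

  warm <- !is.null(start)
  if (!warm) {
    b0 <- tryCatch(
      stats::glm.fit(x, y, family = stats::poisson())$coefficients,
      error = function(e) c(log(mean(y) + 0.01), rep(0, p - 1))
    )
    b0[!is.finite(b0)] <- 0
    start <- c(b0, if (is.null(fix_sigma)) 0.3 else fix_sigma)
  }
  if (is.null(fix_sigma)) {
    lo <- c(rep(-Inf, p), 0)
    start[p + 1] <- max(start[p + 1], 0)
    gr <- if (method == "laplace") function(par) -grad_laplace(par) else NULL
    opt <- stats::optim(start, function(par) -loglik(par), gr = gr,
                        method = "L-BFGS-B", lower = lo,
                        control = list(maxit = 500, factr = 1e5))
    if (!warm) {
      # second pass from the optimum guards against premature line-search stops
      opt2 <- stats::optim(opt$par, function(par) -loglik(par), gr = gr,
                           method = "L-BFGS-B", lower = lo,
                           control = list(maxit = 500, factr = 1e5))
      if (opt2$value < opt$value) opt <- opt2
    }
  } else {
    # sigma pinned: optimize the fixed effects only
    ob <- stats::optim(start[seq_len(p)],
                       function(bb) -loglik(c(bb, fix_sigma)),
                       method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-14))
    ob2 <- stats::optim(ob$par, function(bb) -loglik(c(bb, fix_sigma)),
                        method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    if (ob2$value < ob$value) ob <- ob2
    opt <- list(par = c(ob$par, fix_sigma), value = ob$value,
                convergence = ob$convergence)
  }
  beta <- opt$par[seq_len(p)]
  names(beta) <- colnames(x)
  sigma <- unname(opt$par[p + 1])
  eta0 <- as.vector(x %*% beta)
  t_grp <- as.vector(rowsum(exp(eta0), g))
  b_hat <- if (sigma < 1e-8) rep(0, n_g)
           else pglmm_modes(s_grp, t_grp, sigma^2)
  names(b_hat) <- levels(group)
  hess <- if (hessian) tryCatch(
    stats::optimHess(opt$par, function(par) -loglik(par)),
    error = function(e) NULL
  ) else NULL
  vcov_beta <- if (!is.null(hess)) {
    tryCatch(solve(hess)[seq_len(p), seq_len(p), drop = FALSE],
             error = function(e) matrix(NA_real_, p, p))
  } else matrix(NA_real_, p, p)
  structure(list(
    coefficients = beta, sigma = sigma, sigma2 = sigma^2,
    logLik = -opt$value, ranef = b_hat,
    eta_fixed = eta0, fitted = exp(eta0 + b_hat[g]),
    vcov_beta = vcov_beta, y = y, x = x, group = group,
    method = method, nodes = if (method == "agq") nodes else NA_integer_,
    converged = opt$convergence == 0, par = opt$par
  ), class = "pglmm")
}

#' @export
print.pglmm <- function(x, ...) {
  cat("Poisson GLMM (", x$method, "), ", nlevels(x$group), " groups, n = ",
      length(x$y), "\n", sep = "")
  print(round(x$coefficients, 4))
  cat("sigma(site) =", round(x$sigma, 4),
      " logLik =", round(x$logLik, 2), "\n")
  invisible(x)
}

#' @export
logLik.pglmm <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients) + 1,
            class = "logLik")
}

#' Simulate responses from a fitted Poisson GLMM
#'
#' Draws new group intercepts from `N(0, sigma_hat^2)` and Poisson responses
#' from the fitted fixed-effect linear predictor — the parametric-bootstrap
#' data-generating step.
#'
#' @param object A `pglmm` fit.
#' @param nsim Number of response vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List of integer response vectors.
#' @export
simulate.pglmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  g <- as.integer(object$group)
  lapply(seq_len(nsim), function(k) {
    b <- stats::rnorm(nlevels(object$group), 0, object$sigma)
    stats::rpois(length(object$y), exp(object$eta_fixed + b[g]))
  })
}

# Refit a pglmm to a new response, warm-started at the previous optimum.
refit_pglmm <- function(object, newy) {
  pglmm(newy, object$x, object$group, method = object$method,
        nodes = if (is.na(object$nodes)) 10 else object$nodes,
        start = object$par, hessian = FALSE)
}
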