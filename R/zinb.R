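## Zero-inflated negative binomial baseline: mixture of a point mass at
## zero (intercept-only mixing probability pi) and NB(exp(X beta), theta),
## fit by EM. Used for simulation benchmarking only; the E-step posterior
## of the structural-zero indicator feeds a weighted IRLS M-step.

#' Fit a zero-inflated negative binomial model
#'
#' Mixture `pi * I(y = 0) + (1 - pi) * NB(exp(X beta), theta)` with a
#' scalar (intercept-only) zero-inflation probability, fit by
#' expectation-maximization. The M-step reuses the [nbridge()] machinery
#' with posterior weights `1 - z` on the negative binomial component.
#'
#' @param y non-negative integer counts.
#' @param X design matrix.
#' @param lambda optional ridge penalty for the NB component (default 0).
#' @param control list from [nb_control()]; `maxit` bounds the EM sweeps.
#' @return A list of class `zinb` with elements `beta`, `theta`,
#'   `zero_prob`, `fitted` (mean of the NB component), `mean_fitted`
#'   (marginal mean `(1 - pi) * fitted`), `loglik`, `converged`,
#'   `degenerate` (all-zero response), `n_iter`.
#' @export
fit_zinb <- function(y, X, lambda = 0, control = nb_control()) {
  X <- design_matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  if (any(y < 0) || any(y != round(y)))
    stop_validation("y must contain non-negative integer counts")
  if (all(y == 0)) {
    out <- list(beta = stats::setNames(rep(NA_real_, ncol(X)), colnames(X)),
                theta = NA_real_, zero_prob = 1, fitted = rep(0, n),
                mean_fitted = rep(0, n), loglik = 0, converged = TRUE,
                degenerate = TRUE, n_iter = 0L, y = y)
    class(out) <- "zinb"
    return(out)
  }

  zero <- y == 0
  pi_hat <- min(max(mean(zero) / 2, 1e-4), 1 - 1e-4)
  nb <- nbridge(X, y, lambda = lambda, control = control)
  beta <- nb$beta
  theta <- nb$theta

  obs_loglik <- function(beta, theta, pi_hat) {
    mu <- pmax(exp(drop(X %*% beta)), MU_FLOOR)
    f <- stats::dnbinom(y, size = theta, mu = mu)
    sum(log(pmax(ifelse(zero, pi_hat + (1 - pi_hat) * f, (1 - pi_hat) * f),
                 1e-300)))
  }

  ll <- obs_loglik(beta, theta, pi_hat)
  converged <- FALSE
  it <- 0L
  em_max <- min(control$maxit, 100L)
  while (it < em_max) {
    it <- it + 1L
    mu <- pmax(exp(drop(X %*% beta)), MU_FLOOR)
    f0 <- stats::dnbinom(0, size = theta, mu = mu)
    z <- ifelse(zero, pi_hat / pmax(pi_hat + (1 - pi_hat) * f0, 1e-300), 0)
    pi_hat <- min(max(mean(z), 1e-8), 1 - 1e-8)
    w <- pmax(1 - z, 1e-8)
    m <- nbridge(X, y, lambda = lambda, weights = w,
                 beta_init = beta, theta_init = theta, control = control)
    beta <- m$beta
    theta <- m$theta
    ll_new <- obs_loglik(beta, theta, pi_hat)
    if (!is.finite(ll_new)) break
    if (abs(ll_new - ll) < control$tol * (abs(ll) + 0.1)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }

  fitted <- exp(drop(X %*% beta))
  out <- list(beta = beta, theta = theta, zero_prob = pi_hat,
              fitted = fitted, mean_fitted = (1 - pi_hat) * fitted,
              loglik = ll, converged = converged, degenerate = FALSE,
              n_iter = it, y = y)
  class(out) <- "zinb"
  out
}

#' @export
print.zinb <- function(x, ...) {
  cat("Zero-inflated negative binomial fit\n")
  cat("  zero_prob =", format(x$zero_prob, digits = 4),
      " theta =", format(x$theta, digits = 4),
      " converged:", x$converged, "\n")
  if (!x$degenerate) {
    cat("NB-component coefficients (log scale):\n")
    print(round(x$beta, 4))
  } else cat("  degenerate fit: all counts zero\n")
  invisible(x)
}
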