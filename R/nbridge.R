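## Ridge-penalized negative binomial regression with log link.
##
## Parameterization used everywhere in this package: NB(mu, theta) with
## variance mu + mu^2/theta (theta is the "size"/dispersion; larger theta
## means closer to Poisson). The penalized objective is
##   Q(beta, theta) = loglik(beta, theta) - (lambda/2) * sum_{j penalized} beta_j^2
## with the intercept unpenalized. beta is updated by iteratively
## reweighted least squares with an exact ridge solve and step halving;
## theta by safeguarded Newton on log(theta). Both steps are ascent steps,
## so Q is non-decreasing across outer iterations.

MU_FLOOR <- 1e-10

nb_loglik <- function(y, mu, theta, weights = NULL) {
  ll <- stats::dnbinom(y, size = theta, mu = pmax(mu, MU_FLOOR), log = TRUE)
  if (is.null(weights)) sum(ll) else sum(weights * ll)
}

## Maximum-likelihood dispersion given fitted means: safeguarded Newton on
## log(theta), clamped to [theta_min, theta_max]. Optional prior weights.
theta_ml_update <- function(y, mu, theta, weights = NULL,
                            theta_min = 1e-3, theta_max = 1e5, maxit = 10) {
  if (is.null(weights)) weights <- rep.int(1, length(y))
  mu <- pmax(mu, MU_FLOOR)
  ll <- function(th) sum(weights * stats::dnbinom(y, size = th, mu = mu, log = TRUE))
  th <- min(max(theta, theta_min), theta_max)
  cur <- ll(th)
  for (it in seq_len(maxit)) {
    s <- sum(weights * (digamma(y + th) - digamma(th) + log(th) + 1 -
                          log(th + mu) - (y + th) / (th + mu)))
    h <- sum(weights * (trigamma(y + th) - trigamma(th) + 1 / th -
                          2 / (th + mu) + (y + th) / (th + mu)^2))
    ## Newton on u = log(theta)
    du <- th * s
    d2u <- th^2 * h + th * s
    step <- if (is.finite(d2u) && d2u < 0) -du / d2u else sign(du)
    if (!is.finite(step)) break
    step <- max(min(step, 2), -2)
    new_th <- exp(log(th) + step)
    new_th <- min(max(new_th, theta_min), theta_max)
    new_ll <- ll(new_th)
    k <- 0
    while (new_ll < cur && k < 10) {   # backtrack to keep likelihood ascending
      step <- step / 2
      new_th <- min(max(exp(log(th) + step), theta_min), theta_max)
      new_ll <- ll(new_th)
      k <- k + 1
    }
    if (new_ll < cur) break
    moved <- abs(log(new_th) - log(th))
    th <- new_th
    cur <- new_ll
    if (moved < 1e-8) break
  }
  th
}

#' Control parameters for the penalized negative binomial fitter
#'
#' @param tol relative tolerance on the penalized objective for outer-loop
#'   convergence.
#' @param maxit maximum number of outer iterations.
#' @param theta_min,theta_max clamp interval for the dispersion estimate.
#' @param zero_tol coefficients with absolute value below this count as
#'   numerically zero when computing degrees of freedom.
#' @return A list of control parameters.
#' @export
nb_control <- function(tol = 1e-6, maxit = 200, theta_min = 1e-3,
                       theta_max = 1e5, zero_tol = 1e-8) {
  list(tol = tol, maxit = maxit, theta_min = theta_min,
       theta_max = theta_max, zero_tol = zero_tol)
}

#' Ridge-penalized negative binomial regression
#'
#' Fits a log-link negative binomial GLM maximizing
#' `loglik(beta, theta) - (lambda/2) * sum(beta_j^2)` over the non-intercept
#' coefficients, alternating a ridge IRLS update for `beta` (with step
#' halving, so the penalized objective never decreases) with a Newton
#' maximum-likelihood update for the dispersion `theta`
#' (variance = mu + mu^2/theta). `lambda = 0` gives the unpenalized
#' maximum-likelihood fit.
#'
#' @param x design matrix (samples x coefficients), e.g. from
#'   [build_design()]. A column named `"(Intercept)"` (or a constant first
#'   column) is left unpenalized.
#' @param y vector of non-negative integer counts, one per row of `x`.
#' @param lambda ridge penalty, `>= 0`.
#' @param weights optional non-negative prior weights.
#' @param beta_init,theta_init optional starting values (used for warm
#'   starts along a penalty path).
#' @param control list from [nb_control()].
#' @return An object of class `nbridge`: a list with elements `beta`,
#'   `theta`, `lambda`, `converged`, `n_iter`, `loglik` (penalized
#'   objective at the optimum), `loglik_unpen`, `fitted`, `df`, plus the
#'   data for downstream methods. If the objective becomes non-finite the
#'   fit is returned with `converged = FALSE` rather than raising.
#' @examples
#' X <- cbind("(Intercept)" = 1, z = rep(c(0, 1), each = 4))
#' y <- c(3, 5, 7, 9, 10, 14, 8, 12)
#' fit <- nbridge(X, y, lambda = 1)
#' coef(fit)
#' @export
nbridge <- function(x, y, lambda = 0, weights = NULL,
                    beta_init = NULL, theta_init = NULL,
                    control = nb_control()) {
  X <- design_matrix(x)
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop_validation("length(y) must equal nrow(x)")
  if (any(y < 0) || any(y != round(y)))
    stop_validation("y must contain non-negative integer counts")
  if (all(y == 0))
    stop("all counts are zero: the gene is an essential/conditionally-essential ",
         "candidate; use the mean-count classifier, not the regression model")
  if (lambda < 0) stop_validation("lambda must be >= 0")
  if (is.null(weights)) weights <- rep.int(1, n)
  penalized <- rep(TRUE, p)
  ic <- which(colnames(X) == "(Intercept)")
  if (!length(ic) && p >= 1 && all(X[, 1] == 1)) ic <- 1L
  if (length(ic)) penalized[ic[1]] <- FALSE
  D <- diag(as.numeric(penalized), p)

  wm <- stats::weighted.mean(y, weights)
  beta <- if (!is.null(beta_init)) as.numeric(beta_init) else {
    b <- numeric(p)
    if (length(ic)) b[ic[1]] <- log(max(wm, 0.01))
    b
  }
  theta <- if (!is.null(theta_init)) theta_init else {
    v <- stats::weighted.mean((y - wm)^2, weights)
    th <- if (v > wm) wm^2 / (v - wm) else 1e4
    min(max(th, control$theta_min), control$theta_max)
  }

  pen <- function(b) (lambda / 2) * sum(b[penalized]^2)
  objective <- function(b, th) {
    eta <- drop(X %*% b)
    nb_loglik(y, exp(eta), th, weights) - pen(b)
  }

  Q <- objective(beta, theta)
  if (!is.finite(Q)) {  # pathological start; retreat to flat fit
    beta <- numeric(p)
    if (length(ic)) beta[ic[1]] <- log(max(wm, 0.01))
    Q <- objective(beta, theta)
  }
  converged <- FALSE
  it <- 0L
  monotone <- TRUE
  while (it < control$maxit) {
    it <- it + 1L
    Q_prev <- Q
    ## --- beta step: ridge-penalized weighted least squares + step halving
    eta <- drop(X %*% beta)
    mu <- pmax(exp(eta), MU_FLOOR)
    w <- weights * mu * theta / (theta + mu)
    z <- eta + (y - mu) / mu
    A <- crossprod(X, X * w) + lambda * D
    b <- crossprod(X, w * z)
    prop <- tryCatch(drop(solve(A, b)), error = function(e) NULL)
    if (is.null(prop))
      prop <- tryCatch(drop(solve(A + diag(1e-8, p), b)), error = function(e) NULL)
    if (!is.null(prop) && all(is.finite(prop))) {
      step <- prop - beta
      t_ <- 1
      repeat {
        cand <- beta + t_ * step
        Qc <- objective(cand, theta)
        if (is.finite(Qc) && Qc >= Q - 1e-10) { beta <- cand; Q <- Qc; break }
        t_ <- t_ / 2
        if (t_ < 1e-4) break  # no admissible step; keep current beta
      }
    }
    ## --- theta step: ML update at current means
    mu <- pmax(exp(drop(X %*% beta)), MU_FLOOR)
    theta <- theta_ml_update(y, mu, theta, weights,
                             control$theta_min, control$theta_max)
    Q <- objective(beta, theta)
    if (!is.finite(Q)) {
      converged <- FALSE
      monotone <- FALSE
      break
    }
    if (Q < Q_prev - 1e-8) monotone <- FALSE
    if (abs(Q - Q_prev) < control$tol * (abs(Q_prev) + 0.1)) {
      converged <- TRUE
      break
    }
  }

  fitted <- exp(drop(X %*% beta))
  names(beta) <- colnames(X)
  ## effective degrees of freedom of the ridge smoother,
  ## tr[(X'WX + lambda D)^{-1} X'WX]; equals p at lambda = 0 and tends to 1
  ## (the unpenalized intercept) as lambda grows
  mu_f <- pmax(fitted, MU_FLOOR)
  w_f <- weights * mu_f * theta / (theta + mu_f)
  XtWX <- crossprod(X, X * w_f)
  df <- tryCatch(sum(diag(solve(XtWX + lambda * D, XtWX))),
                 error = function(e) sum(abs(beta[penalized]) > control$zero_tol) + 1)
  out <- list(beta = beta, theta = theta, lambda = lambda,
              converged = converged && is.finite(Q), n_iter = it,
              loglik = Q, loglik_unpen = nb_loglik(y, fitted, theta, weights),
              fitted = fitted, df = df, penalized = penalized,
              monotone = monotone, y = y, x = X, weights = weights,
              control = control)
  class(out) <- "nbridge"
  out
}

#' Fit a penalized negative binomial regression (alias)
#'
#' `fit_penalized_nb(y, X, lambda)` is the operation-style interface to
#' [nbridge()]; `fit_unregularized_nb(y, X)` is exactly
#' `fit_penalized_nb(y, X, lambda = 0)`.
#'
#' @param y count vector, one entry per sample.
#' @param X nested design matrix from [build_design()].
#' @param lambda ridge penalty (`>= 0`).
#' @param ... passed to [nbridge()].
#' @return An `nbridge` fit.
#' @export
fit_penalized_nb <- function(y, X, lambda, ...) nbridge(X, y, lambda = lambda, ...)

#' @rdname fit_penalized_nb
#' @export
fit_unregularized_nb <- function(y, X, ...) nbridge(X, y, lambda = 0, ...)

#' Select the ridge penalty by BIC along a warm-started path
#'
#' Fits [nbridge()] along a decreasing grid of penalties, warm-starting
#' each fit from the previous one, and selects the penalty minimizing
#' `BIC = -2 * loglik_unpen + log(n) * df`, where `df` is the effective
#' degrees of freedom of the ridge smoother,
#' `tr[(X'WX + lambda D)^(-1) X'WX]` (a zero-coefficient count is
#' meaningless for a ridge penalty, which shrinks without ever reaching
#' zero exactly).
#'
#' @param y count vector.
#' @param X design matrix.
#' @param grid strictly positive, decreasing penalty values. Default: 25
#'   log-spaced values from `100 * n` down to `0.001 * n`.
#' @param control list from [nb_control()].
#' @return A list with `lambda` (the selected penalty), `fit` (the selected
#'   `nbridge` fit) and `path` (data frame with one row per grid value:
#'   `lambda`, `loglik`, `df`, `bic`, `converged`).
#' @export
select_lambda <- function(y, X, grid = NULL, control = nb_control()) {
  n <- length(y)
  if (is.null(grid)) grid <- n * 10^seq(2, -3, length.out = 25)
  if (any(grid <= 0)) stop_validation("lambda grid must be strictly positive")
  if (is.unsorted(rev(grid), strictly = FALSE) && length(grid) > 1)
    stop_validation("lambda grid must be decreasing")
  fits <- vector("list", length(grid))
  beta0 <- NULL
  theta0 <- NULL
  for (k in seq_along(grid)) {
    f <- nbridge(X, y, lambda = grid[k], beta_init = beta0,
                 theta_init = theta0, control = control)
    fits[[k]] <- f
    if (f$converged) { beta0 <- f$beta; theta0 <- f$theta }
  }
  path <- data.frame(
    lambda = grid,
    loglik = vapply(fits, function(f) f$loglik_unpen, 0),
    df = vapply(fits, function(f) f$df, 0),
    converged = vapply(fits, function(f) f$converged, TRUE))
  path$bic <- -2 * path$loglik + log(n) * path$df
  ok <- which(path$converged)
  if (!length(ok)) {
    best <- length(grid)   # nothing converged: flag failure on the last fit
    fits[[best]]$converged <- FALSE
    return(list(lambda = grid[best], fit = fits[[best]], path = path))
  }
  best <- ok[which.min(path$bic[ok])]
  list(lambda = grid[best], fit = fits[[best]], path = path)
}

#' Residual variance of a fit
#'
#' Variance (denominator `n`) of the raw response-scale residuals
#' `y - fitted`; with `type = "pearson"` the residuals are standardized by
#' the model's standard deviation `sqrt(mu + mu^2/theta)` first. Raw
#' residuals put all model families on one response-scale axis.
#'
#' @param fit an `nbridge` (or `zinb`) fit.
#' @param y the observed counts (defaults to the counts stored in the fit).
#' @param type `"response"` (raw) or `"pearson"`.
#' @return A non-negative number.
#' @export
residual_variance <- function(fit, y = fit$y, type = c("response", "pearson")) {
  type <- match.arg(type)
  if (inherits(fit, "zinb")) {
    mu <- fit$fitted
    pi_ <- fit$zero_prob
    m <- fit$mean_fitted                       # marginal mean (1 - pi) * mu
    r <- y - m
    if (type == "pearson") {
      v <- (1 - pi_) * (mu + mu^2 / fit$theta) + pi_ * (1 - pi_) * mu^2
      r <- r / sqrt(pmax(v, MU_FLOOR))
    }
  } else {
    r <- y - fit$fitted
    if (type == "pearson")
      r <- r / sqrt(fit$fitted + fit$fitted^2 / fit$theta)
  }
  mean((r - mean(r))^2)
}

## ---- S3 methods -----------------------------------------------------------

#' @export
print.nbridge <- function(x, ...) {
  cat("Ridge-penalized negative binomial fit\n")
  cat("  lambda =", format(x$lambda, digits = 4),
      " theta =", format(x$theta, digits = 4),
      " converged:", x$converged, "(", x$n_iter, "iterations )\n")
  cat("Coefficients (log scale):\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' @export
coef.nbridge <- function(object, ...) object$beta

#' @export
fitted.nbridge <- function(object, ...) object$fitted

#' @export
logLik.nbridge <- function(object, ...) {
  structure(object$loglik_unpen, df = object$df, nobs = length(object$y),
            class = "logLik")
}

#' @export
residuals.nbridge <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted
  if (type == "pearson")
    r <- r / sqrt(object$fitted + object$fitted^2 / object$theta)
  r
}

#' @export
predict.nbridge <- function(object, newx = NULL, type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newx)) object$x else design_matrix(newx)
  eta <- drop(X %*% object$beta)
  if (type == "link") eta else exp(eta)
}

#' @export
simulate.nbridge <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    n <- length(object$fitted)
    out <- matrix(stats::rnbinom(n * nsim, mu = rep(object$fitted, nsim),
                                 size = object$theta), n, nsim)
    colnames(out) <- paste0("sim_", seq_len(nsim))
    as.data.frame(out)
  })
}

#' @export
summary.nbridge <- function(object, ...) {
  out <- list(beta = object$beta, theta = object$theta, lambda = object$lambda,
              converged = object$converged, n_iter = object$n_iter,
              df = object$df, loglik_unpen = object$loglik_unpen,
              resvar = residual_variance(object),
              n = length(object$y))
  class(out) <- "summary.nbridge"
  out
}

#' @export
print.summary.nbridge <- function(x, ...) {
  cat("Ridge-penalized negative binomial fit (n =", x$n, ")\n")
  cat("  lambda:", format(x$lambda, digits = 4),
      " dispersion theta:", format(x$theta, digits = 4), "\n")
  cat("  log-likelihood:", format(x$loglik_unpen, digits = 6),
      " df:", x$df, "\n")
  cat("  residual variance:", format(x$resvar, digits = 6),
      " converged:", x$converged, "\n")
  cat("Coefficients (log scale):\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' @export
plot.nbridge <- function(x, ...) {
  graphics::plot(x$fitted, residuals(x), xlab = "fitted mean",
                 ylab = "raw residual", main = "nbridge fit", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
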