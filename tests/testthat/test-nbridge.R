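test_that("intercept-only fits recover the log sample mean in closed form", {
  f <- fit_penalized_nb(c(3, 5, 7, 9), intercept_X(4), lambda = 0)
  expect_equal(unname(f$beta), log(6), tolerance = 1e-6)
  expect_true(f$converged)

  f2 <- fit_unregularized_nb(c(0, 0, 0, 10), intercept_X(4))
  expect_equal(unname(f2$beta), log(2.5), tolerance = 1e-6)
})

test_that("a dominating penalty drives effects to zero and the intercept to the overall mean", {
  set.seed(2)
  s <- make_samples("wt", c("ctl", "str"), 4)
  X <- build_design(s, c("wt", "ctl"))
  y <- rnbinom(8, mu = rep(c(10, 60), each = 4), size = 5)
  f <- fit_penalized_nb(y, X, lambda = 1e9)
  expect_lt(abs(f$beta[2]), 1e-5)
  expect_equal(unname(f$beta[1]), log(mean(y)), tolerance = 1e-4)
})

test_that("the penalized solution dominates a dense coefficient grid", {
  set.seed(3)
  X <- cbind("(Intercept)" = 1, z = rep(c(0, 1), each = 4))
  y <- rnbinom(8, mu = exp(2 + 0.8 * X[, 2]), size = 3)
  lambda <- 2
  f <- nbridge(X, y, lambda = lambda, control = nb_control(tol = 1e-10))
  grid0 <- seq(f$beta[1] - 0.2, f$beta[1] + 0.2, length.out = 81)
  grid1 <- seq(f$beta[2] - 0.2, f$beta[2] + 0.2, length.out = 81)
  Q <- outer(grid0, grid1, Vectorize(function(b0, b1)
    pen_loglik(c(b0, b1), f$theta, y, X, lambda, c(FALSE, TRUE))))
  Qhat <- pen_loglik(f$beta, f$theta, y, X, lambda, c(FALSE, TRUE))
  expect_gte(Qhat, max(Q) - 1e-9)
  best <- which(Q == max(Q), arr.ind = TRUE)[1, ]
  # the grid argmax sits within one grid step (5e-3) of the solution
  expect_lt(abs(grid0[best[1]] - f$beta[1]), 0.01)
  expect_lt(abs(grid1[best[2]] - f$beta[2]), 0.01)
})

test_that("the penalized objective is monotone over outer iterations", {
  set.seed(14)
  b <- bench_design()
  for (k in 1:10) {
    y <- rnbinom(60, mu = exp(rnorm(1, log(50), 1)), size = runif(1, 0.2, 50))
    if (all(y == 0)) next
    f <- nbridge(b$X, y, lambda = 10^runif(1, -2, 2))
    expect_true(f$monotone)
  }
})

test_that("the penalized coefficient norm shrinks along a warm-started path", {
  set.seed(15)
  b <- bench_design()
  grid <- 60 * 10^seq(2, -3, length.out = 15)
  for (k in 1:10) {
    mu <- exp(2 + as.vector(unclass(b$X)[, -1] %*% rnorm(11, 0, 0.4)))
    y <- rnbinom(60, mu = mu, size = 10)
    beta0 <- NULL; theta0 <- NULL
    norms <- numeric(0)
    for (lam in grid) {
      f <- nbridge(b$X, y, lambda = lam, beta_init = beta0, theta_init = theta0)
      beta0 <- f$beta; theta0 <- f$theta
      norms <- c(norms, sum(f$beta[f$penalized]^2))
    }
    # grid is decreasing, so the norm must be non-decreasing in fit order
    expect_true(all(diff(norms) >= -1e-8))
  }
})

test_that("BIC penalty selection behaves on noise, signal and trivial grids", {
  set.seed(11)
  b <- bench_design()
  picked_high <- replicate(50, {
    y <- rnbinom(60, mu = 40, size = 8)
    sl <- select_lambda(y, b$X)
    sl$lambda >= stats::median(sl$path$lambda)
  })
  expect_gte(mean(picked_high), 0.8)

  # one strong true effect (log 10) survives selection
  set.seed(12)
  eff <- ifelse(colnames(b$X) == "env:e2|g1", log(10), 0)[-1]
  mu <- exp(log(40) + as.vector(unclass(b$X)[, -1] %*% eff))
  y <- rnbinom(60, mu = mu, size = 8)
  sl <- select_lambda(y, b$X)
  expect_gt(abs(sl$fit$beta["env:e2|g1"]), 1)

  y2 <- rnbinom(60, mu = 40, size = 8)
  one <- select_lambda(y2, b$X, grid = 7)
  expect_equal(one$lambda, 7)
})

test_that("the unregularized fit is the lambda = 0 penalized fit and is optimal", {
  set.seed(5)
  b <- bench_design()
  y <- rnbinom(60, mu = 30, size = 5)
  f0 <- fit_unregularized_nb(y, b$X)
  fp <- fit_penalized_nb(y, b$X, lambda = 0)
  expect_identical(f0$beta, fp$beta)
  expect_identical(f0$theta, fp$theta)
  # its unpenalized likelihood dominates the lambda = 1 fit's
  f1 <- fit_penalized_nb(y, b$X, lambda = 1)
  expect_gte(f0$loglik_unpen, f1$loglik_unpen - 1e-8)
})

test_that("all-zero responses are routed to the essentiality classifier", {
  expect_error(nbridge(intercept_X(6), rep(0, 6)), "essential")
})

test_that("residual variance has its closed-form values and nesting property", {
  f <- fit_unregularized_nb(c(3, 5, 7, 9), intercept_X(4))
  expect_equal(residual_variance(f), 5, tolerance = 1e-6)
  # perfect fit
  fperf <- list(fitted = c(3, 5, 7, 9), theta = 10, y = c(3, 5, 7, 9))
  expect_equal(residual_variance(fperf), 0)
  # the saturated fit never has larger raw residual variance than intercept-only
  set.seed(21)
  s <- make_samples(c("a", "b"), c("x", "y"), 5)
  X <- build_design(s, c("a", "x"))
  for (k in 1:5) {
    y <- rnbinom(20, mu = rep(sample(c(5, 20, 60, 100), 4), each = 5), size = 3)
    if (all(y == 0)) next
    fs <- fit_unregularized_nb(y, X)
    fi <- fit_unregularized_nb(y, intercept_X(20))
    expect_lte(residual_variance(fs, y), residual_variance(fi, y) + 1e-8)
  }
})

test_that("nbridge methods are coherent", {
  set.seed(8)
  X <- cbind("(Intercept)" = 1, z = rep(c(0, 1), each = 10))
  y <- rnbinom(20, mu = exp(2 + X[, 2]), size = 4)
  f <- nbridge(X, y, lambda = 0.5)
  expect_equal(fitted(f), predict(f), tolerance = 1e-12)
  expect_equal(predict(f, type = "link"), log(fitted(f)), tolerance = 1e-12)
  expect_equal(residuals(f), y - fitted(f))
  expect_equal(length(coef(f)), 2)
  sim <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(20L, 3L))
  expect_identical(simulate(f, nsim = 3, seed = 1), sim)
  expect_s3_class(summary(f), "summary.nbridge")
  expect_output(print(f), "negative binomial")
  ll <- logLik(f)
  expect_equal(as.numeric(ll), f$loglik_unpen)
})
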