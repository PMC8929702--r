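# shared builders for small designs and counts used across tests

make_samples <- function(backgrounds, environments, replicates) {
  g <- rep(backgrounds, each = length(environments) * replicates)
  e <- rep(rep(environments, each = replicates), length(backgrounds))
  r <- rep(seq_len(replicates), length(backgrounds) * length(environments))
  data.frame(sample_id = paste(g, e, r, sep = "_"),
             background = g, environment = e, replicate = r,
             stringsAsFactors = FALSE)
}

# the benchmark-style design: 3 backgrounds x 4 environments x 5 replicates
bench_design <- function() {
  s <- make_samples(paste0("g", 1:3), paste0("e", 1:4), 5)
  list(samples = s, X = build_design(s, c("g1", "e1")))
}

intercept_X <- function(n) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))

# independent penalized NB objective used by oracle tests (no shared code
# with the fitter beyond dnbinom itself)
pen_loglik <- function(beta, theta, y, X, lambda, penalized) {
  mu <- exp(drop(X %*% beta))
  sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE)) -
    (lambda / 2) * sum(beta[penalized]^2)
}
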