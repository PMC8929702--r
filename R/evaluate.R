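## Evaluation harness: per-gene model comparison on the fit benchmark and
## sensitivity/specificity/accuracy on the power-study sets.

#' Benchmark the regularized fit against the baselines
#'
#' Fits each simulated gene's total counts on the nested design with the
#' requested models: `"nb"` (unregularized negative binomial), `"rnb"`
#' (ridge penalty selected per gene by BIC) and `"zinb"`
#' (zero-inflated baseline), and records the raw residual variance of each
#' fit. The summary fraction is the percentage of genes, among those whose
#' regularized fit converged, where the regularized model attains
#' *strictly* lower residual variance than the unregularized model; ties
#' count as not better, and genes whose regularized fit did not converge
#' are excluded from the denominator.
#'
#' @param data a `sim_dataset` from [simulate_fit_benchmark()].
#' @param models subset of `c("nb", "rnb", "zinb")` (default all three).
#' @param grid optional penalty grid for the BIC path.
#' @param control list from [nb_control()].
#' @param quiet suppress progress messages.
#' @return A list of class `fit_benchmark` with `per_gene` (data frame:
#'   gene, mean count, residual variance per model, convergence flags),
#'   `fraction_rnb_better` (percent), `n_compared`, `n_nonconverged`.
#' @export
evaluate_fit_benchmark <- function(data, models = c("nb", "rnb", "zinb"),
                                   grid = NULL, control = nb_control(),
                                   quiet = TRUE) {
  stopifnot(inherits(data, "sim_dataset"))
  models <- match.arg(models, several.ok = TRUE)
  ctl <- c(data$samples$background[1], data$samples$environment[1])
  X <- build_design(data$samples, control = ctl)
  counts <- data$total
  ng <- nrow(counts)
  per <- data.frame(gene = rownames(counts),
                    mean_count = rowMeans(counts),
                    stringsAsFactors = FALSE)
  Xm <- design_matrix(X)
  rv <- function(fit, y) residual_variance(fit, y)
  res <- list()
  for (m in models) {
    rvv <- rep(NA_real_, ng)
    conv <- rep(FALSE, ng)
    for (i in seq_len(ng)) {
      y <- as.numeric(counts[i, ])
      if (all(y == 0)) next
      fit <- tryCatch(switch(m,
        nb = nbridge(Xm, y, lambda = 0, control = control),
        rnb = select_lambda(y, Xm, grid = grid, control = control)$fit,
        zinb = fit_zinb(y, Xm, control = control)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rvv[i] <- rv(fit, y)
      conv[i] <- isTRUE(fit$converged)
      if (!quiet && i %% 500 == 0) message("  [", m, "] gene ", i, "/", ng)
    }
    res[[m]] <- list(rv = rvv, conv = conv)
    per[[paste0("resvar_", m)]] <- rvv
    per[[paste0("converged_", m)]] <- conv
  }
  frac <- NA_real_
  n_cmp <- NA_integer_
  n_bad <- NA_integer_
  if (all(c("nb", "rnb") %in% models)) {
    usable <- res$rnb$conv & !is.na(res$rnb$rv) & !is.na(res$nb$rv)
    n_cmp <- sum(usable)
    n_bad <- ng - sum(res$rnb$conv)
    frac <- 100 * mean(res$rnb$rv[usable] < res$nb$rv[usable])
  }
  structure(list(per_gene = per, fraction_rnb_better = frac,
                 n_compared = n_cmp, n_nonconverged = n_bad),
            class = "fit_benchmark")
}

#' @export
print.fit_benchmark <- function(x, ...) {
  cat("Fit benchmark over", nrow(x$per_gene), "genes\n")
  if (!is.na(x$fraction_rnb_better))
    cat(sprintf("  regularized better (strictly lower residual variance): %.2f%% of %d genes (%d regularized fits non-converged)\n",
                x$fraction_rnb_better, x$n_compared, x$n_nonconverged))
  invisible(x)
}

## Fit one power-study flavor with one model and return the per-gene
## condition coefficient (NA for genes that were not usable).
power_coef <- function(counts, X, model, ridge_lambda, control) {
  fits <- fit_all_genes(counts, X,
                        lambda = if (model == "rnb") ridge_lambda else 0,
                        model = if (model == "zinb") "zinb" else "nb",
                        control = control)
  lab <- attr(X, "labels")
  col <- which(lab$kind == "nested")[1]
  beta <- fits$beta[, col]
  beta[!fits$converged | !is.na(fits$excluded)] <- NA
  beta
}

#' Sensitivity, specificity and accuracy on power-study sets
#'
#' Runs the full discovery path (per-gene fit, empirical null, local fdr,
#' marginal calls, intersection) on each simulated set and scores the calls
#' against the truth labels: sensitivity = called affected / affected,
#' specificity = uncalled null / null, accuracy = correct / all.
#'
#' @param sets list of `sim_dataset` from [simulate_power_sets()].
#' @param models subset of `c("nb", "rnb", "zinb")`.
#' @param flavors subset of `c("total", "unique", "intersection")`.
#' @param threshold lfdr calling threshold (default 0.2).
#' @param ridge_lambda penalty used for the regularized model (default
#'   0.25, i.e. a N(0, 2^2) prior on natural-log fold changes, wide enough
#'   for the 50-fold-and-beyond effects knockouts produce; coefficients
#'   pooled across genes for the empirical null must be comparably shrunk,
#'   so a single mild penalty is used rather than per-gene selection).
#' @param control list from [nb_control()].
#' @return A data frame with one row per set x model x flavor:
#'   `set`, `condition_mu_total`, `condition_mu_unique`, `model`, `flavor`,
#'   `n_called`, `sensitivity`, `specificity`, `accuracy`.
#' @export
evaluate_power <- function(sets, models = "rnb",
                           flavors = c("total", "unique", "intersection"),
                           threshold = 0.2, ridge_lambda = 0.25,
                           control = nb_control()) {
  models <- match.arg(models, c("nb", "rnb", "zinb"), several.ok = TRUE)
  flavors <- match.arg(flavors, c("total", "unique", "intersection"),
                       several.ok = TRUE)
  out <- list()
  for (k in seq_along(sets)) {
    d <- sets[[k]]
    X <- build_design(d$samples, control = c("wt", "control"))
    truth <- d$truth$affected
    for (m in models) {
      calls <- list()
      for (fl in c("total", "unique")) {
        beta <- power_coef(d[[fl]], X, m, ridge_lambda, control)
        nul <- empirical_null(beta)
        lf <- local_fdr(beta, nul)
        calls[[fl]] <- call_marginal(beta, lf, nul, threshold = threshold)
      }
      calls$intersection <- intersect_calls(calls$total, calls$unique)
      for (fl in flavors) {
        called <- calls[[fl]] != "none"
        sens <- if (any(truth)) sum(called & truth) / sum(truth) else NA_real_
        spec <- sum(!called & !truth) / sum(!truth)
        acc <- (sum(called & truth) + sum(!called & !truth)) / length(truth)
        out[[length(out) + 1]] <- data.frame(
          set = d$truth$set %||% k,
          condition_mu_total = d$truth$total_affected_mu,
          condition_mu_unique = d$truth$unique_affected_mu,
          model = m, flavor = fl, n_called = sum(called),
          sensitivity = sens, specificity = spec, accuracy = acc,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
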