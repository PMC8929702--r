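## Per-gene fitting across a gene x sample count matrix. Genes are fit
## independently; non-convergence and all-zero genes are flagged, never
## raised, so a whole-matrix run always completes.

#' Fit the (penalized) negative binomial model to every gene
#'
#' Fits each row of a gene count matrix against the nested design. All-zero
#' genes are not fit: they are flagged `excluded = "essential-candidate"`
#' (the model is restricted to conditionally nonessential genes; zero-count
#' genes are handled by the mean-count classifier). Genes whose fit does
#' not converge are flagged and should be excluded from downstream
#' coefficient pooling.
#'
#' @param counts a `gene_counts` matrix (genes x samples).
#' @param X nested design matrix from [build_design()]; its rows must match
#'   the count columns.
#' @param lambda penalty policy: `"bic"` (default) selects per gene by
#'   [select_lambda()]; `"bic_global"` selects one shared penalty that
#'   minimizes the BIC summed over a deterministic subsample of genes and
#'   fits every gene at it (use this when coefficients are pooled across
#'   genes downstream -- empirical-null calling needs comparable shrinkage);
#'   a single number fixes the penalty for all genes (0 = unregularized).
#' @param grid optional penalty grid for `lambda = "bic"`.
#' @param model `"nb"` (default) or `"zinb"` for the zero-inflated baseline.
#' @param control list from [nb_control()].
#' @param quiet suppress progress messages.
#' @return An object of class `tn_fits`: list with `beta` (genes x
#'   coefficients), `theta`, `lambda`, `converged`, `excluded` (NA or
#'   reason), `loglik`, `resvar`, `flavor`, `labels` (design column
#'   labels), `zero_prob` (ZINB only).
#' @export
fit_all_genes <- function(counts, X, lambda = "bic", grid = NULL,
                          model = c("nb", "zinb"), control = nb_control(),
                          quiet = TRUE) {
  model <- match.arg(model)
  Xm <- design_matrix(X)
  if (ncol(counts) != nrow(Xm))
    stop_validation("count columns (", ncol(counts),
                    ") do not match design rows (", nrow(Xm), ")")
  ng <- nrow(counts)
  p <- ncol(Xm)
  if (identical(lambda, "bic_global")) {
    lambda <- select_lambda_global(counts, Xm, grid = grid, control = control)
    if (!quiet) message("  shared penalty (global BIC): lambda = ",
                        format(lambda, digits = 4))
  }
  beta <- matrix(NA_real_, ng, p, dimnames = list(rownames(counts), colnames(Xm)))
  theta <- rep(NA_real_, ng)
  lam <- rep(NA_real_, ng)
  conv <- rep(FALSE, ng)
  excl <- rep(NA_character_, ng)
  ll <- rep(NA_real_, ng)
  rv <- rep(NA_real_, ng)
  zp <- if (model == "zinb") rep(NA_real_, ng) else NULL
  for (i in seq_len(ng)) {
    y <- as.numeric(counts[i, ])
    if (all(y == 0)) {
      excl[i] <- "essential-candidate"
      next
    }
    fit <- tryCatch({
      if (model == "zinb") {
        fit_zinb(y, Xm, lambda = if (is.numeric(lambda)) lambda else 0,
                 control = control)
      } else if (identical(lambda, "bic")) {
        select_lambda(y, Xm, grid = grid, control = control)$fit
      } else {
        nbridge(Xm, y, lambda = lambda, control = control)
      }
    }, error = function(e) NULL)
    if (is.null(fit)) {
      excl[i] <- "fit-error"
      next
    }
    beta[i, ] <- fit$beta
    theta[i] <- fit$theta
    lam[i] <- if (!is.null(fit$lambda)) fit$lambda else NA_real_
    conv[i] <- isTRUE(fit$converged)
    ll[i] <- if (!is.null(fit$loglik_unpen)) fit$loglik_unpen else fit$loglik
    rv[i] <- residual_variance(fit, y)
    if (model == "zinb") zp[i] <- fit$zero_prob
    if (!quiet && i %% 500 == 0)
      message("  fitted ", i, "/", ng, " genes")
  }
  out <- list(beta = beta, theta = theta, lambda = lam, converged = conv,
              excluded = excl, loglik = ll, resvar = rv,
              flavor = attr(counts, "flavor"), model = model,
              labels = attr(X, "labels"), zero_prob = zp,
              genes = rownames(counts))
  class(out) <- "tn_fits"
  out
}

#' Select one shared ridge penalty across genes by summed BIC
#'
#' Runs the BIC path on a deterministic subsample of genes (every k-th
#' gene, at most `n_sub`) and returns the grid value minimizing the sum of
#' the per-gene BICs. A shared penalty keeps shrinkage comparable across
#' genes, which matters when coefficients are pooled for empirical-null
#' estimation.
#'
#' @param counts a `gene_counts` matrix.
#' @param X design matrix.
#' @param grid penalty grid (default as in [select_lambda()]).
#' @param n_sub maximum number of subsampled genes (default 200).
#' @param control list from [nb_control()].
#' @return The selected penalty (a single number).
#' @export
select_lambda_global <- function(counts, X, grid = NULL, n_sub = 200,
                                 control = nb_control()) {
  Xm <- design_matrix(X)
  n <- nrow(Xm)
  if (is.null(grid)) grid <- n * 10^seq(2, -3, length.out = 25)
  ng <- nrow(counts)
  idx <- unique(round(seq(1, ng, length.out = min(n_sub, ng))))
  bic_sum <- rep(0, length(grid))
  bic_n <- 0L
  for (i in idx) {
    y <- as.numeric(counts[i, ])
    if (all(y == 0)) next
    sl <- tryCatch(select_lambda(y, Xm, grid = grid, control = control),
                   error = function(e) NULL)
    if (is.null(sl) || !all(sl$path$converged)) next
    bic_sum <- bic_sum + sl$path$bic
    bic_n <- bic_n + 1L
  }
  if (bic_n == 0L)
    stop("no gene produced a converged penalty path; cannot select a shared penalty")
  grid[which.min(bic_sum)]
}

#' @export
print.tn_fits <- function(x, ...) {
  ng <- length(x$genes)
  cat("Per-gene ", toupper(x$model), " fits (flavor: ",
      x$flavor %||% "?", "): ", ng, " genes\n", sep = "")
  cat("  excluded:", sum(!is.na(x$excluded)),
      " non-converged:", sum(!x$converged & is.na(x$excluded)), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Collect usable coefficients from per-gene fits
#'
#' Returns the coefficient values for one design column across all genes
#' that were fit and converged (the pool used for empirical-null
#' estimation).
#'
#' @param fits a `tn_fits` object.
#' @param column design column name (see `colnames(fits$beta)`).
#' @return Named numeric vector of coefficients (genes that converged).
#' @export
coef_pool <- function(fits, column) {
  if (!column %in% colnames(fits$beta))
    stop_validation("unknown coefficient column: ", column)
  keep <- fits$converged & is.na(fits$excluded)
  stats::setNames(fits$beta[keep, column], fits$genes[keep])
}

#' Export per-gene fits as a tidy table
#'
#' One row per gene x coefficient with the estimate, dispersion, penalty
#' and convergence flag; the format written by the `fit` stage of the
#' pipeline.
#'
#' @param fits a `tn_fits` object.
#' @return A data frame.
#' @export
fits_table <- function(fits) {
  cols <- colnames(fits$beta)
  ng <- length(fits$genes)
  data.frame(
    gene = rep(fits$genes, each = length(cols)),
    flavor = fits$flavor %||% NA_character_,
    coefficient = rep(cols, ng),
    estimate = as.vector(t(fits$beta)),
    theta = rep(fits$theta, each = length(cols)),
    lambda = rep(fits$lambda, each = length(cols)),
    converged = rep(fits$converged, each = length(cols)),
    excluded = rep(fits$excluded, each = length(cols)),
    stringsAsFactors = FALSE)
}
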