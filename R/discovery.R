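## Empirical-null local false discovery rate calling. The coefficient for a
## given design column, pooled across genes, is modeled as a two-group
## mixture: a central Gaussian (null genes) plus tails (conditionally
## beneficial/detrimental genes). The null is estimated from the center of
## the empirical distribution so that an abundance of true effects in the
## tails does not inflate it.

#' Estimate the empirical null from pooled coefficients
#'
#' Central matching: the null center `delta0` is the median and the spread
#' `sigma0` is the interquartile range divided by `2 * qnorm(0.75)` (the
#' Gaussian IQR), so only the central 50% of the distribution informs the
#' null. The null proportion `pi0` is the ratio of the data mass within
#' `delta0 +/- sigma0` to the mass a Gaussian puts there, truncated at 1.
#' `method = "mle"` instead fits the Gaussian by maximum likelihood on the
#' observations truncated to the central 80% window (a doubly-truncated
#' normal is weakly identified on a narrower window).
#'
#' @param betas numeric vector of one coefficient across genes (at least 50
#'   finite values).
#' @param method `"central"` (default) or `"mle"`.
#' @return An object of class `empirical_null`: list with `delta0`,
#'   `sigma0`, `pi0`, `n`.
#' @export
empirical_null <- function(betas, method = c("central", "mle")) {
  method <- match.arg(method)
  x <- betas[is.finite(betas)]
  if (length(x) < 50)
    stop("too few genes for empirical-null estimation (need >= 50 finite ",
         "coefficients, got ", length(x), ")")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  if (q[3] - q[1] <= 0)
    stop("degenerate coefficient distribution: zero central spread")
  delta0 <- q[2]
  sigma0 <- (q[3] - q[1]) / (2 * stats::qnorm(0.75))
  if (method == "mle") {
    ## ML fit of a Gaussian to the observations inside the central window,
    ## accounting for the truncation
    qq <- stats::quantile(x, c(0.1, 0.9), names = FALSE)
    lo <- qq[1]; hi <- qq[2]
    xc <- x[x >= lo & x <= hi]
    nll <- function(par) {
      m <- par[1]; s <- exp(par[2])
      z <- stats::pnorm(hi, m, s) - stats::pnorm(lo, m, s)
      -sum(stats::dnorm(xc, m, s, log = TRUE)) + length(xc) * log(max(z, 1e-12))
    }
    opt <- stats::optim(c(delta0, log(sigma0)), nll, method = "Nelder-Mead")
    delta0 <- opt$par[1]
    sigma0 <- exp(opt$par[2])
  }
  inwin <- mean(x >= delta0 - sigma0 & x <= delta0 + sigma0)
  pi0 <- min(1, inwin / (2 * stats::pnorm(1) - 1))
  structure(list(delta0 = delta0, sigma0 = sigma0, pi0 = pi0, n = length(x)),
            class = "empirical_null")
}

#' @export
print.empirical_null <- function(x, ...) {
  cat("Empirical null: N(", format(x$delta0, digits = 4), ", ",
      format(x$sigma0, digits = 4), "^2), pi0 = ",
      format(x$pi0, digits = 4), " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Local false discovery rate under the empirical null
#'
#' Two-group mixture: `lfdr(b) = min(1, pi0 * f0(b) / f(b))` where `f0` is
#' the empirical-null Gaussian density and `f` is a smooth estimate of the
#' marginal coefficient density obtained by Poisson regression of binned
#' counts on a natural spline of the bin midpoints (Lindsey's method).
#'
#' @param betas coefficient vector across genes.
#' @param null an `empirical_null` object.
#' @param bins number of histogram bins for the marginal density
#'   (default 120).
#' @param df spline degrees of freedom (default 7).
#' @return Numeric vector of lfdr values in `[0, 1]`, `NA` where `betas`
#'   is not finite.
#' @export
local_fdr <- function(betas, null, bins = 120, df = 7) {
  stopifnot(inherits(null, "empirical_null"))
  ok <- is.finite(betas)
  x <- betas[ok]
  n <- length(x)
  rng <- range(x)
  if (diff(rng) <= 0) stop("degenerate coefficient distribution")
  brk <- seq(rng[1], rng[2], length.out = bins + 1)
  mid <- (brk[-1] + brk[-(bins + 1)]) / 2
  width <- diff(brk)[1]
  cnt <- tabulate(findInterval(x, brk, rightmost.closed = TRUE), nbins = bins)
  basis <- splines::ns(mid, df = df)
  ## empty bins legitimately drive some fitted rates to zero
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, basis), cnt, family = stats::poisson()))
  fhat_bin <- pmax(fit$fitted.values, 1e-10) / (n * width)   # density per bin
  ## evaluate at the observations via their bin
  bin_of <- findInterval(x, brk, rightmost.closed = TRUE)
  bin_of[bin_of < 1] <- 1
  bin_of[bin_of > bins] <- bins
  f <- fhat_bin[bin_of]
  f0 <- stats::dnorm(x, null$delta0, null$sigma0)
  out <- rep(NA_real_, length(betas))
  out[ok] <- pmin(1, null$pi0 * f0 / f)
  out
}

#' Tail-area false discovery rate (reported for reference)
#'
#' `Fdr(b) = min(1, pi0 * P0(|B - delta0| >= |b - delta0|) / Fbar(b))`
#' where `P0` is the two-sided empirical-null tail probability and `Fbar`
#' the empirical two-sided tail fraction. Calling uses [local_fdr()]; this
#' tail-area version is exported for reporting.
#'
#' @inheritParams local_fdr
#' @return Numeric vector of tail-area Fdr values in `[0, 1]`.
#' @export
tail_fdr <- function(betas, null) {
  stopifnot(inherits(null, "empirical_null"))
  ok <- is.finite(betas)
  x <- betas[ok]
  dev <- abs(x - null$delta0)
  p0 <- 2 * stats::pnorm(-dev / null$sigma0)
  ecdf_tail <- vapply(dev, function(d) mean(dev >= d), 0)
  out <- rep(NA_real_, length(betas))
  out[ok] <- pmin(1, null$pi0 * p0 / pmax(ecdf_tail, 1 / length(x)))
  out
}

#' Marginal beneficial/detrimental calls from lfdr values
#'
#' A gene is called in one count flavor when its lfdr is at or below the
#' threshold; the direction comes from the sign of the coefficient
#' relative to the null center: fewer insertions than expected (negative
#' shift) means disruption decreases growth, i.e. the gene is conditionally
#' beneficial; a positive shift means conditionally detrimental.
#'
#' @param betas coefficient vector across genes.
#' @param lfdr matching lfdr vector from [local_fdr()].
#' @param null the `empirical_null` used (supplies the center).
#' @param threshold lfdr calling threshold (default 0.2).
#' @return Character vector in `{"beneficial", "detrimental", "none"}`
#'   (`"none"` for `NA` inputs).
#' @export
call_marginal <- function(betas, lfdr, null, threshold = 0.2) {
  if (length(betas) != length(lfdr))
    stop_validation("betas and lfdr must be aligned")
  out <- rep("none", length(betas))
  sig <- !is.na(lfdr) & lfdr <= threshold & is.finite(betas)
  out[sig & betas < null$delta0] <- "beneficial"
  out[sig & betas > null$delta0] <- "detrimental"
  out
}

#' Intersect marginal calls from the two count flavors
#'
#' The final call is the shared direction when the total-count and
#' unique-count calls agree, and `"none"` otherwise (including direction
#' conflicts). Requiring agreement of both flavors trades false positives
#' for false negatives.
#'
#' @param total_calls,unique_calls character vectors from
#'   [call_marginal()] over the same gene universe.
#' @return Character vector of final directions.
#' @export
intersect_calls <- function(total_calls, unique_calls) {
  if (length(total_calls) != length(unique_calls))
    stop_validation("call vectors must cover the same gene universe")
  ifelse(total_calls == unique_calls, total_calls, "none")
}

#' Categorize genes for one condition by the hierarchical decision rule
#'
#' Per gene: `essential` when the mean control total count is below 1;
#' otherwise `conditionally_essential` when the mean total count in the
#' target condition is below 1; otherwise the final intersected direction
#' (`beneficial`/`detrimental`) when present, else `neutral`. Per-flavor
#' conditional-essentiality indicators (total, unique, overlap) are
#' returned alongside so tallies can be reported per flavor, but the
#' category itself uses total counts.
#'
#' @param counts_total,counts_unique `gene_counts` matrices over the same
#'   genes and samples.
#' @param samples sample metadata.
#' @param condition length-2 `c(background, environment)` target condition.
#' @param control length-2 control pair.
#' @param final_direction character vector from [intersect_calls()] aligned
#'   to the rows of `counts_total` (use `"none"` for genes without a model
#'   call).
#' @return A data frame with `gene`, `category` (one of `essential`,
#'   `conditionally_essential`, `beneficial`, `detrimental`, `neutral`),
#'   the replicate-mean counts, and logical columns `cond_ess_total`,
#'   `cond_ess_unique`, `cond_ess_overlap`.
#' @export
classify_genes <- function(counts_total, counts_unique, samples, condition,
                           control, final_direction) {
  samples <- validate_sample_meta(samples, control = control)
  if (!identical(rownames(counts_total), rownames(counts_unique)))
    stop_validation("total and unique matrices must share the same genes")
  sel_ctl <- samples$background == control[[1]] &
    samples$environment == control[[2]]
  sel_cnd <- samples$background == condition[[1]] &
    samples$environment == condition[[2]]
  if (!any(sel_cnd))
    stop_validation("condition (", condition[[1]], ", ", condition[[2]],
                    ") has no samples in the design")
  idx <- match(samples$sample_id, colnames(counts_total))
  if (anyNA(idx)) stop_validation("sample metadata does not match count columns")
  m_ctl_tot <- rowMeans(counts_total[, idx[sel_ctl], drop = FALSE])
  m_cnd_tot <- rowMeans(counts_total[, idx[sel_cnd], drop = FALSE])
  m_ctl_unq <- rowMeans(counts_unique[, idx[sel_ctl], drop = FALSE])
  m_cnd_unq <- rowMeans(counts_unique[, idx[sel_cnd], drop = FALSE])
  ng <- nrow(counts_total)
  if (length(final_direction) != ng)
    stop_validation("final_direction must align with the gene rows")
  essential <- m_ctl_tot < 1
  ce_total <- !essential & m_cnd_tot < 1
  ce_unique <- (m_ctl_unq >= 1) & (m_cnd_unq < 1)   # unique-flavor variant
  category <- ifelse(essential, "essential",
              ifelse(ce_total, "conditionally_essential",
              ifelse(final_direction == "beneficial", "beneficial",
              ifelse(final_direction == "detrimental", "detrimental",
                     "neutral"))))
  data.frame(gene = rownames(counts_total),
             category = category,
             mean_control_total = m_ctl_tot,
             mean_condition_total = m_cnd_tot,
             mean_control_unique = m_ctl_unq,
             mean_condition_unique = m_cnd_unq,
             cond_ess_total = ce_total,
             cond_ess_unique = ce_unique,
             cond_ess_overlap = ce_total & ce_unique,
             stringsAsFactors = FALSE)
}
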