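test_that("central matching recovers a Gaussian null, robustly to tails", {
  set.seed(1)
  x <- rnorm(4000)
  nul <- empirical_null(x)
  expect_gt(nul$delta0, -0.1); expect_lt(nul$delta0, 0.1)
  expect_gt(nul$sigma0, 0.9); expect_lt(nul$sigma0, 1.1)
  expect_lte(nul$pi0, 1)

  set.seed(1)
  xm <- c(rnorm(3800), rnorm(200, mean = 5))   # 5% shifted component
  nulm <- empirical_null(xm)
  expect_gt(nulm$sigma0, 0.9); expect_lt(nulm$sigma0, 1.2)

  expect_error(empirical_null(rep(1, 100)), "degenerate")
  expect_error(empirical_null(rnorm(20)), "too few")
  # the truncated-ML variant agrees closely on clean Gaussian data
  nul2 <- empirical_null(x, method = "mle")
  expect_lt(abs(nul2$delta0 - nul$delta0), 0.1)
  expect_lt(abs(nul2$sigma0 - nul$sigma0), 0.15)
})

test_that("local fdr is capped at the null mode and vanishes far out", {
  set.seed(1)
  x <- c(rnorm(3800), rnorm(200, mean = 5))
  nul <- empirical_null(x)
  lf <- local_fdr(x, nul)
  expect_true(all(lf >= 0 & lf <= 1))
  # at the null center the two-group numerator dominates
  centre <- which.min(abs(x - nul$delta0))
  expect_gt(lf[centre], 0.9)
  # 10 null SDs out (the shifted component sits near 5 = 10 sigma0) lfdr is tiny
  far <- which(x > 4.5)
  expect_lt(stats::median(lf[far]), 0.01)
})

test_that("pure-null coefficients are almost never called", {
  set.seed(33)
  frac <- replicate(20, {
    x <- rnorm(4000, sd = runif(1, 0.5, 2))
    nul <- empirical_null(x)
    lf <- local_fdr(x, nul)
    mean(lf <= 0.2)
  })
  expect_lte(mean(frac), 0.01)
})

test_that("thresholding is monotone and directions follow the coefficient sign", {
  set.seed(34)
  x <- c(rnorm(500), -3, 3)
  nul <- empirical_null(x)
  lf <- local_fdr(x, nul)
  calls_10 <- call_marginal(x, lf, nul, threshold = 0.1)
  calls_20 <- call_marginal(x, lf, nul, threshold = 0.2)
  expect_lte(sum(calls_10 != "none"), sum(calls_20 != "none"))

  nul0 <- structure(list(delta0 = 0, sigma0 = 1, pi0 = 1, n = 100),
                    class = "empirical_null")
  expect_equal(call_marginal(-3, 0.01, nul0), "beneficial")
  expect_equal(call_marginal(3, 0.01, nul0), "detrimental")
  expect_equal(call_marginal(-3, 0.5, nul0), "none")
})

test_that("tail-area Fdr lies in [0,1] and shrinks in the tails", {
  set.seed(35)
  x <- c(rnorm(500), 6)
  nul <- empirical_null(x)
  fdr <- tail_fdr(x, nul)
  expect_true(all(fdr >= 0 & fdr <= 1))
  expect_lt(fdr[501], 0.05)
})

test_that("flavor intersection keeps only agreeing directions", {
  tot <- c("beneficial", "beneficial", "beneficial", "detrimental", "none")
  unq <- c("beneficial", "none", "detrimental", "detrimental", "none")
  expect_equal(intersect_calls(tot, unq),
               c("beneficial", "none", "none", "detrimental", "none"))
  # the intersected call set is contained in both marginal call sets
  fin <- intersect_calls(tot, unq)
  expect_true(all(fin == "none" | fin == tot))
  expect_true(all(fin == "none" | fin == unq))
})

test_that("the hierarchical categories partition the gene set", {
  samples <- make_samples("wt", c("control", "stress"), 2)
  genes <- c("ess", "condess", "ben", "det", "neu")
  # columns in samples order: control_1, control_2, stress_1, stress_2
  tot <- rbind(
    ess     = c(0L, 1L, 5L, 5L),      # control mean 0.5 < 1
    condess = c(4L, 4L, 0L, 1L),      # condition mean 0.5 < 1
    ben     = c(9L, 11L, 2L, 4L),
    det     = c(9L, 11L, 30L, 28L),
    neu     = c(9L, 11L, 10L, 10L))
  colnames(tot) <- samples$sample_id
  tot <- as_gene_counts(tot, "total")
  unq <- as_gene_counts(pmin(unclass(tot), 3L), "unique")
  dimnames(unq) <- dimnames(tot)
  cls <- classify_genes(tot, unq, samples,
                        condition = c("wt", "stress"), control = c("wt", "control"),
                        final_direction = c("none", "none", "beneficial",
                                            "detrimental", "none"))
  expect_equal(cls$category,
               c("essential", "conditionally_essential", "beneficial",
                 "detrimental", "neutral"))
  expect_true(all(table(cls$gene) == 1))
  expect_error(
    classify_genes(tot, unq, samples, condition = c("wt", "missing"),
                   control = c("wt", "control"),
                   final_direction = rep("none", 5)),
    "no samples")
})
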