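test_that("the fit benchmark has the study dimensions and total/unique link", {
  sim <- simulate_fit_benchmark(fit_sim_params(seed = 42))
  expect_equal(dim(sim$total), c(4000L, 60L))
  expect_equal(dim(sim$unique), c(4000L, 60L))
  expect_equal(length(unique(sim$samples$background)), 3)
  expect_equal(length(unique(sim$samples$environment)), 4)
  # a sample with zero unique insertions has a zero total (empty sum)
  expect_true(all(sim$total[sim$unique == 0L] == 0L))
  # per-site reads are NB(100, 1), so ~1% of sites draw zero reads and a
  # total can occasionally undershoot the unique count; it must be rare
  expect_lt(mean(sim$total < sim$unique), 0.02)
  # truth bookkeeping: 8 blocks of 500 genes
  expect_equal(as.integer(table(sim$truth$block)), rep(500L, 8))
  # reproducible from the seed
  sim2 <- simulate_fit_benchmark(fit_sim_params(seed = 42))
  expect_identical(unclass(sim$total), unclass(sim2$total))
})

test_that("closed-form total-count draws match explicit per-site sums", {
  # total | u unique insertions is a sum of u iid per-site NB(100, 1) reads;
  # the generator draws it in one shot via NB additivity. Compare both
  # routes at u = 4 by Monte Carlo.
  set.seed(77)
  n <- 1e5
  direct <- rnbinom(n, mu = 400, size = 4)
  bysite <- rowSums(matrix(rnbinom(4 * n, mu = 100, size = 1), n, 4))
  expect_lt(abs(mean(direct) - 400) / 400, 0.01)
  expect_lt(abs(mean(bysite) - 400) / 400, 0.01)
  expect_lt(abs(mean(direct) - mean(bysite)) / 400, 0.015)
  expect_lt(abs(var(direct) - var(bysite)) / var(bysite), 0.05)
})

test_that("power sets have the stated composition and laws", {
  p <- power_sim_params(seed = 5, n_replicates = 5)
  sets <- simulate_power_sets(p)
  expect_length(sets, 20)
  expect_equal(sets[[1]]$truth$total_affected_mu, 1)
  expect_equal(sets[[20]]$truth$total_affected_mu, 950)
  expect_equal(sets[[1]]$truth$unique_affected_mu, 1)
  expect_equal(sets[[20]]$truth$unique_affected_mu, 20)
  for (d in sets[c(1, 10, 20)]) {
    expect_equal(dim(d$total), c(4000L, 10L))
    expect_equal(sum(d$truth$affected), 100)
  }
  # null genes: pooled control-arm mean within 1% of 1000
  d <- sets[[3]]
  ctl <- d$total[!d$truth$affected, d$samples$environment == "control"]
  expect_lt(abs(mean(ctl) - 1000) / 1000, 0.01)
  # sub-seeded sets are reproducible independently of order
  again <- simulate_power_sets(p)[[3]]
  expect_identical(unclass(d$total), unclass(again$total))
})

test_that("the poolcount fixture is deterministic and exercises edge cases", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- make_fixture_poolcount(seed = 7, dir = d1)
  f2 <- make_fixture_poolcount(seed = 7, dir = d2)
  for (k in names(f1))
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]))

  samples <- read_sample_meta(f1$samples)
  sc <- read_poolcount(f1$poolcount, samples)
  genes <- read_gene_table(f1$genes, "tsv")
  agg <- aggregate_counts(sc, genes)
  # at least one gene with zero counts everywhere
  expect_gte(sum(rowSums(agg$total) == 0), 1)
  # the overlapping gene pair shares at least one site
  g19 <- genes[genes$locus == "gene19", ]
  g20 <- genes[genes$locus == "gene20", ]
  shared <- sc$sites$scaffold == g19$scaffold &
    sc$sites$position >= max(g19$start, g20$start) &
    sc$sites$position <= min(g19$end, g20$end)
  expect_gte(sum(shared), 1)
})

test_that("fixture aggregation matches the frozen golden table", {
  fx <- make_fixture_poolcount(seed = 7, dir = withr::local_tempdir())
  samples <- read_sample_meta(fx$samples)
  agg <- aggregate_counts(read_poolcount(fx$poolcount, samples),
                          read_gene_table(fx$genes, "tsv"))
  golden <- utils::read.delim(
    system.file("extdata", "fixture_seed7_golden.tsv", package = "contness"),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(golden))) {
    expect_equal(unname(agg[[golden$flavor[i]]][golden$gene[i],
                                                golden$sample[i]]),
                 golden$count[i])
  }
})

test_that("simulated negative binomial laws have the nominal moments", {
  # the three (mu, theta) pairs used across the simulations, drawn through
  # the power-set generator at n = 1e5
  check <- function(mu, theta, draws) {
    expect_lt(abs(mean(draws) - mu) / mu, 0.02)
    v <- mu + mu^2 / theta
    expect_lt(abs(var(draws) - v) / v, 0.05)
  }
  p <- power_sim_params(n_sets = 1, genes_per_set = 10000, n_affected = 0,
                        total_affected_mu = 0, unique_affected_mu = 0,
                        total_mu = 1000, total_theta = 100,
                        unique_mu = 20, unique_theta = 100,
                        n_replicates = 5, seed = 101)
  d <- simulate_power_sets(p)[[1]]
  check(1000, 100, as.vector(unclass(d$total)))
  check(20, 100, as.vector(unclass(d$unique)))
  p2 <- power_sim_params(n_sets = 1, genes_per_set = 10000, n_affected = 0,
                         total_affected_mu = 0, unique_affected_mu = 0,
                         total_mu = 16, total_theta = 1,
                         n_replicates = 5, seed = 102)
  d2 <- simulate_power_sets(p2)[[1]]
  check(16, 1, as.vector(unclass(d2$total)))
})
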