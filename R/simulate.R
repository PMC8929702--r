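## Two simulation frameworks.
##
## (1) Model-fit benchmark: 3 backgrounds x 4 environments x 5 replicates,
##     8 blocks of 500 genes. Per background, Gamma hyper-parameters
##     a_g, b_g ~ U(0, 5); per (background, environment, block) a dispersion
##     theta_gel ~ Gamma(shape = a_g, rate = b_g). Unique counts are
##     NB(mu_l, theta_gel) with block means mu = (0.5, 1, 2, 4, 8, 16, 32, 64)
##     shared by all cells (no true effects). The total count given u unique
##     insertions is the sum of u iid NB(mu = 100, theta = 1) per-site read
##     counts, drawn in closed form as NB(mu = 100 u, theta = u) by negative
##     binomial additivity; u = 0 gives a zero total.
##
## (2) Power study: 20 sets of 4000 genes, control vs condition arms.
##     Totals: null NB(1000, 100); the 100 affected genes use the set's
##     condition mean from (1, 50, 100, ..., 950). Uniques: null NB(20, 100);
##     affected condition means 1..20. Arms are independent; truth labels
##     accompany each set.

#' Parameters of the model-fit benchmark simulation
#'
#' @param n_backgrounds,n_conditions,n_replicates design dimensions
#'   (defaults 3, 4, 5).
#' @param genes_per_block genes per dispersion block (default 500).
#' @param mu_levels block means for unique counts (length gives the number
#'   of blocks).
#' @param hyper_range range of the uniform hyper-prior on the Gamma shape
#'   and rate (default `c(0, 5)`).
#' @param site_read_mu,site_read_theta per-site read-count law for totals
#'   (defaults 100 and 1).
#' @param seed integer seed.
#' @return A list of class `fit_sim_params`.
#' @export
fit_sim_params <- function(n_backgrounds = 3, n_conditions = 4,
                           n_replicates = 5, genes_per_block = 500,
                           mu_levels = c(0.5, 1, 2, 4, 8, 16, 32, 64),
                           hyper_range = c(0, 5),
                           site_read_mu = 100, site_read_theta = 1,
                           seed = 1) {
  structure(list(n_backgrounds = n_backgrounds, n_conditions = n_conditions,
                 n_replicates = n_replicates, genes_per_block = genes_per_block,
                 mu_levels = mu_levels, hyper_range = hyper_range,
                 site_read_mu = site_read_mu, site_read_theta = site_read_theta,
                 seed = seed),
            class = "fit_sim_params")
}

#' Simulate the model-fit benchmark dataset
#'
#' @param params a [fit_sim_params()] list.
#' @return A list of class `sim_dataset` with `unique` and `total`
#'   `gene_counts` matrices, `samples` metadata, and `truth` (per-gene
#'   block, mean, and per-cell dispersions).
#' @export
simulate_fit_benchmark <- function(params = fit_sim_params()) {
  stopifnot(inherits(params, "fit_sim_params"))
  G <- params$n_backgrounds
  E <- params$n_conditions
  R <- params$n_replicates
  nb <- length(params$mu_levels)
  gpb <- params$genes_per_block
  ng <- nb * gpb
  n <- G * E * R
  samples <- data.frame(
    sample_id = sprintf("g%d_e%d_r%d", rep(seq_len(G), each = E * R),
                        rep(rep(seq_len(E), each = R), G),
                        rep(seq_len(R), G * E)),
    background = paste0("g", rep(seq_len(G), each = E * R)),
    environment = paste0("e", rep(rep(seq_len(E), each = R), G)),
    replicate = rep(seq_len(R), G * E),
    stringsAsFactors = FALSE)
  bg_i <- rep(seq_len(G), each = E * R)
  env_i <- rep(rep(seq_len(E), each = R), G)

  with_seed(params$seed, {
    a_g <- stats::runif(G, params$hyper_range[1], params$hyper_range[2])
    b_g <- stats::runif(G, params$hyper_range[1], params$hyper_range[2])
    ## dispersion per (background, environment, block), clamped away from 0
    theta_gel <- array(pmax(stats::rgamma(G * E * nb,
                                          shape = rep(a_g, times = E * nb),
                                          rate = rep(b_g, times = E * nb)),
                            1e-6),
                       dim = c(G, E, nb))
    genes <- sprintf("gene_%04d", seq_len(ng))
    block <- rep(seq_len(nb), each = gpb)
    uniq <- matrix(0L, ng, n, dimnames = list(genes, samples$sample_id))
    tot <- uniq
    for (l in seq_len(nb)) {
      rows <- which(block == l)
      th_sample <- theta_gel[cbind(bg_i, env_i, l)]      # length n
      u <- stats::rnbinom(length(rows) * n, mu = params$mu_levels[l],
                          size = rep(th_sample, each = length(rows)))
      u <- matrix(u, length(rows), n)
      t_ <- u
      nz <- which(u > 0)
      t_[nz] <- stats::rnbinom(length(nz),
                               mu = params$site_read_mu * u[nz],
                               size = params$site_read_theta * u[nz])
      uniq[rows, ] <- u
      tot[rows, ] <- t_
    }
    truth <- list(block = stats::setNames(block, genes),
                  mu = stats::setNames(params$mu_levels[block], genes),
                  a_g = a_g, b_g = b_g, theta_gel = theta_gel)
    structure(list(unique = as_gene_counts(uniq, "unique"),
                   total = as_gene_counts(tot, "total"),
                   samples = samples, truth = truth, params = params),
              class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated Tn-seq dataset:", nrow(x$total), "genes x",
      ncol(x$total), "samples\n")
  invisible(x)
}

#' Parameters of the power-study simulation
#'
#' @param n_sets number of simulated sets (default 20).
#' @param genes_per_set genes per set (default 4000).
#' @param n_affected truly affected genes per set (default 100; 0 gives a
#'   pure-null set).
#' @param total_mu,total_theta null/control law for total counts
#'   (defaults 1000 and 100).
#' @param total_affected_mu condition means of affected genes for totals,
#'   one per set (default `c(1, seq(50, 950, by = 50))`).
#' @param unique_mu,unique_theta null/control law for unique counts
#'   (defaults 20 and 100).
#' @param unique_affected_mu condition means of affected genes for uniques
#'   (default `1:20`).
#' @param n_replicates replicates per arm (default 5).
#' @param seed integer master seed; each set uses a derived sub-seed.
#' @return A list of class `power_sim_params`.
#' @export
power_sim_params <- function(n_sets = 20, genes_per_set = 4000,
                             n_affected = 100,
                             total_mu = 1000, total_theta = 100,
                             total_affected_mu = c(1, seq(50, 950, by = 50)),
                             unique_mu = 20, unique_theta = 100,
                             unique_affected_mu = seq_len(20),
                             n_replicates = 5, seed = 1) {
  if (length(total_affected_mu) != n_sets || length(unique_affected_mu) != n_sets)
    stop_validation("affected-mean grids must have one value per set")
  if (n_affected > genes_per_set)
    stop_validation("n_affected cannot exceed genes_per_set")
  structure(list(n_sets = n_sets, genes_per_set = genes_per_set,
                 n_affected = n_affected, total_mu = total_mu,
                 total_theta = total_theta,
                 total_affected_mu = total_affected_mu,
                 unique_mu = unique_mu, unique_theta = unique_theta,
                 unique_affected_mu = unique_affected_mu,
                 n_replicates = n_replicates, seed = seed),
            class = "power_sim_params")
}

#' Simulate the control-vs-condition power-study sets
#'
#' @param params a [power_sim_params()] list.
#' @return A list of `n_sets` elements, each a `sim_dataset` with `total`
#'   and `unique` matrices over `2 * n_replicates` samples (control and
#'   condition arms), sample metadata, and `truth` (logical `affected`
#'   vector plus the set's affected means).
#' @export
simulate_power_sets <- function(params = power_sim_params()) {
  stopifnot(inherits(params, "power_sim_params"))
  ng <- params$genes_per_set
  R <- params$n_replicates
  n <- 2L * R
  samples <- data.frame(
    sample_id = c(sprintf("control_r%d", seq_len(R)),
                  sprintf("condition_r%d", seq_len(R))),
    background = "wt",
    environment = rep(c("control", "condition"), each = R),
    replicate = rep(seq_len(R), 2),
    stringsAsFactors = FALSE)
  genes <- sprintf("gene_%04d", seq_len(ng))
  lapply(seq_len(params$n_sets), function(k) {
    with_seed(derive_seed(params$seed, k), {
      affected <- c(rep(TRUE, params$n_affected),
                    rep(FALSE, ng - params$n_affected))
      draw <- function(mu_null, theta, mu_aff) {
        ctl <- matrix(stats::rnbinom(ng * R, mu = mu_null, size = theta), ng, R)
        cnd <- matrix(stats::rnbinom(ng * R, mu = mu_null, size = theta), ng, R)
        if (any(affected))
          cnd[affected, ] <- stats::rnbinom(sum(affected) * R, mu = mu_aff,
                                            size = theta)
        cbind(ctl, cnd)
      }
      tot <- draw(params$total_mu, params$total_theta,
                  params$total_affected_mu[k])
      unq <- draw(params$unique_mu, params$unique_theta,
                  params$unique_affected_mu[k])
      dimnames(tot) <- dimnames(unq) <- list(genes, samples$sample_id)
      structure(list(total = as_gene_counts(tot, "total"),
                     unique = as_gene_counts(unq, "unique"),
                     samples = samples,
                     truth = list(affected = stats::setNames(affected, genes),
                                  total_affected_mu = params$total_affected_mu[k],
                                  unique_affected_mu = params$unique_affected_mu[k],
                                  set = k),
                     params = params),
                class = "sim_dataset")
    })
  })
}

#' Write a small deterministic poolcount fixture
#'
#' Generates a complete miniature study on disk: a poolcount TSV (~200
#' sites, ~20 genes), a 5-column gene TSV, and a sample-metadata TSV for a
#' 2 background x 2 environment x 2 replicate design. The gene set includes
#' one gene with zero counts in every sample and one overlapping gene pair.
#' Identical seeds produce byte-identical files.
#'
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return Named list of file paths (`poolcount`, `genes`, `samples`).
#' @export
make_fixture_poolcount <- function(seed = 7, dir = tempfile("fixture")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    ng <- 20
    genes <- data.frame(
      locus = sprintf("gene%02d", seq_len(ng)),
      scaffold = rep(c("chr1", "chr2"), each = ng / 2),
      start = rep(seq(101, by = 500, length.out = ng / 2), 2),
      stringsAsFactors = FALSE)
    genes$end <- genes$start + 399L
    genes$strand <- rep(c("+", "-"), length.out = ng)
    ## gene19 overlaps gene20 (same scaffold); shift gene20 into gene19's span
    genes$start[ng] <- genes$start[ng - 1] + 200L
    genes$end[ng] <- genes$start[ng] + 399L
    samples <- data.frame(
      sample_id = c("wt_ctl_1", "wt_ctl_2", "wt_str_1", "wt_str_2",
                    "mut_ctl_1", "mut_ctl_2", "mut_str_1", "mut_str_2"),
      background = rep(c("wt", "mut"), each = 4),
      environment = rep(rep(c("control", "stress"), each = 2), 2),
      replicate = rep(1:2, 4),
      stringsAsFactors = FALSE)
    ## ~10 candidate sites per gene plus intergenic sites; gene05 gets none
    ## with nonzero counts (all-zero gene)
    site_rows <- list()
    sid <- 0
    for (i in seq_len(ng)) {
      npos <- 8
      pos <- sort(sample(genes$start[i]:genes$end[i], npos))
      for (p in pos) {
        sid <- sid + 1
        site_rows[[sid]] <- data.frame(
          barcode = sprintf("BC%04d", sid), scaffold = genes$scaffold[i],
          strand = sample(c("+", "-"), 1), pos = p, stringsAsFactors = FALSE)
      }
    }
    for (k in 1:40) {   # intergenic sites
      sid <- sid + 1
      site_rows[[sid]] <- data.frame(
        barcode = sprintf("BC%04d", sid),
        scaffold = sample(c("chr1", "chr2"), 1),
        strand = sample(c("+", "-"), 1),
        pos = sample(9000:12000, 1), stringsAsFactors = FALSE)
    }
    sites <- do.call(rbind, site_rows)
    counts <- matrix(stats::rnbinom(nrow(sites) * nrow(samples), mu = 6,
                                    size = 2),
                     nrow(sites), nrow(samples),
                     dimnames = list(NULL, samples$sample_id))
    zero_gene <- genes$locus == "gene05"
    in_zero <- sites$scaffold == genes$scaffold[zero_gene] &
      sites$pos >= genes$start[zero_gene] & sites$pos <= genes$end[zero_gene]
    counts[in_zero, ] <- 0L
    pool <- cbind(sites, as.data.frame(counts, check.names = FALSE))
    paths <- list(poolcount = file.path(dir, "fixture.poolcount.tsv"),
                  genes = file.path(dir, "fixture.genes.tsv"),
                  samples = file.path(dir, "fixture.samples.tsv"))
    utils::write.table(pool, paths$poolcount, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(genes[, c("locus", "scaffold", "start", "end", "strand")],
                       paths$genes, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(samples, paths$samples, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths
  })
}
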