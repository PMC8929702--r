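## End-to-end orchestration: aggregate -> fit (both flavors) -> empirical
## null / lfdr / marginal calls -> intersection -> categories, with a
## machine-readable manifest. Every stage logs and any stage error aborts
## with the stage name.

#' Assemble a run configuration
#'
#' @param poolcount path to the site-level poolcount TSV.
#' @param genes path to the gene annotation (TSV or GFF3).
#' @param samples path to the sample-metadata TSV.
#' @param control length-2 `c(background, environment)` control pair.
#' @param out_dir output directory.
#' @param gene_dialect `"tsv"` or `"gff3"`.
#' @param trim_frac trimmed fraction of the gene body (default 0).
#' @param lambda penalty policy for the per-gene fits. Default 0.25 (a
#'   N(0, 2^2) prior on natural-log fold changes -- wide enough for the
#'   strong effects gene disruption produces): pooled coefficients must be
#'   comparably shrunk for the empirical null, so a single mild penalty is
#'   the default rather than per-gene selection. Also accepted: any fixed
#'   number, `"bic"` (per-gene BIC) or `"bic_global"` (shared penalty by
#'   summed BIC).
#' @param lfdr_threshold calling threshold (default 0.2).
#' @param null_method `"central"` or `"mle"` empirical-null estimation.
#' @param seed integer seed recorded in the manifest and used for any
#'   randomized stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(poolcount, genes, samples, control, out_dir,
                       gene_dialect = c("tsv", "gff3"), trim_frac = 0,
                       lambda = 0.25, lfdr_threshold = 0.2,
                       null_method = "central", seed = 1) {
  cfg <- list(poolcount = poolcount, genes = genes, samples = samples,
              control = control, out_dir = out_dir,
              gene_dialect = match.arg(gene_dialect), trim_frac = trim_frac,
              lambda = lambda, lfdr_threshold = lfdr_threshold,
              null_method = null_method, seed = seed)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a key = value text file
#'
#' Lines of the form `key = value` (comments start with `#`). Keys are the
#' arguments of [run_config()]; `control` is written `background:environment`.
#'
#' @param path path to the config file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop_format("malformed config line: ", lines[bad][1])
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  need <- c("poolcount", "genes", "samples", "control", "out_dir")
  miss <- setdiff(need, names(vals))
  if (length(miss)) stop_format("config missing key(s): ",
                                paste(miss, collapse = ", "))
  ctl <- strsplit(vals[["control"]], ":", fixed = TRUE)[[1]]
  if (length(ctl) != 2) stop_format("control must be 'background:environment'")
  num <- function(k, d) if (k %in% names(vals)) as.numeric(vals[[k]]) else d
  run_config(
    poolcount = vals[["poolcount"]], genes = vals[["genes"]],
    samples = vals[["samples"]], control = ctl, out_dir = vals[["out_dir"]],
    gene_dialect = if ("gene_dialect" %in% names(vals)) vals[["gene_dialect"]] else "tsv",
    trim_frac = num("trim_frac", 0),
    lambda = if (!"lambda" %in% names(vals)) 0.25 else
      if (vals[["lambda"]] %in% c("bic", "bic_global")) vals[["lambda"]] else
        as.numeric(vals[["lambda"]]),
    lfdr_threshold = num("lfdr_threshold", 0.2),
    null_method = if ("null_method" %in% names(vals)) vals[["null_method"]] else "central",
    seed = as.integer(num("seed", 1)))
}

stage <- function(name, quiet, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  if (!quiet)
    message(sprintf("[%s] done in %.2fs", name, proc.time()[["elapsed"]] - t0))
  out
}

#' Run the full pipeline
#'
#' Aggregates site counts to gene totals/uniques, fits the penalized
#' negative binomial per gene for both flavors (excluding essential and
#' conditionally essential genes by the mean-count rule), estimates one
#' empirical null per coefficient and flavor, makes marginal lfdr calls,
#' intersects the flavors, categorizes every gene for every non-control
#' condition, and writes `counts_total.tsv`, `counts_unique.tsv`,
#' `fits.tsv`, `calls.tsv`, `tallies.tsv`, `manifest.tsv` and
#' `manifest.json` into the output directory.
#'
#' @param config a `run_config` list (or path to a config file).
#' @param quiet suppress stage logging.
#' @return Invisibly, a list with the counts, fits, calls data frame,
#'   tallies data frame and manifest.
#' @export
run_end_to_end <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  for (f in c("poolcount", "genes", "samples"))
    if (!file.exists(config[[f]]))
      stop_validation("input file does not exist: ", config[[f]])
  set.seed(config$seed)
  samples <- stage("samples", quiet,
                   read_sample_meta(config$samples, control = config$control))
  sites <- stage("poolcount", quiet, read_poolcount(config$poolcount, samples))
  genes <- stage("genes", quiet,
                 read_gene_table(config$genes, dialect = config$gene_dialect))
  counts <- stage("aggregate", quiet,
                  aggregate_counts(sites, genes, trim_frac = config$trim_frac))
  X <- stage("design", quiet, build_design(samples, control = config$control))
  lab <- attr(X, "labels")
  conditions <- lab[lab$kind != "intercept", , drop = FALSE]
  conditions$environment[is.na(conditions$environment)] <-
    attr(X, "control")[["environment"]]
  colkeys <- colnames(design_matrix(X))[-1]

  ## mean-count exclusion: essential (control) or conditionally essential in
  ## any condition cell -> classified by the decision rule, not the model
  idx <- match(samples$sample_id, colnames(counts$total))
  cellmeans <- function(sel) rowMeans(counts$total[, idx[sel], drop = FALSE])
  ess <- cellmeans(samples$background == config$control[[1]] &
                     samples$environment == config$control[[2]]) < 1
  condess <- rep(FALSE, nrow(counts$total))
  for (i in seq_len(nrow(conditions))) {
    sel <- samples$background == conditions$background[i] &
      samples$environment == conditions$environment[i]
    condess <- condess | (cellmeans(sel) < 1)
  }
  model_genes <- !ess & !condess

  fits <- stage("fit", quiet, {
    lapply(list(total = counts$total, unique = counts$unique), function(cm)
      fit_all_genes(cm[model_genes, , drop = FALSE], X,
                    lambda = config$lambda, quiet = quiet))
  })

  calls <- stage("call", quiet, {
    rows <- list()
    for (i in seq_len(nrow(conditions))) {
      key <- colkeys[i]
      per_flavor <- lapply(fits, function(f) {
        beta <- f$beta[, i + 1]
        beta[!f$converged | !is.na(f$excluded)] <- NA
        if (sum(is.finite(beta)) >= 50) {
          nul <- empirical_null(beta, method = config$null_method)
          lf <- local_fdr(beta, nul)
          list(beta = beta, lfdr = lf,
               call = call_marginal(beta, lf, nul,
                                    threshold = config$lfdr_threshold),
               unresolved = !f$converged & is.na(f$excluded))
        } else {
          list(beta = beta, lfdr = rep(NA_real_, length(beta)),
               call = rep("none", length(beta)),
               unresolved = !f$converged & is.na(f$excluded))
        }
      })
      final <- intersect_calls(per_flavor$total$call, per_flavor$unique$call)
      dir_all <- rep("none", nrow(counts$total))
      names(dir_all) <- rownames(counts$total)
      dir_all[rownames(counts$total)[model_genes]] <- final
      cls <- classify_genes(counts$total, counts$unique, samples,
                            condition = c(conditions$background[i],
                                          conditions$environment[i]),
                            control = config$control,
                            final_direction = dir_all)
      unresolved <- rep(FALSE, nrow(counts$total))
      unresolved[model_genes] <- per_flavor$total$unresolved |
        per_flavor$unique$unresolved
      cls$category[unresolved & !(cls$category %in%
                                    c("essential", "conditionally_essential"))] <-
        "unresolved"
      expand <- function(v) {
        out <- rep(NA_real_, nrow(counts$total))
        out[model_genes] <- v
        out
      }
      expand_chr <- function(v, fill = "none") {
        out <- rep(fill, nrow(counts$total))
        out[model_genes] <- v
        out
      }
      rows[[i]] <- data.frame(
        gene = cls$gene, condition = key,
        background = conditions$background[i],
        environment = conditions$environment[i],
        beta_total = expand(per_flavor$total$beta),
        lfdr_total = expand(per_flavor$total$lfdr),
        beta_unique = expand(per_flavor$unique$beta),
        lfdr_unique = expand(per_flavor$unique$lfdr),
        call_total = expand_chr(per_flavor$total$call),
        call_unique = expand_chr(per_flavor$unique$call),
        direction = unname(dir_all),
        category = cls$category,
        cond_ess_total = cls$cond_ess_total,
        cond_ess_unique = cls$cond_ess_unique,
        cond_ess_overlap = cls$cond_ess_overlap,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })

  tallies <- stage("tally", quiet, {
    agg <- function(cond) {
      d <- calls[calls$condition == cond, ]
      data.frame(
        condition = cond,
        n_essential = sum(d$category == "essential"),
        n_cond_essential_total = sum(d$cond_ess_total),
        n_cond_essential_unique = sum(d$cond_ess_unique),
        n_cond_essential_overlap = sum(d$cond_ess_overlap),
        n_called_total = sum(d$call_total != "none"),
        n_called_unique = sum(d$call_unique != "none"),
        n_called_overlap = sum(d$direction != "none"),
        n_beneficial = sum(d$category == "beneficial"),
        n_detrimental = sum(d$category == "detrimental"),
        n_neutral = sum(d$category == "neutral"),
        n_unresolved = sum(d$category == "unresolved"),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, lapply(unique(calls$condition), agg))
  })

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  write_gene_counts(counts$total, out("counts_total.tsv"))
  write_gene_counts(counts$unique, out("counts_unique.tsv"))
  ft <- rbind(fits_table(fits$total), fits_table(fits$unique))
  utils::write.table(ft, out("fits.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(calls, out("calls.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(tallies, out("tallies.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- data.frame(
    key = c("package_version", "seed", "control", "trim_frac", "lambda",
            "lfdr_threshold", "null_method", "n_genes", "n_samples",
            "n_model_genes"),
    value = c(as.character(utils::packageVersion("contness")),
              config$seed, paste(config$control, collapse = ":"),
              config$trim_frac, as.character(config$lambda),
              config$lfdr_threshold, config$null_method,
              nrow(counts$total), ncol(counts$total), sum(model_genes)),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, out("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(stats::setNames(as.list(manifest$value), manifest$key),
                       out("manifest.json"), auto_unbox = TRUE)
  invisible(list(counts = counts, fits = fits, calls = calls,
                 tallies = tallies, manifest = manifest))
}
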