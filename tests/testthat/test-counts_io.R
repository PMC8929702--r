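test_that("poolcount parsing reads sites and rejects malformed input", {
  dir <- withr::local_tempdir()
  samples <- data.frame(sample_id = c("s1", "s2"), background = "wt",
                        environment = c("control", "stress"), replicate = 1L)
  pc <- file.path(dir, "pc.tsv")
  writeLines(c("barcode\tscaffold\tstrand\tpos\ts1\ts2",
               "AAA\tchr1\t+\t150\t5\t0",
               "AAB\tchr1\t-\t160\t0\t2",
               "AAC\tchr2\t+\t300\t7\t1"), pc)
  sc <- read_poolcount(pc, samples)
  expect_s3_class(sc, "site_counts")
  expect_equal(nrow(sc$sites), 3)
  expect_equal(ncol(sc$counts), 2)
  expect_equal(sc$counts["AAA", "s1"], 5L)

  bad <- file.path(dir, "nopos.tsv")
  writeLines(c("barcode\tscaffold\tstrand\ts1\ts2", "AAA\tchr1\t+\t5\t0"), bad)
  expect_error(read_poolcount(bad, samples), "pos")

  neg <- file.path(dir, "neg.tsv")
  writeLines(c("barcode\tscaffold\tstrand\tpos\ts1\ts2",
               "AAA\tchr1\t+\t150\t-3\t0"), neg)
  expect_error(read_poolcount(neg, samples), "negative count")

  missing_sample <- samples
  missing_sample$sample_id <- c("s1", "s9")
  expect_error(read_poolcount(pc, missing_sample), "s9")
})

test_that("poolcount fixture round-trips through write and read", {
  fx <- make_fixture_poolcount(seed = 7, dir = withr::local_tempdir())
  samples <- read_sample_meta(fx$samples)
  sc <- read_poolcount(fx$poolcount, samples)
  out <- file.path(withr::local_tempdir(), "again.tsv")
  write_poolcount(sc, out)
  sc2 <- read_poolcount(out, samples)
  expect_identical(sc$sites, sc2$sites)
  expect_identical(sc$counts, sc2$counts)
})

test_that("gene tables parse from TSV and GFF3 with validation", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "g.tsv")
  writeLines("geneA\tchr1\t100\t200\t+", tsv)
  gt <- read_gene_table(tsv, "tsv")
  expect_equal(nrow(gt), 1)
  expect_equal(gt$end - gt$start + 1, 101)

  gff <- file.path(dir, "g.gff")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t100\t200\t.\t+\t.\tID=gA;locus_tag=geneA",
               "chr1\tsrc\tCDS\t100\t200\t.\t+\t0\tParent=gA"), gff)
  gg <- read_gene_table(gff, "gff3")
  expect_equal(gg$locus, "geneA")
  expect_equal(gg$start, 100L)
  expect_equal(gg$end, 200L)

  bad <- file.path(dir, "bad.tsv")
  writeLines("geneA\tchr1\t300\t200\t+", bad)
  expect_error(read_gene_table(bad, "tsv"), "start > end")

  dup <- file.path(dir, "dup.tsv")
  writeLines(c("geneA\tchr1\t100\t200\t+", "geneA\tchr1\t300\t400\t+"), dup)
  expect_error(read_gene_table(dup, "tsv"), "duplicate locus")
})

test_that("aggregation follows the windowed total/unique definitions", {
  samples <- data.frame(sample_id = "s1", background = "wt",
                        environment = "control", replicate = 1L)
  dir <- withr::local_tempdir()
  pc <- file.path(dir, "pc.tsv")
  writeLines(c("barcode\tscaffold\tstrand\tpos\ts1",
               "A\tchr1\t+\t150\t5",
               "B\tchr1\t-\t160\t0",
               "C\tchr1\t+\t300\t7",
               "D\tchr1\t+\t110\t9"), pc)
  sc <- read_poolcount(pc, samples)
  genes <- structure(data.frame(locus = "geneA", scaffold = "chr1",
                                start = 100L, end = 200L, strand = "+",
                                stringsAsFactors = FALSE),
                     class = c("gene_table", "data.frame"))
  agg <- aggregate_counts(sc, genes, trim_frac = 0)
  # site at 300 is outside; site at 160 has zero reads
  expect_equal(unname(agg$total["geneA", "s1"]), 5L + 9L)
  expect_equal(unname(agg$unique["geneA", "s1"]), 2L)

  # trim 0.2 of L = 101 -> window [120, 180]: site at 110 now excluded
  agg2 <- aggregate_counts(sc, genes, trim_frac = 0.2)
  expect_equal(unname(agg2$total["geneA", "s1"]), 5L)
  expect_equal(unname(agg2$unique["geneA", "s1"]), 1L)

  expect_error(aggregate_counts(sc, genes, trim_frac = 0.5), "trim_frac")
})

test_that("fixture aggregation matches a brute-force interval scan", {
  fx <- make_fixture_poolcount(seed = 7, dir = withr::local_tempdir())
  samples <- read_sample_meta(fx$samples)
  sc <- read_poolcount(fx$poolcount, samples)
  genes <- read_gene_table(fx$genes, "tsv")
  agg <- aggregate_counts(sc, genes, trim_frac = 0)

  for (i in seq_len(nrow(genes))) {
    inside <- sc$sites$scaffold == genes$scaffold[i] &
      sc$sites$position >= genes$start[i] & sc$sites$position <= genes$end[i]
    for (s in samples$sample_id) {
      expect_equal(unname(agg$total[genes$locus[i], s]),
                   sum(sc$counts[inside, s]))
      expect_equal(unname(agg$unique[genes$locus[i], s]),
                   sum(sc$counts[inside, s] > 0))
    }
  }
  # total >= unique elementwise when derived from the same sites
  expect_true(all(agg$total >= agg$unique))
})

test_that("aggregation is additive over disjoint site splits", {
  fx <- make_fixture_poolcount(seed = 3, dir = withr::local_tempdir())
  samples <- read_sample_meta(fx$samples)
  sc <- read_poolcount(fx$poolcount, samples)
  genes <- read_gene_table(fx$genes, "tsv")
  half <- seq_len(nrow(sc$sites)) %% 2 == 0
  sub <- function(keep) {
    out <- list(sites = sc$sites[keep, , drop = FALSE],
                counts = sc$counts[keep, , drop = FALSE])
    class(out) <- "site_counts"
    out
  }
  whole <- aggregate_counts(sc, genes)
  a <- aggregate_counts(sub(half), genes)
  b <- aggregate_counts(sub(!half), genes)
  expect_equal(unclass(whole$total), unclass(a$total) + unclass(b$total),
               ignore_attr = TRUE)
  # unique counts are additive too because the split shares no sites
  expect_equal(unclass(whole$unique), unclass(a$unique) + unclass(b$unique),
               ignore_attr = TRUE)
})

test_that("gene count matrices round-trip with flavor metadata", {
  m <- as_gene_counts(matrix(c(1L, 2L, 3L, 4L), 2, 2,
                             dimnames = list(c("g1", "g2"), c("s1", "s2"))),
                      "unique")
  p <- file.path(withr::local_tempdir(), "m.tsv")
  write_gene_counts(m, p)
  m2 <- read_gene_counts(p)
  expect_identical(unclass(m2), unclass(m))
  expect_identical(attr(m2, "flavor"), "unique")

  empty <- as_gene_counts(matrix(integer(), 0, 2,
                                 dimnames = list(NULL, c("s1", "s2"))), "total")
  pe <- file.path(withr::local_tempdir(), "empty.tsv")
  write_gene_counts(empty, pe)
  e2 <- read_gene_counts(pe)
  expect_equal(nrow(e2), 0)
  expect_identical(attr(e2, "flavor"), "total")

  dup <- file.path(withr::local_tempdir(), "dup.tsv")
  writeLines(c("#flavor=total", "gene\ts1", "g1\t3", "g1\t4"), dup)
  expect_error(read_gene_counts(dup), "duplicate gene")
})
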