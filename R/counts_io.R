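## Site-level insertion count I/O and aggregation to per-gene total and
## unique count matrices.

#' Read a poolcount-style site count table
#'
#' Reads a tab-separated file with one row per insertion site (barcode).
#' Metadata columns `barcode`, `scaffold`, `strand` and `pos` must precede
#' one count column per sample; extra metadata columns (e.g. `rcbarcode`)
#' are ignored. Every `sample_id` in `samples` must appear as a column.
#'
#' @param path path to the poolcount TSV file.
#' @param samples sample metadata data frame (see [read_sample_meta()]);
#'   its `sample_id` values select and order the count columns.
#' @return An object of class `site_counts`: a list with elements
#'   `sites` (data frame: `site_id`, `scaffold`, `strand`, `position`) and
#'   `counts` (integer matrix, sites x samples).
#' @export
read_poolcount <- function(path, samples) {
  samples <- validate_sample_meta(samples)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("barcode", "scaffold", "strand", "pos")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_format("poolcount file is missing column(s): ", paste(miss, collapse = ", "))
  miss_s <- setdiff(samples$sample_id, names(df))
  if (length(miss_s))
    stop_format("poolcount file is missing sample column(s): ",
                paste(miss_s, collapse = ", "))
  counts <- as.matrix(df[, samples$sample_id, drop = FALSE])
  for (j in seq_len(ncol(counts))) {
    cj <- counts[, j]
    if (!is.numeric(cj) || any(!is.finite(cj)) || any(cj != round(cj)))
      stop_validation("non-numeric count in column '", samples$sample_id[j],
                      "', row ", which(!is.finite(cj) | cj != round(cj))[1])
    if (any(cj < 0))
      stop_validation("negative count in column '", samples$sample_id[j],
                      "', row ", which(cj < 0)[1])
  }
  storage.mode(counts) <- "integer"
  pos <- df$pos
  if (!is_count_vector(pos) || any(pos < 1))
    stop_validation("site positions must be integers >= 1")
  strand <- as.character(df$strand)
  if (!all(strand %in% c("+", "-")))
    stop_validation("strand must be '+' or '-'")
  out <- list(
    sites = data.frame(site_id = as.character(df$barcode),
                       scaffold = as.character(df$scaffold),
                       strand = strand,
                       position = as.integer(pos),
                       stringsAsFactors = FALSE),
    counts = counts)
  dimnames(out$counts) <- list(out$sites$site_id, samples$sample_id)
  class(out) <- "site_counts"
  out
}

#' Write a site count table in poolcount format
#'
#' @param x a `site_counts` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_poolcount <- function(x, path) {
  stopifnot(inherits(x, "site_counts"))
  df <- cbind(data.frame(barcode = x$sites$site_id,
                         scaffold = x$sites$scaffold,
                         strand = x$sites$strand,
                         pos = x$sites$position,
                         stringsAsFactors = FALSE),
              as.data.frame(x$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.site_counts <- function(x, ...) {
  cat("Site count table:", nrow(x$sites), "sites x", ncol(x$counts), "samples\n")
  cat("Scaffolds:", paste(unique(x$sites$scaffold), collapse = ", "), "\n")
  invisible(x)
}

#' Read a gene annotation table
#'
#' Two dialects are supported. `"tsv"`: five columns
#' (locus, scaffold, start, end, strand), header optional. `"gff3"`:
#' standard 9-column GFF3; rows of type `gene` are kept and the locus is
#' taken from the `locus_tag`, `ID` or `Name` attribute (first available).
#' Coordinates are 1-based inclusive in both dialects.
#'
#' @param path path to the annotation file.
#' @param dialect `"tsv"` or `"gff3"`.
#' @return A data frame of class `gene_table` with columns `locus`,
#'   `scaffold`, `start`, `end`, `strand`.
#' @export
read_gene_table <- function(path, dialect = c("tsv", "gff3")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    first <- utils::read.delim(path, header = FALSE, sep = "\t", nrows = 1,
                               stringsAsFactors = FALSE)
    has_header <- ncol(first) >= 4 &&
      (is.na(suppressWarnings(as.numeric(first[[3]]))) ||
       is.na(suppressWarnings(as.numeric(first[[4]]))))
    df <- utils::read.delim(path, header = has_header, sep = "\t",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 5)
      stop_format("gene TSV must have 5 columns (locus, scaffold, start, end, strand)")
    df <- df[, 1:5]
    names(df) <- c("locus", "scaffold", "start", "end", "strand")
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ok <- vapply(fields, length, 1L) == 9L
    if (!any(ok)) stop_format("no 9-column records found in GFF3 file")
    fields <- fields[ok]
    m <- do.call(rbind, fields)
    keep <- m[, 3] == "gene"
    if (!any(keep)) stop_format("no rows of type 'gene' in GFF3 file")
    m <- m[keep, , drop = FALSE]
    locus <- apply(m, 1, function(row) {
      attrs <- strsplit(row[9], ";", fixed = TRUE)[[1]]
      kv <- strsplit(attrs, "=", fixed = TRUE)
      keys <- vapply(kv, `[`, "", 1)
      vals <- vapply(kv, function(x) if (length(x) > 1) x[2] else NA_character_, "")
      for (k in c("locus_tag", "ID", "Name")) {
        hit <- match(k, trimws(keys))
        if (!is.na(hit) && !is.na(vals[hit])) return(trimws(vals[hit]))
      }
      NA_character_
    })
    if (anyNA(locus))
      stop_format("GFF3 gene row without locus_tag/ID/Name attribute")
    df <- data.frame(locus = locus, scaffold = m[, 1],
                     start = as.integer(m[, 4]), end = as.integer(m[, 5]),
                     strand = m[, 7], stringsAsFactors = FALSE)
  }
  df$locus <- as.character(df$locus)
  df$scaffold <- as.character(df$scaffold)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$strand <- as.character(df$strand)
  if (any(!is.finite(df$start)) || any(!is.finite(df$end)) || any(df$start < 1))
    stop_validation("gene coordinates must be integers >= 1")
  bad <- which(df$start > df$end)
  if (length(bad))
    stop_validation("gene '", df$locus[bad[1]], "' has start > end")
  if (anyDuplicated(df$locus))
    stop_validation("duplicate locus: ",
                    df$locus[duplicated(df$locus)][1])
  if (!all(df$strand %in% c("+", "-")))
    stop_validation("gene strand must be '+' or '-'")
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Aggregate site counts to per-gene total and unique count matrices
#'
#' Total counts sum the reads at all insertion sites falling inside the
#' (optionally trimmed) gene body; unique counts are the number of such
#' sites with a nonzero read count in the sample. With gene length
#' `L = end - start + 1` and `t = floor(trim_frac * L)`, a site is assigned
#' to the gene when its position lies within `[start + t, end - t]` on the
#' same scaffold, regardless of strand. A site inside two overlapping genes
#' contributes to both; genes with no sites get zero counts.
#'
#' @param sites a `site_counts` object.
#' @param genes a `gene_table`.
#' @param trim_frac fraction in `[0, 0.5)` of the gene length trimmed from
#'   each end before assigning sites. Default 0.
#' @return A list with elements `total` and `unique`, each an integer
#'   matrix (genes x samples) of class `gene_counts` with a `flavor`
#'   attribute.
#' @export
aggregate_counts <- function(sites, genes, trim_frac = 0) {
  stopifnot(inherits(sites, "site_counts"))
  if (!is.numeric(trim_frac) || trim_frac < 0 || trim_frac >= 0.5)
    stop_validation("trim_frac must lie in [0, 0.5)")
  ns <- ncol(sites$counts)
  ng <- nrow(genes)
  tot <- matrix(0L, ng, ns, dimnames = list(genes$locus, colnames(sites$counts)))
  unq <- tot
  pos <- sites$sites$position
  scaf <- sites$sites$scaffold
  for (i in seq_len(ng)) {
    L <- genes$end[i] - genes$start[i] + 1L
    t <- floor(trim_frac * L)
    lo <- genes$start[i] + t
    hi <- genes$end[i] - t
    hit <- which(scaf == genes$scaffold[i] & pos >= lo & pos <= hi)
    if (length(hit)) {
      cs <- sites$counts[hit, , drop = FALSE]
      tot[i, ] <- as.integer(colSums(cs))
      unq[i, ] <- as.integer(colSums(cs > 0L))
    }
  }
  list(total = as_gene_counts(tot, "total"),
       unique = as_gene_counts(unq, "unique"))
}

#' Construct a gene count matrix
#'
#' @param values non-negative integer matrix, genes x samples, with
#'   dimnames.
#' @param flavor `"total"` or `"unique"`.
#' @return The matrix with class `gene_counts` and a `flavor` attribute.
#' @export
as_gene_counts <- function(values, flavor = c("total", "unique")) {
  flavor <- match.arg(flavor)
  values <- as.matrix(values)
  if (any(values < 0)) stop_validation("gene counts must be non-negative")
  storage.mode(values) <- "integer"
  structure(values, flavor = flavor, class = c("gene_counts", class(values)))
}

#' @export
print.gene_counts <- function(x, ...) {
  cat("Gene count matrix (", attr(x, "flavor"), "): ",
      nrow(x), " genes x ", ncol(x), " samples\n", sep = "")
  invisible(x)
}

## subsetting keeps the flavor attribute on matrix results
#' @export
`[.gene_counts` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod()
  if (is.matrix(out))
    out <- structure(out, flavor = attr(x, "flavor"),
                     class = c("gene_counts", "matrix", "array"))
  out
}

#' Write / read a gene count matrix as TSV
#'
#' Genes are rows and samples columns; the first column is `gene`. The
#' flavor is preserved through a `#flavor=` header comment line.
#'
#' @param matrix a `gene_counts` matrix.
#' @param path file path.
#' @return `write_gene_counts` returns `path` invisibly;
#'   `read_gene_counts` returns a `gene_counts` matrix.
#' @export
write_gene_counts <- function(matrix, path) {
  stopifnot(inherits(matrix, "gene_counts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#flavor=", attr(matrix, "flavor")), con)
  genes <- rownames(matrix)
  if (is.null(genes)) genes <- character(nrow(matrix))
  df <- data.frame(gene = genes,
                   as.data.frame(unclass(matrix), check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_counts
#' @export
read_gene_counts <- function(path) {
  first <- readLines(path, n = 1)
  flavor <- "total"
  if (startsWith(first, "#flavor="))
    flavor <- sub("^#flavor=", "", first)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene")
    stop_format("gene count file must have 'gene' as its first column")
  if (anyDuplicated(df$gene))
    stop_validation("duplicate gene row: ", df$gene[duplicated(df$gene)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  if (nrow(df) && !is_count_vector(as.vector(m)))
    stop_validation("gene counts must be non-negative integers")
  as_gene_counts(m, match.arg(flavor, c("total", "unique")))
}
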