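#' @importFrom methods as is
#' @importFrom stats median rnorm runif rbinom rnbinom rlnorm cor pnorm
#'   quantile setNames complete.cases fisher.test sd var lm coef
#' @importFrom utils read.delim write.table head modifyList
NULL

# All genomic intervals in this package use the BED convention:
# 0-based, half-open [start, end). GFF3 (1-based, closed) is converted
# on read and write at the boundary.

#' Validate a peak/interval data frame
#'
#' Checks that a data frame carries well-formed genomic intervals in the
#' package's internal convention (0-based, half-open).
#'
#' @param x data.frame with at least columns `chrom`, `start`, `end`.
#' @param require_score require a numeric, finite `score` column.
#' @param what label used in error messages.
#' @return `x`, invisibly, after validation.
#' @export
validate_intervals <- function(x, require_score = FALSE, what = "interval") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(what, " table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(x)) {
    bad <- which(!(x$start >= 0 & x$start < x$end))
    if (length(bad)) {
      stop(sprintf("malformed %s at row %d: [%s, %s) on %s",
                   what, bad[1], x$start[bad[1]], x$end[bad[1]],
                   x$chrom[bad[1]]))
    }
  }
  if (require_score) {
    if (is.null(x$score) || !all(is.finite(x$score))) {
      stop(what, " table needs a finite numeric 'score' column")
    }
  }
  invisible(x)
}

#' Convert an interval data frame to a GRanges
#'
#' @param x data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   optional further columns carried over as metadata.
#' @return a [GenomicRanges::GRanges] (1-based closed, as Bioconductor uses).
#' @export
intervals_to_granges <- function(x) {
  validate_intervals(x)
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
  extra <- setdiff(names(x), c("chrom", "start", "end"))
  if (length(extra)) {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(x[, extra, drop = FALSE])
  }
  gr
}

#' Convert a GRanges back to the internal interval data frame
#'
#' @param gr a [GenomicRanges::GRanges].
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open) plus
#'   any metadata columns.
#' @export
granges_to_intervals <- function(gr) {
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) out <- cbind(out, mc)
  rownames(out) <- NULL
  out
}

#' Read scored peaks from a BED file
#'
#' Reads BED3/BED6; the BED score column (column 5) becomes `score` and the
#' name column (column 4) becomes `name` when present.
#'
#' @param path path to a BED file.
#' @return data.frame with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- granges_to_intervals(gr)
  st <- as.character(BiocGenerics::strand(gr))
  if (any(st != "*")) out$strand <- st
  out
}

#' Write intervals to a BED file
#'
#' Writes BED6 when `name`/`score`/`strand` columns are present, BED3
#' otherwise.
#'
#' @param x interval data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed_peaks <- function(x, path) {
  validate_intervals(x)
  gr <- intervals_to_granges(x)
  if (!is.null(x$strand)) {
    BiocGenerics::strand(gr) <- x$strand
    S4Vectors::mcols(gr)$strand <- NULL
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Extracts `gene` records (and their exons, when present) into the package's
#' 0-based half-open convention, computing the TSS from the strand.
#'
#' @param path path to a GFF3 file.
#' @return list with elements `genes` (data.frame: `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `tss`) and `exons` (data.frame: `gene_id`,
#'   `chrom`, `start`, `end`).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  df <- granges_to_intervals(gr)
  df$strand <- as.character(BiocGenerics::strand(gr))
  genes <- df[df$type == "gene", , drop = FALSE]
  id <- if (!is.null(genes$ID)) as.character(genes$ID) else
    as.character(genes$Name)
  genes <- data.frame(
    gene_id = id, chrom = genes$chrom, start = genes$start,
    end = genes$end, strand = genes$strand, stringsAsFactors = FALSE
  )
  genes$tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  exons <- df[df$type == "exon", , drop = FALSE]
  ex <- if (nrow(exons)) {
    parent <- vapply(exons$Parent, function(p) as.character(p)[1],
                     character(1))
    data.frame(gene_id = sub("^mRNA:", "", parent), chrom = exons$chrom,
               start = exons$start, end = exons$end,
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(), chrom = character(),
               start = integer(), end = integer())
  }
  list(genes = genes, exons = ex)
}

#' Write simulated gene models to GFF3
#'
#' @param genes data.frame as returned in `make_genome()$genes`.
#' @param exons data.frame of exon intervals with a `gene_id` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, exons, path) {
  g <- intervals_to_granges(genes[, c("chrom", "start", "end")])
  BiocGenerics::strand(g) <- genes$strand
  S4Vectors::mcols(g)$type <- "gene"
  S4Vectors::mcols(g)$ID <- genes$gene_id
  e <- intervals_to_granges(exons[, c("chrom", "start", "end")])
  BiocGenerics::strand(e) <- genes$strand[match(exons$gene_id,
                                                genes$gene_id)]
  S4Vectors::mcols(e)$type <- "exon"
  S4Vectors::mcols(e)$Parent <- exons$gene_id
  combined <- suppressWarnings(c(g, e))
  S4Vectors::mcols(combined)$source <- "drmscan"
  rtracklayer::export(combined, path, format = "GFF3")
  invisible(path)
}

#' Write a count matrix with its design to TSV files
#'
#' The count TSV has a header row of sample ids and a first column of peak
#' ids in `chrom:start-end` form.
#'
#' @param counts integer matrix, peaks x samples, with dimnames.
#' @param design data.frame describing samples (`sample`, `stage`, `damage`,
#'   `replicate`).
#' @param counts_path,design_path output paths.
#' @return invisibly, a list of the two paths.
#' @export
write_count_matrix <- function(counts, design, counts_path, design_path) {
  df <- data.frame(peak_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(design, design_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(counts = counts_path, design = design_path))
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param counts_path,design_path paths written by [write_count_matrix()].
#' @return list with `counts` (matrix) and `design` (data.frame).
#' @export
read_count_matrix <- function(counts_path, design_path) {
  df <- read.delim(counts_path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  list(counts = m, design = read.delim(design_path))
}
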