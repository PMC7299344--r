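# Peak annotation: nearest-two candidate target genes (strand-agnostic)
# and genomic feature-category assignment with Fisher enrichment of a peak
# subset (e.g. the DRMS set) against the atlas background.

FEATURE_CATEGORIES <- c("active_promoter", "active_exon", "active_intron",
                        "other_open_chromatin", "other")

#' Nearest two genes to a peak
#'
#' Distance is 0 when the peak overlaps the gene body, otherwise the gap
#' between the closest edges; strand and side are ignored ("nearest two
#' genes regardless of orientation"). Ties are broken by gene start, then
#' gene id. With `mode = "tss"` the distance is measured from the peak to
#' the transcription start site instead of the gene body.
#'
#' @param peak single-row interval data.frame (`chrom`, `start`, `end`).
#' @param genes gene data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`).
#' @param mode `"body"` (default) or `"tss"`.
#' @param per_side when TRUE, return the nearest gene on each side
#'   (upstream/downstream) instead of the two nearest overall.
#' @return data.frame (`gene_id`, `distance`) with <= 2 rows; empty with a
#'   warning when the chromosome has no genes.
#' @export
nearest_two_genes <- function(peak, genes, mode = c("body", "tss"),
                              per_side = FALSE) {
  mode <- match.arg(mode)
  validate_intervals(peak, what = "peak")
  g <- genes[genes$chrom == peak$chrom[1], , drop = FALSE]
  if (!nrow(g)) {
    warning("no genes on chromosome ", peak$chrom[1])
    return(data.frame(gene_id = character(), distance = integer()))
  }
  if (mode == "tss") {
    gstart <- g$tss
    gend <- g$tss + 1L
  } else {
    gstart <- g$start
    gend <- g$end
  }
  pgr <- intervals_to_granges(peak[1, c("chrom", "start", "end")])
  ggr <- GenomicRanges::GRanges(peak$chrom[1],
                                IRanges::IRanges(gstart + 1L, gend))
  d <- GenomicRanges::distance(pgr, ggr)
  ord <- order(d, g$start, g$gene_id)
  if (per_side) {
    left <- ord[gend[ord] <= peak$start[1]]
    right <- ord[gstart[ord] >= peak$end[1]]
    overlap <- setdiff(ord, c(left, right))
    pick <- unique(c(overlap, head(left, 1), head(right, 1)))
    pick <- pick[order(d[pick], g$start[pick], g$gene_id[pick])]
    pick <- head(pick, 2)
  } else {
    pick <- head(ord, 2)
  }
  data.frame(gene_id = g$gene_id[pick], distance = as.integer(d[pick]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Annotate every peak with its nearest two genes
#'
#' @param peaks interval data.frame with a `peak_id` column (e.g. an
#'   atlas).
#' @param genes gene data.frame as in [nearest_two_genes()].
#' @param ... passed to [nearest_two_genes()].
#' @return data.frame (`peak_id`, `rank`, `gene_id`, `distance`).
#' @export
annotate_nearest_genes <- function(peaks, genes, ...) {
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    hit <- suppressWarnings(
      nearest_two_genes(peaks[i, , drop = FALSE], genes, ...)
    )
    if (!nrow(hit)) return(NULL)
    data.frame(peak_id = peaks$peak_id[i], rank = seq_len(nrow(hit)),
               hit, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(peak_id = character(), rank = integer(),
                      gene_id = character(), distance = integer())
  }
  rownames(out) <- NULL
  out
}

#' Build a genomic feature-category map from gene models
#'
#' Constructs labeled intervals from gene models and an active-gene list:
#' promoters (TSS +/- `promoter_window`) and the exons/introns of active
#' genes, plus optional `other_open_chromatin` intervals (e.g. accessible
#' peaks outside those features). Bases covered by several categories are
#' resolved at query time by the fixed precedence
#' promoter > exon > intron > other open chromatin > other.
#'
#' @param genes,exons data.frames as returned by [make_genome()] or
#'   [read_gene_models()].
#' @param active_genes character vector of active `gene_id`s (all genes
#'   when NULL).
#' @param open_chromatin optional interval data.frame labeled
#'   `other_open_chromatin`.
#' @param promoter_window half-width of the promoter window around the TSS.
#' @return data.frame (`chrom`, `start`, `end`, `category`).
#' @export
build_category_map <- function(genes, exons, active_genes = NULL,
                               open_chromatin = NULL,
                               promoter_window = 250) {
  if (is.null(active_genes)) active_genes <- genes$gene_id
  act <- genes[genes$gene_id %in% active_genes, , drop = FALSE]
  prom <- data.frame(chrom = act$chrom,
                     start = pmax(0L, act$tss - promoter_window),
                     end = act$tss + promoter_window + 1L,
                     category = "active_promoter", stringsAsFactors = FALSE)
  ex <- exons[exons$gene_id %in% active_genes, , drop = FALSE]
  exdf <- data.frame(chrom = ex$chrom, start = ex$start, end = ex$end,
                     category = "active_exon", stringsAsFactors = FALSE)
  # introns: gene body minus exons
  body <- intervals_to_granges(act[, c("chrom", "start", "end")])
  exgr <- intervals_to_granges(ex[, c("chrom", "start", "end")])
  intr <- GenomicRanges::setdiff(body, exgr)
  intrdf <- granges_to_intervals(intr)
  intrdf <- intrdf[intrdf$end > intrdf$start, , drop = FALSE]
  if (nrow(intrdf)) intrdf$category <- "active_intron"
  pieces <- list(prom, exdf,
                 if (nrow(intrdf)) intrdf else NULL,
                 if (!is.null(open_chromatin)) {
                   data.frame(open_chromatin[, c("chrom", "start", "end")],
                              category = "other_open_chromatin",
                              stringsAsFactors = FALSE)
                 } else NULL)
  out <- do.call(rbind, Filter(Negate(is.null), pieces))
  rownames(out) <- NULL
  out
}

#' Categorize a peak by its midpoint
#'
#' Assigns the category of the peak midpoint under the precedence
#' active_promoter > active_exon > active_intron > other_open_chromatin;
#' an uncovered midpoint is `"other"`.
#'
#' @param peaks interval data.frame (one or more peaks).
#' @param category_map data.frame (`chrom`, `start`, `end`, `category`).
#' @return character vector of categories, one per peak.
#' @export
categorize_peak <- function(peaks, category_map) {
  validate_intervals(peaks, what = "peak")
  mid <- as.integer(floor((peaks$start + peaks$end) / 2))
  midgr <- GenomicRanges::GRanges(peaks$chrom,
                                  IRanges::IRanges(mid + 1L, mid + 1L))
  mapgr <- intervals_to_granges(category_map[, c("chrom", "start", "end")])
  hits <- GenomicRanges::findOverlaps(midgr, mapgr)
  out <- rep("other", nrow(peaks))
  if (length(hits)) {
    prec <- match(category_map$category, FEATURE_CATEGORIES)
    best <- tapply(prec[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits), min)
    out[as.integer(names(best))] <- FEATURE_CATEGORIES[best]
  }
  out
}

#' Feature-category enrichment of a peak subset
#'
#' For each category, compares the fraction of subset peaks in the category
#' with the background fraction: fold enrichment is their ratio and the
#' p-value comes from a two-sided Fisher exact test on the 2x2 table
#' (in/out of category x in/out of subset, subset vs rest of background),
#' BH-adjusted across categories.
#'
#' @param subset_peaks,background_peaks interval data.frames; the subset
#'   must be a subset of the background (checked by `peak_id` when present).
#' @param category_map data.frame (`chrom`, `start`, `end`, `category`).
#' @return data.frame: `category`, `n_subset`, `n_background`, `fold`
#'   (NA for categories empty in the background), `pvalue`, `padj`.
#' @export
category_enrichment <- function(subset_peaks, background_peaks,
                                category_map) {
  if (!is.null(subset_peaks$peak_id) &&
      !is.null(background_peaks$peak_id) &&
      !all(subset_peaks$peak_id %in% background_peaks$peak_id)) {
    stop("subset peaks must be contained in the background")
  }
  cat_sub <- categorize_peak(subset_peaks, category_map)
  cat_bg <- categorize_peak(background_peaks, category_map)
  n_s <- nrow(subset_peaks)
  n_b <- nrow(background_peaks)
  rows <- lapply(FEATURE_CATEGORIES, function(cc) {
    a <- sum(cat_sub == cc)
    b <- sum(cat_bg == cc)
    fold <- if (b == 0) NA_real_ else (a / n_s) / (b / n_b)
    p <- if (b == 0) NA_real_ else {
      # subset vs the rest of the background
      tab <- matrix(c(a, n_s - a, b - a, (n_b - n_s) - (b - a)), nrow = 2)
      fisher.test(tab, alternative = "two.sided")$p.value
    }
    data.frame(category = cc, n_subset = a, n_background = b, fold = fold,
               pvalue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$pvalue)
  rownames(out) <- NULL
  out
}
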