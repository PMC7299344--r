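# Union peak atlas construction: rank-select per-condition peak calls,
# merge everything that overlaps by >= 1 bp into non-overlapping atlas
# peaks, and count fragments over the atlas.

#' Select the top-scoring peaks from a scored peak set
#'
#' Returns the `n` highest-scoring peaks. Ties at the n-th rank are broken
#' deterministically by (chrom, start) ascending so repeated runs select the
#' same peaks. If fewer than `n` peaks are available all are returned with
#' a warning.
#'
#' @param peaks scored peak data.frame (`chrom`, `start`, `end`, `score`).
#' @param n number of peaks to keep (>= 0).
#' @return the selected peaks, ordered by (chrom, start).
#' @export
select_top_peaks <- function(peaks, n) {
  if (length(n) != 1 || is.na(n) || n < 0) stop("n must be a single count >= 0")
  validate_intervals(peaks, require_score = TRUE, what = "scored peak")
  if (n < nrow(peaks)) {
    ord <- order(-peaks$score, peaks$chrom, peaks$start)
    keep <- sort(ord[seq_len(n)])
    peaks <- peaks[keep, , drop = FALSE]
  } else if (n > nrow(peaks)) {
    warning(sprintf("requested %d peaks but only %d available; returning all",
                    n, nrow(peaks)))
  }
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

#' Merge overlapping peaks into a union atlas
#'
#' Takes the transitive closure of >= 1 bp overlap: every group of
#' mutually-reachable overlapping peaks becomes one atlas peak spanning
#' min(start) to max(end). Under the half-open convention, bookended peaks
#' (`end == start` of the next) overlap by 0 bp and are NOT merged. The
#' operation is idempotent and invariant to input order.
#'
#' @param peaks interval data.frame; extra columns are dropped.
#' @param chroms optional chromosome allow-list; peaks on other chromosomes
#'   are discarded before merging.
#' @return a `peak_atlas` data.frame: `chrom`, `start`, `end`, `peak_id`
#'   (stable `chrom:start-end` ids), `n_inputs` (number of input peaks
#'   merged into each atlas peak), sorted by (chrom, start), pairwise
#'   non-overlapping.
#' @export
merge_overlapping <- function(peaks, chroms = NULL) {
  validate_intervals(peaks, what = "peak")
  if (!is.null(chroms)) {
    peaks <- peaks[peaks$chrom %in% chroms, , drop = FALSE]
  }
  gr <- intervals_to_granges(peaks[, c("chrom", "start", "end")])
  # min.gapwidth = 0L merges >=1 bp overlaps only; adjacent ranges
  # (gap width 0 in 1-based closed coords) stay separate.
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 0L,
                                  with.revmap = TRUE)
  n_inputs <- lengths(S4Vectors::mcols(merged)$revmap)
  S4Vectors::mcols(merged) <- NULL
  atlas <- granges_to_intervals(merged)
  atlas$n_inputs <- n_inputs
  atlas <- atlas[order(atlas$chrom, atlas$start), , drop = FALSE]
  atlas$peak_id <- sprintf("%s:%d-%d", atlas$chrom, atlas$start, atlas$end)
  rownames(atlas) <- NULL
  atlas <- atlas[, c("chrom", "start", "end", "peak_id", "n_inputs")]
  class(atlas) <- c("peak_atlas", "data.frame")
  atlas
}

#' Build the union atlas from ranked per-condition peak sets
#'
#' Convenience wrapper: select the top `n_top` peaks from each condition's
#' scored set, pool them, and merge overlaps into the atlas.
#'
#' @param peak_sets named list of scored peak data.frames, one per
#'   condition.
#' @param n_top number of top-ranked peaks to take from each set.
#' @param chroms optional chromosome allow-list passed to
#'   [merge_overlapping()].
#' @return a `peak_atlas` data.frame (see [merge_overlapping()]).
#' @export
build_atlas <- function(peak_sets, n_top = 11500, chroms = NULL) {
  stopifnot(is.list(peak_sets), length(peak_sets) >= 1)
  selected <- lapply(peak_sets, select_top_peaks, n = n_top)
  pooled <- do.call(rbind, lapply(selected, function(p) {
    p[, c("chrom", "start", "end")]
  }))
  rownames(pooled) <- NULL
  merge_overlapping(pooled, chroms = chroms)
}

#' Count fragments over atlas peaks
#'
#' Entry (i, j) is the number of sample-j fragments overlapping atlas peak i
#' by at least 1 bp. A fragment spanning k peaks increments all k cells
#' (multi-overlap counting, as featureCounts' `allowMultiOverlap`).
#'
#' @param fragments named list of per-sample fragment interval data.frames
#'   (`chrom`, `start`, `end`).
#' @param atlas a `peak_atlas` from [merge_overlapping()].
#' @return integer matrix, atlas peaks x samples, with `peak_id` rownames.
#' @export
count_in_atlas <- function(fragments, atlas) {
  stopifnot(is.list(fragments), length(fragments) >= 1)
  if (is.null(names(fragments))) {
    names(fragments) <- sprintf("sample_%d", seq_along(fragments))
  }
  agr <- intervals_to_granges(atlas[, c("chrom", "start", "end")])
  counts <- vapply(names(fragments), function(s) {
    fr <- fragments[[s]]
    validate_intervals(fr, what = sprintf("fragment (sample %s)", s))
    if (!nrow(fr)) {
      warning("sample ", s, " has zero fragments; counting zeros")
      return(integer(length(agr)))
    }
    fgr <- intervals_to_granges(fr[, c("chrom", "start", "end")])
    GenomicRanges::countOverlaps(agr, fgr, minoverlap = 1L)
  }, integer(nrow(atlas)))
  rownames(counts) <- atlas$peak_id
  counts
}
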