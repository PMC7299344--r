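# Z-score signal tracks and difference tracks for browser-style display of
# pooled per-condition accessibility, e.g. damage-responsiveness as
# (early damaged - early undamaged) and maturity silencing as
# (early damaged - late damaged).

#' Binned z-score signal track for one condition
#'
#' Pools the fragments of all replicates of a condition, counts fragments
#' overlapping each fixed-size bin, and standardizes the binned coverage to
#' z-scores against the genome-wide bin mean and standard deviation.
#'
#' @param fragments a fragment interval data.frame or a list of them
#'   (replicates; pooled before binning).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param bin_size bin width in bp.
#' @return data.frame (`chrom`, `start`, `end`, `z`), one row per bin, in
#'   bedGraph-ready form.
#' @export
signal_track <- function(fragments, chrom_lengths, bin_size = 10) {
  if (is.data.frame(fragments)) fragments <- list(fragments)
  pooled <- do.call(rbind, lapply(fragments, function(f) {
    validate_intervals(f, what = "fragment")
    f[, c("chrom", "start", "end")]
  }))
  bins <- GenomicRanges::tileGenome(chrom_lengths, tilewidth = bin_size,
                                    cut.last.tile.in.chrom = TRUE)
  cov <- if (nrow(pooled)) {
    GenomicRanges::countOverlaps(bins, intervals_to_granges(pooled),
                                 minoverlap = 1L)
  } else {
    integer(length(bins))
  }
  s <- sd(cov)
  if (!is.finite(s) || s == 0) {
    if (all(cov == mean(cov))) {
      # uniform coverage standardizes to identically zero
      z <- rep(0, length(cov))
    } else {
      stop("zero variance in binned coverage; cannot compute z-scores")
    }
  } else {
    z <- (cov - mean(cov)) / s
  }
  out <- granges_to_intervals(bins)
  out$z <- z
  out
}

#' Subtract one z-score track from another
#'
#' Bin-wise difference `a - b`; positive values mark regions more accessible
#' in condition `a`.
#'
#' @param a,b tracks from [signal_track()] over identical bins.
#' @return data.frame like the inputs with `z = a$z - b$z`.
#' @export
subtract_tracks <- function(a, b) {
  if (!identical(a[, c("chrom", "start", "end")],
                 b[, c("chrom", "start", "end")])) {
    stop("tracks must be binned identically")
  }
  out <- a
  out$z <- a$z - b$z
  out
}

#' Write a track to a bedGraph file
#'
#' @param track data.frame (`chrom`, `start`, `end`, `z`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=bedGraph", con)
  write.table(track[, c("chrom", "start", "end", "z")], con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
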