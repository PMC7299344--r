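# Enhancer sequence screens: IUPAC consensus scanning on both strands
# (AP-1 / Pho / Sp1 by default), exact k-mer search across a genome, and a
# per-sequence site map combining all configured motifs.

#' Default motif consensus set
#'
#' Literature consensus sequences for the binding sites screened in
#' damage-responsive (AP-1, the JNK-responsive Jun/Fos dimer) and
#' Polycomb-associated silencing elements (Pleiohomeotic core, Sp1). All
#' are overridable; the set is a convenience, not a claim of completeness.
#'
#' @return named character vector of IUPAC patterns.
#' @export
default_motifs <- function() {
  c(AP1 = "TGASTCA", Pho = "GCCAT", Sp1 = "GGGCGG")
}

IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "B",
                 "D", "H", "V", "N")

validate_iupac <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, IUPAC_CHARS)
  if (length(bad)) {
    stop("non-IUPAC character(s) in pattern: ", paste(bad, collapse = ", "))
  }
  toupper(pattern)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

hit_frame <- function(seqid, starts, width, strand, motif, sequence) {
  if (!length(starts)) {
    return(data.frame(seqid = character(), start = integer(),
                      length = integer(), strand = character(),
                      motif = character(), match = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    seqid = seqid, start = as.integer(starts), length = as.integer(width),
    strand = strand, motif = motif,
    match = substring(sequence, starts + 1L, starts + width),
    stringsAsFactors = FALSE
  )
}

#' Scan a sequence for a degenerate (IUPAC) motif
#'
#' Reports every match of the IUPAC pattern on the plus strand and (by
#' default) the minus strand. Minus-strand hits are located by matching the
#' reverse complement of the pattern against the plus strand; their
#' coordinates are the plus-strand span of the match and the reported
#' `match` column is the plus-strand substring. Overlapping hits are all
#' reported. Coordinates are 0-based.
#'
#' @param sequence character string (ACGT; other letters never match).
#' @param pattern IUPAC consensus string.
#' @param motif_name name recorded in the `motif` column.
#' @param seqid sequence id recorded in the `seqid` column.
#' @param both_strands scan the minus strand too.
#' @return data.frame of hits: `seqid`, `start`, `length`, `strand`,
#'   `motif`, `match`.
#' @export
scan_iupac <- function(sequence, pattern, motif_name = pattern,
                       seqid = "seq", both_strands = TRUE) {
  pattern <- validate_iupac(pattern)
  subj <- Biostrings::DNAString(sequence)
  w <- nchar(pattern)
  plus <- Biostrings::matchPattern(pattern, subj, fixed = FALSE)
  out <- hit_frame(seqid, BiocGenerics::start(plus) - 1L, w, "+",
                   motif_name, sequence)
  if (both_strands) {
    minus <- Biostrings::matchPattern(revcomp(pattern), subj, fixed = FALSE)
    out <- rbind(out, hit_frame(seqid, BiocGenerics::start(minus) - 1L, w,
                                "-", motif_name, sequence))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact search for a k-mer across a set of sequences
#'
#' Finds every exact occurrence of the query on both strands of every
#' sequence (e.g. a genome-wide search for a 17 bp conserved motif). A
#' palindromic query is reported once per strand with identical
#' coordinates; deduplicate downstream if single-stranded counting is
#' wanted.
#'
#' @param genome named character vector of sequences (or a single string).
#' @param query_kmer ACGT string; ambiguous bases are refused (use
#'   [scan_iupac()]).
#' @param both_strands search the minus strand too.
#' @return data.frame of hits as in [scan_iupac()].
#' @export
exact_motif_search <- function(genome, query_kmer, both_strands = TRUE) {
  q <- toupper(query_kmer)
  if (grepl("[^ACGT]", q)) {
    stop("query contains ambiguous bases; use scan_iupac() for IUPAC ",
         "patterns")
  }
  if (is.null(names(genome))) {
    names(genome) <- sprintf("seq_%d", seq_along(genome))
  }
  out <- lapply(names(genome), function(id) {
    subj <- Biostrings::DNAString(genome[[id]])
    w <- nchar(q)
    plus <- Biostrings::matchPattern(q, subj, fixed = TRUE)
    hits <- hit_frame(id, BiocGenerics::start(plus) - 1L, w, "+", q,
                      genome[[id]])
    if (both_strands) {
      minus <- Biostrings::matchPattern(revcomp(q), subj, fixed = TRUE)
      hits <- rbind(hits, hit_frame(id, BiocGenerics::start(minus) - 1L, w,
                                    "-", q, genome[[id]]))
    }
    hits
  })
  out <- do.call(rbind, out)
  out <- out[order(match(out$seqid, names(genome)), out$start,
                   out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map all configured motif sites on a sequence
#'
#' Runs [scan_iupac()] for every motif in the set and returns one ordered
#' table — the textual analogue of an annotated enhancer schematic, with
#' site orientation. Output order is (start, motif, strand), independent of
#' the order motifs are supplied in.
#'
#' @param sequence character string.
#' @param motifs named character vector of IUPAC patterns (defaults to
#'   [default_motifs()]).
#' @param seqid sequence id for the report.
#' @return data.frame of hits sorted by coordinate.
#' @export
site_map_report <- function(sequence, motifs = default_motifs(),
                            seqid = "seq") {
  if (!length(motifs)) {
    return(hit_frame("x", integer(), 0L, "+", "x", "")[0, ])
  }
  if (is.null(names(motifs))) names(motifs) <- motifs
  out <- do.call(rbind, lapply(names(motifs), function(m) {
    scan_iupac(sequence, motifs[[m]], motif_name = m, seqid = seqid)
  }))
  out <- out[order(out$start, out$motif, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find maximal conserved blocks shared by all sequences
#'
#' Detects every maximal run of identical sequence of length at least
#' `min_len` present in all input sequences (exact identity, no alignment —
#' the operation behind "stretches of identical DNA >= 50 bp" screens of
#' orthologous enhancers). Anchoring uses `min_len`-mers of the first
#' sequence, each verified in all other sequences and extended maximally in
#' both directions; contained or duplicate blocks are removed.
#'
#' @param sequences character vector of >= 2 sequences; the first is the
#'   reference whose coordinates anchor the report.
#' @param min_len minimum block length (>= 8; shorter screens are refused
#'   as combinatorially uninformative).
#' @return data.frame, one row per block: `start`, `end` (0-based half-open
#'   in the reference), `length`, `block` (the sequence itself), and
#'   `start_<i>` columns giving the block's 0-based start in each other
#'   sequence (first occurrence).
#' @export
find_conserved_blocks <- function(sequences, min_len = 50) {
  stopifnot(length(sequences) >= 2, all(nchar(sequences) > 0))
  if (min_len < 8) stop("min_len must be >= 8")
  ref <- sequences[[1]]
  others <- sequences[-1]
  n1 <- nchar(ref)
  if (n1 < min_len || any(nchar(others) < min_len)) {
    return(empty_blocks(length(others)))
  }
  k <- as.integer(min_len)
  starts <- seq_len(n1 - k + 1L)
  kmers <- substring(ref, starts, starts + k - 1L)
  present <- rep(TRUE, length(kmers))
  for (s in others) {
    pos <- seq_len(nchar(s) - k + 1L)
    present <- present & (kmers %in% substring(s, pos, pos + k - 1L))
  }
  anchors <- which(present)
  if (!length(anchors)) return(empty_blocks(length(others)))
  blocks <- list()
  for (a in anchors) {
    b <- extend_anchor(ref, others, a - 1L, k)
    if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  }
  if (!length(blocks)) return(empty_blocks(length(others)))
  out <- do.call(rbind, blocks)
  out <- out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
  # drop blocks contained in a longer one at the same locus
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    contained <- out$start <= out$start[i] & out$end >= out$end[i] &
      (out$end - out$start) > (out$end[i] - out$start[i])
    if (any(contained)) keep[i] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_blocks <- function(n_others) {
  out <- data.frame(start = integer(), end = integer(), length = integer(),
                    block = character(), stringsAsFactors = FALSE)
  for (i in seq_len(n_others)) out[[sprintf("start_%d", i + 1L)]] <- integer()
  out
}

# Extend the k-mer at 0-based ref position a0 maximally in all sequences.
# Returns a one-row data.frame or NULL when no consistent extension exists.
extend_anchor <- function(ref, others, a0, k) {
  kmer <- substr(ref, a0 + 1L, a0 + k)
  # occurrences of the anchor k-mer in each other sequence
  occ <- lapply(others, function(s) {
    m <- Biostrings::matchPattern(kmer, Biostrings::DNAString(s))
    BiocGenerics::start(m) - 1L
  })
  if (any(!lengths(occ))) return(NULL)
  best <- NULL
  combos <- expand.grid(lapply(occ, function(p) {
    utils::head(p, 25L)  # guard against repeat-induced blowup
  }))
  for (r in seq_len(nrow(combos))) {
    pos <- as.integer(combos[r, ])
    left <- 0L
    while (a0 - left - 1L >= 0L && all(pos - left - 1L >= 0L) &&
           all(substr(ref, a0 - left, a0 - left) ==
               mapply(function(s, p) substr(s, p - left, p - left),
                      others, pos))) {
      left <- left + 1L
    }
    right <- 0L
    lens <- nchar(others)
    while (a0 + k + right < nchar(ref) &&
           all(pos + k + right < lens) &&
           all(substr(ref, a0 + k + right + 1L, a0 + k + right + 1L) ==
               mapply(function(s, p) substr(s, p + k + right + 1L,
                                            p + k + right + 1L),
                      others, pos))) {
      right <- right + 1L
    }
    len <- k + left + right
    row <- data.frame(start = a0 - left, end = a0 + k + right,
                      length = len,
                      block = substr(ref, a0 - left + 1L, a0 + k + right),
                      stringsAsFactors = FALSE)
    for (i in seq_along(pos)) {
      row[[sprintf("start_%d", i + 1L)]] <- pos[i] - left
    }
    best <- rbind(best, row)
  }
  best
}
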