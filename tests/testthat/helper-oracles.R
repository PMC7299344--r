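# Independent brute-force oracles and small fixture generators. These are
# deliberately naive (quadratic loops, position-by-position matching) so
# they share no code path with the implementations they check.

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000,
                             max_width = 60) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width,
             stringsAsFactors = FALSE)
}

# transitive-closure merge by repeated pairwise sweeps until fixpoint
oracle_merge <- function(peaks) {
  iv <- peaks[, c("chrom", "start", "end")]
  repeat {
    changed <- FALSE
    i <- 1
    while (i <= nrow(iv)) {
      j <- i + 1
      while (j <= nrow(iv)) {
        same <- iv$chrom[i] == iv$chrom[j]
        ov <- same && iv$start[i] < iv$end[j] && iv$start[j] < iv$end[i]
        if (ov) {
          iv$start[i] <- min(iv$start[i], iv$start[j])
          iv$end[i] <- max(iv$end[i], iv$end[j])
          iv <- iv[-j, , drop = FALSE]
          changed <- TRUE
        } else {
          j <- j + 1
        }
      }
      i <- i + 1
    }
    if (!changed) break
  }
  iv <- iv[order(iv$chrom, iv$start), ]
  rownames(iv) <- NULL
  iv
}

oracle_count <- function(fragments, atlas) {
  out <- matrix(0L, nrow(atlas), length(fragments),
                dimnames = list(atlas$peak_id, names(fragments)))
  for (s in seq_along(fragments)) {
    fr <- fragments[[s]]
    for (i in seq_len(nrow(atlas))) {
      for (k in seq_len(nrow(fr))) {
        if (fr$chrom[k] == atlas$chrom[i] &&
            fr$start[k] < atlas$end[i] && atlas$start[i] < fr$end[k]) {
          out[i, s] <- out[i, s] + 1L
        }
      }
    }
  }
  out
}

oracle_nearest_two <- function(peak, genes) {
  g <- genes[genes$chrom == peak$chrom[1], , drop = FALSE]
  if (!nrow(g)) return(data.frame(gene_id = character(),
                                  distance = integer()))
  d <- integer(nrow(g))
  for (i in seq_len(nrow(g))) {
    if (peak$end[1] <= g$start[i]) {
      d[i] <- g$start[i] - peak$end[1]
    } else if (g$end[i] <= peak$start[1]) {
      d[i] <- peak$start[1] - g$end[i]
    } else {
      d[i] <- 0L
    }
  }
  ord <- order(d, g$start, g$gene_id)
  head(data.frame(gene_id = g$gene_id[ord], distance = d[ord],
                  stringsAsFactors = FALSE), 2)
}

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

oracle_scan_strand <- function(sequence, pattern) {
  sc <- strsplit(sequence, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  w <- length(pc)
  hits <- integer()
  for (i in seq_len(max(0, length(sc) - w + 1))) {
    ok <- TRUE
    for (j in seq_len(w)) {
      if (!(sc[i + j - 1] %in% IUPAC_SETS[[pc[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i - 1L)
  }
  hits
}

oracle_scan <- function(sequence, pattern) {
  plus <- oracle_scan_strand(sequence, pattern)
  minus <- oracle_scan_strand(sequence, oracle_revcomp(pattern))
  data.frame(start = c(plus, minus),
             strand = rep(c("+", "-"), c(length(plus), length(minus))),
             stringsAsFactors = FALSE)
}

# all maximal substrings of the first sequence, length >= min_len,
# present in every other sequence
oracle_blocks <- function(sequences, min_len) {
  ref <- sequences[[1]]
  others <- sequences[-1]
  n <- nchar(ref)
  common <- function(a, b) {
    sub <- substr(ref, a + 1L, b)
    all(vapply(others, function(s) grepl(sub, s, fixed = TRUE),
               logical(1)))
  }
  out <- data.frame(start = integer(), end = integer())
  for (a in 0:(n - min_len)) {
    for (b in (a + min_len):n) {
      if (!common(a, b)) break
      extendable_right <- b < n && common(a, b + 1L)
      extendable_left <- a > 0 && common(a - 1L, b)
      if (!extendable_right && !extendable_left) {
        out <- rbind(out, data.frame(start = a, end = b))
      }
    }
  }
  unique(out[order(out$start, out$end), , drop = FALSE])
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# small default-style design scaled down for unit tests
small_design <- function(...) {
  sim_design(n_peaks = 600, genome_length = 3e6, ...)
}
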