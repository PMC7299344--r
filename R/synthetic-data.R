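# Synthetic study generator: a staged (early/late L3) x damaged/undamaged
# replicate design with negative-binomial counts, whole-tissue dilution of
# the responding-cell signal, and planted damage-responsive /
# maturity-silenced / DRMS peaks with recorded ground truth.

PEAK_LABELS <- c("null", "damage_responsive_early", "damage_responsive_late",
                 "damage_responsive_both", "maturity_silenced", "drms")

default_conditions <- function() {
  data.frame(
    stage = rep(c("earlyL3", "lateL3"), each = 2),
    damage = rep(c("damaged", "undamaged"), times = 2),
    stringsAsFactors = FALSE
  )
}

#' Simulation design for a synthetic accessibility study
#'
#' Captures the study layout emulated by the generator: four conditions
#' (early/late third instar, damaged/undamaged), three biological replicates
#' each, negative-binomial counts over a shared peak atlas, and dilution of
#' the damage-responsive signal because only a fraction `dilution_fraction`
#' of the profiled tissue is actually responding.
#'
#' @param n_peaks number of atlas peaks to simulate.
#' @param n_replicates biological replicates per condition.
#' @param dilution_fraction fraction `f` in (0, 1] of the damaged tissue
#'   that responds; the bulk mean of a responsive peak is
#'   `mu * ((1 - f) + f * 2^delta)`.
#' @param dispersion negative-binomial dispersion `alpha` (variance
#'   `m + alpha * m^2`); `0` gives Poisson counts.
#' @param base_mean typical expected count per peak; per-peak means are
#'   drawn log-normally around it (`sdlog = 1`) to give a realistic
#'   dynamic range.
#' @param effect_lfc planted log2 effect of damage within responding cells.
#' @param silence_lfc planted log2 drop of silenced peaks in late-stage
#'   tissue (tissue-wide, not diluted).
#' @param label_props named numeric of label proportions over
#'   `c("null", "damage_responsive_early", "damage_responsive_late",
#'   "damage_responsive_both", "maturity_silenced", "drms")`; must sum to 1.
#' @param genome_length length of the synthetic chromosome peaks are
#'   placed on.
#' @param peak_width range (min, max) of simulated peak widths in bp.
#' @param depth_sdlog log-sd of the log-normal per-sample depth factors.
#' @param conditions data.frame with columns `stage`, `damage`; defaults to
#'   the four-condition study layout.
#' @param seed integer RNG seed; every quantity derived from a design is
#'   reproducible given the seed.
#' @return an object of class `sim_design` (a validated list).
#' @export
sim_design <- function(n_peaks = 5000,
                       n_replicates = 3,
                       dilution_fraction = 0.15,
                       dispersion = 0.05,
                       base_mean = 200,
                       effect_lfc = 4,
                       silence_lfc = 2,
                       label_props = c(null = 0.90,
                                       damage_responsive_early = 0.02,
                                       damage_responsive_late = 0.01,
                                       damage_responsive_both = 0.01,
                                       maturity_silenced = 0.04,
                                       drms = 0.02),
                       genome_length = 2e7,
                       peak_width = c(200, 600),
                       depth_sdlog = 0.15,
                       conditions = default_conditions(),
                       seed = 1L) {
  stopifnot(n_peaks >= 1, n_replicates >= 1)
  if (!(dilution_fraction > 0 && dilution_fraction <= 1)) {
    stop("dilution_fraction must be in (0, 1]")
  }
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (base_mean <= 0) stop("base_mean must be > 0")
  if (!setequal(names(label_props), PEAK_LABELS) ||
      abs(sum(label_props) - 1) > 1e-8 || any(label_props < 0)) {
    stop("label_props must be nonnegative over the six labels and sum to 1")
  }
  design <- list(
    n_peaks = as.integer(n_peaks), n_replicates = as.integer(n_replicates),
    dilution_fraction = dilution_fraction, dispersion = dispersion,
    base_mean = base_mean, effect_lfc = effect_lfc,
    silence_lfc = silence_lfc, label_props = label_props[PEAK_LABELS],
    genome_length = genome_length, peak_width = peak_width,
    depth_sdlog = depth_sdlog, conditions = conditions,
    seed = as.integer(seed)
  )
  class(design) <- "sim_design"
  design
}

condition_ids <- function(design) {
  paste(design$conditions$stage, design$conditions$damage, sep = "_")
}

#' Plant ground-truth peaks for a simulation design
#'
#' Assigns each simulated atlas peak a label, a per-peak expected count, and
#' planted effect sizes, and places the peaks without overlap on a synthetic
#' chromosome. The labels partition the peaks; a `drms` peak carries both a
#' damage response in early-stage tissue and tissue-wide late-stage
#' silencing.
#'
#' @param design a [sim_design()].
#' @return data.frame of class `sim_truth`: `peak_id`, `chrom`, `start`,
#'   `end`, `label`, `mu` (expected base count), `delta_damage`,
#'   `delta_silence` (planted log2 effects; 0 where inactive).
#' @export
simulate_truth <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  n <- design$n_peaks
  counts <- floor(design$label_props * n)
  counts["null"] <- counts["null"] + (n - sum(counts))
  label <- sample(rep(names(counts), times = counts))
  width <- sample(seq(design$peak_width[1], design$peak_width[2]), n,
                  replace = TRUE)
  slot <- design$genome_length / n
  if (slot <= max(width) + 2) stop("genome_length too small for n_peaks")
  offset <- vapply(width, function(w) {
    sample.int(max(1L, as.integer(slot - w - 1L)), 1L)
  }, integer(1))
  start <- as.integer((seq_len(n) - 1) * slot) + offset
  mu <- rlnorm(n, meanlog = log(design$base_mean), sdlog = 1)
  truth <- data.frame(
    peak_id = sprintf("peak_%05d", seq_len(n)),
    chrom = "chrS", start = start, end = start + width,
    label = label, mu = mu,
    delta_damage = ifelse(grepl("^damage_responsive|^drms", label),
                          design$effect_lfc, 0),
    delta_silence = ifelse(label %in% c("maturity_silenced", "drms"),
                           design$silence_lfc, 0),
    stringsAsFactors = FALSE
  )
  class(truth) <- c("sim_truth", "data.frame")
  truth
}

# Expected bulk mean of peak i in condition c at unit depth.
# Damage effects act only in the responding fraction f of damaged tissue:
#   mix = (1 - f) + f * 2^delta_damage;
# late-stage silencing acts tissue-wide: factor 2^{-delta_silence}.
truth_condition_means <- function(truth, design) {
  conds <- design$conditions
  f <- design$dilution_fraction
  m <- matrix(0, nrow = nrow(truth), ncol = nrow(conds),
              dimnames = list(truth$peak_id, condition_ids(design)))
  for (k in seq_len(nrow(conds))) {
    stage <- conds$stage[k]; damage <- conds$damage[k]
    active <- (damage == "damaged") & (
      (truth$label %in% c("damage_responsive_early", "drms") &
         stage == "earlyL3") |
      (truth$label == "damage_responsive_late" & stage == "lateL3") |
      (truth$label == "damage_responsive_both")
    )
    delta <- ifelse(active, truth$delta_damage, 0)
    mix <- (1 - f) + f * 2^delta
    # undamaged tissue has no responding fraction; delta is 0 there anyway
    sil <- ifelse(stage == "lateL3", 2^(-truth$delta_silence), 1)
    m[, k] <- truth$mu * mix * sil
  }
  m
}

#' Simulate a replicate count matrix with planted effects
#'
#' Draws negative-binomial counts for every atlas peak and sample. For peak
#' i in sample j of condition c the mean is
#' `s_j * mu_i * ((1 - f) + f * 2^delta_ic) * 2^(-silence_ic)`, with `s_j`
#' a log-normal per-sample depth factor, `f` the responding-tissue fraction
#' (1 for undamaged conditions, where no damage effect acts), and variance
#' `m + alpha * m^2`.
#'
#' @param design a [sim_design()].
#' @param truth optional [simulate_truth()] output; generated from `design`
#'   when omitted.
#' @return list of class `sim_counts`: `counts` (integer matrix, peaks x
#'   samples), `design_table` (sample, stage, damage, replicate),
#'   `depth_factors` (true `s_j`), `truth`.
#' @export
simulate_counts <- function(design, truth = NULL) {
  stopifnot(inherits(design, "sim_design"))
  if (is.null(truth)) truth <- simulate_truth(design)
  set.seed(design$seed + 1L)
  conds <- design$conditions
  cond_id <- condition_ids(design)
  design_table <- data.frame(
    sample = paste0(rep(cond_id, each = design$n_replicates), "_r",
                    rep(seq_len(design$n_replicates), times = nrow(conds))),
    stage = rep(conds$stage, each = design$n_replicates),
    damage = rep(conds$damage, each = design$n_replicates),
    replicate = rep(seq_len(design$n_replicates), times = nrow(conds)),
    stringsAsFactors = FALSE
  )
  n_samples <- nrow(design_table)
  s <- rlnorm(n_samples, meanlog = 0, sdlog = design$depth_sdlog)
  cm <- truth_condition_means(truth, design)
  cond_of_sample <- match(paste(design_table$stage, design_table$damage,
                                sep = "_"), cond_id)
  counts <- matrix(0L, nrow = nrow(truth), ncol = n_samples,
                   dimnames = list(truth$peak_id, design_table$sample))
  alpha <- design$dispersion
  for (j in seq_len(n_samples)) {
    m <- s[j] * cm[, cond_of_sample[j]]
    counts[, j] <- as.integer(if (alpha > 0) {
      rnbinom(length(m), mu = m, size = 1 / alpha)
    } else {
      stats::rpois(length(m), lambda = m)
    })
  }
  out <- list(counts = counts, design_table = design_table,
              depth_factors = setNames(s, design_table$sample),
              truth = truth)
  class(out) <- "sim_counts"
  out
}

#' Simulate per-condition scored peak sets
#'
#' Emulates ranked peak calls per condition: every truth peak whose expected
#' bulk mean in a condition clears `access_floor` is reported with a score
#' equal to that mean (the stand-in for a peak-caller quality score), peak
#' boundaries are jittered so condition sets overlap without being
#' identical, and condition-specific noise peaks with sub-floor scores pad
#' each set to `n_top_pool` entries.
#'
#' @param truth a [simulate_truth()] data frame.
#' @param design the matching [sim_design()].
#' @param n_top_pool number of peaks to report per condition; must be at
#'   least the number of accessible truth peaks in every condition.
#' @param access_floor expected-count threshold below which a peak is
#'   considered closed (not called) in a condition.
#' @param jitter_bp maximum absolute uniform jitter applied independently to
#'   each reported boundary.
#' @return named list (one element per condition) of scored peak
#'   data.frames: `chrom`, `start`, `end`, `name`, `score`, `truth_peak`
#'   (`NA` for noise peaks).
#' @export
simulate_scored_peaks <- function(truth, design, n_top_pool = NULL,
                                  access_floor = 5, jitter_bp = 25) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed + 2L)
  cm <- truth_condition_means(truth, design)
  out <- list()
  for (k in seq_len(ncol(cm))) {
    cond <- colnames(cm)[k]
    acc <- which(cm[, k] >= access_floor)
    if (!is.null(n_top_pool) && n_top_pool < length(acc)) {
      stop("n_top_pool smaller than the number of accessible peaks in ",
           cond)
    }
    jit <- function(n) {
      if (jitter_bp > 0) sample(seq(-jitter_bp, jitter_bp), n,
                                replace = TRUE) else integer(n)
    }
    start <- pmax(0L, truth$start[acc] + jit(length(acc)))
    end <- pmax(start + 1L, truth$end[acc] + jit(length(acc)))
    peaks <- data.frame(
      chrom = truth$chrom[acc], start = start, end = end,
      name = paste0(cond, "_", truth$peak_id[acc]),
      score = cm[acc, k], truth_peak = truth$peak_id[acc],
      stringsAsFactors = FALSE
    )
    n_noise <- if (is.null(n_top_pool)) 0L else n_top_pool - nrow(peaks)
    if (n_noise > 0) {
      w <- sample(seq(design$peak_width[1], design$peak_width[2]), n_noise,
                  replace = TRUE)
      st <- sample.int(design$genome_length - max(w) - 1L, n_noise)
      noise <- data.frame(
        chrom = "chrS", start = st, end = st + w,
        name = sprintf("%s_noise_%05d", cond, seq_len(n_noise)),
        score = runif(n_noise, 0, access_floor),
        truth_peak = NA_character_, stringsAsFactors = FALSE
      )
      peaks <- rbind(peaks, noise)
    }
    out[[cond]] <- peaks[order(peaks$chrom, peaks$start, peaks$end), ]
    rownames(out[[cond]]) <- NULL
  }
  out
}

#' Generate a random genome with gene models
#'
#' Builds an uppercase ACGT chromosome and `gene_count` non-overlapping gene
#' models (random strand, 2-4 exons each), deterministically for a seed.
#'
#' @param seed integer RNG seed.
#' @param length chromosome length in bp; must give every gene a slot of
#'   at least 5 kb (`length >= 5000 * gene_count`) so gene bodies of up to
#'   3 kb fit with intergenic spacing.
#' @param gene_count number of genes to place.
#' @param chrom chromosome name.
#' @return list: `sequence` (single character string), `genes` (data.frame
#'   `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`), `exons`
#'   (data.frame `gene_id`, `chrom`, `start`, `end`).
#' @export
make_genome <- function(seed, length, gene_count, chrom = "chrS") {
  if (length < 5000 * gene_count) {
    stop("length must be >= 5000 * gene_count for the requested genes")
  }
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
               collapse = "")
  slot <- length / gene_count
  genes <- exons <- vector("list", gene_count)
  for (i in seq_len(gene_count)) {
    glen <- sample(1000:3000, 1)
    gstart <- as.integer((i - 1) * slot) +
      sample.int(as.integer(slot - glen - 1L), 1L)
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(2:4, 1)
    # split the body into alternating exons/introns
    cuts <- sort(sample(seq(50, glen - 50), 2 * n_ex - 2))
    bounds <- c(0, cuts, glen)
    ex_start <- bounds[seq(1, 2 * n_ex - 1, by = 2)]
    ex_end <- bounds[seq(2, 2 * n_ex, by = 2)]
    gid <- sprintf("gene_%03d", i)
    genes[[i]] <- data.frame(
      gene_id = gid, chrom = chrom, start = gstart, end = gstart + glen,
      strand = strand,
      tss = if (strand == "+") gstart else gstart + glen - 1L,
      stringsAsFactors = FALSE
    )
    exons[[i]] <- data.frame(gene_id = gid, chrom = chrom,
                             start = gstart + ex_start,
                             end = gstart + ex_end,
                             stringsAsFactors = FALSE)
  }
  list(sequence = seq, genes = do.call(rbind, genes),
       exons = do.call(rbind, exons))
}

#' Generate orthologous sequences with exactly conserved blocks
#'
#' Derives `n_species` orthologs of a reference enhancer by independent
#' per-base substitution at `mut_rate` outside a set of disjoint conserved
#' blocks, which are copied exactly. No indels are introduced, so block
#' coordinates are shared by all species.
#'
#' @param ref_enhancer reference sequence (character string, ACGT).
#' @param n_species number of orthologs to generate.
#' @param conserved_blocks data.frame with `start`, `end` (0-based
#'   half-open, disjoint) or NULL/empty for none.
#' @param mut_rate substitution probability per base outside blocks,
#'   in \[0, 1).
#' @param seed integer RNG seed.
#' @return list: `sequences` (named character vector of length
#'   `n_species`), `blocks` (the conserved-block coordinates, as given).
#' @export
make_orthologs <- function(ref_enhancer, n_species, conserved_blocks = NULL,
                           mut_rate = 0.1, seed = 1L) {
  stopifnot(mut_rate >= 0, mut_rate < 1, n_species >= 1)
  L <- nchar(ref_enhancer)
  blocks <- conserved_blocks
  if (is.null(blocks) || !nrow(as.data.frame(blocks))) {
    blocks <- data.frame(start = integer(), end = integer())
  }
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  if (nrow(blocks)) {
    if (any(blocks$start < 0 | blocks$end > L | blocks$start >= blocks$end)) {
      stop("conserved blocks must be subintervals of the reference")
    }
    if (nrow(blocks) > 1 &&
        any(blocks$start[-1] < blocks$end[-nrow(blocks)])) {
      stop("conserved blocks must be disjoint")
    }
  }
  protected <- rep(FALSE, L)
  for (b in seq_len(nrow(blocks))) {
    protected[(blocks$start[b] + 1):blocks$end[b]] <- TRUE
  }
  set.seed(seed)
  ref <- strsplit(ref_enhancer, "")[[1]]
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n_species), function(sp) {
    mut <- ref
    hit <- which(!protected & runif(L) < mut_rate)
    if (length(hit)) {
      mut[hit] <- vapply(mut[hit], function(b) {
        sample(setdiff(bases, b), 1)
      }, character(1))
    }
    paste(mut, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("species_%d", seq_len(n_species))
  list(sequences = seqs, blocks = blocks)
}
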