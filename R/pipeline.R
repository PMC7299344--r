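# End-to-end pipeline: simulate (optional) -> atlas -> counts -> three
# differential contrasts -> DRMS classification -> annotation -> motif
# screen, with a YAML config, per-stage seeds derived from one root seed,
# and a machine-readable run manifest.

#' Default pipeline configuration
#'
#' Defaults mirror the analysis parameters the pipeline is built around:
#' top 11,500 peaks per condition pooled into the union set, differential
#' calls at `padj < 0.1` and `|log2FC| > 0.5` (with `padj < 0.05` kept as
#' the stricter companion cutoff), and the three standard contrasts
#' (early damaged vs early undamaged; late damaged vs late undamaged;
#' late damaged vs early damaged).
#'
#' @param seed root seed; stage seeds are derived from it.
#' @return nested list of configuration values.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    n_top = 11500,
    padj_cuts = c(strict = 0.05, standard = 0.1),
    lfc_cut = 0.5,
    chroms = NULL,
    bin_size = 10,
    motifs = as.list(default_motifs()),
    simulate = list(n_peaks = 5000, n_replicates = 3,
                    dilution_fraction = 0.15, dispersion = 0.05,
                    base_mean = 200, effect_lfc = 4, silence_lfc = 2)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override [default_config()]; everything else
#' keeps its default.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- modifyList(default_config(), user)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

stage_seed <- function(root_seed, stage) {
  offsets <- c(simulate = 101, atlas = 211, counts = 307, diff = 401,
               classify = 503, annotate = 601, motifs = 701)
  as.integer((as.numeric(root_seed) * 1000 + offsets[[stage]]) %%
               2147483647)
}

#' Run the full DRMS discovery pipeline on synthetic data
#'
#' Executes every stage against a simulated study: generates truth, scored
#' peak sets and counts from the config's `simulate` block, builds the
#' union atlas, transfers counts onto atlas peaks, runs the three standard
#' contrasts, classifies DRMS peaks at both configured padj cutoffs,
#' annotates atlas peaks with nearest genes and feature categories, scans a
#' planted enhancer sequence for the configured motifs, and writes all
#' outputs plus a JSON manifest (config, seeds, and an md5 digest per
#' output file) into `out_dir`.
#'
#' @param config configuration list from [default_config()] or
#'   [read_config()], or a path to a YAML config file.
#' @param out_dir output directory (created; must not require intermediate
#'   missing parents).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- read_config(config)
  }
  stopifnot(is.list(config), !missing(out_dir))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- simulate -------------------------------------------------------
  simcfg <- config$simulate
  design <- do.call(sim_design, c(simcfg,
                                  list(seed = stage_seed(config$seed,
                                                         "simulate"))))
  truth <- simulate_truth(design)
  sim <- simulate_counts(design, truth)
  n_top_eff <- min(config$n_top, nrow(truth))
  peak_sets <- simulate_scored_peaks(truth, design, n_top_pool = n_top_eff)

  # --- atlas ----------------------------------------------------------
  atlas <- build_atlas(peak_sets, n_top = n_top_eff,
                       chroms = config$chroms)

  # --- counts: transfer simulated truth-peak counts onto atlas peaks ---
  counts <- map_counts_to_atlas(atlas, truth, sim$counts)

  # --- differential: the three standard contrasts ---------------------
  contrasts <- list(
    dr_early = list(numerator = c("earlyL3", "damaged"),
                    denominator = c("earlyL3", "undamaged")),
    dr_late = list(numerator = c("lateL3", "damaged"),
                   denominator = c("lateL3", "undamaged")),
    maturity = list(numerator = c("lateL3", "damaged"),
                    denominator = c("earlyL3", "damaged"))
  )
  sf <- size_factors(counts)
  diffs <- lapply(contrasts, function(ct) {
    nb_wald_test(counts, sim$design_table, contrast = ct, sf = sf)
  })

  # --- classify at each configured padj cutoff ------------------------
  callsets <- lapply(config$padj_cuts, function(cut) {
    classify_drms(
      dr_early = call_set(diffs$dr_early, "up", cut, config$lfc_cut),
      dr_late = call_set(diffs$dr_late, "up", cut, config$lfc_cut),
      ms = call_set(diffs$maturity, "down", cut, config$lfc_cut),
      thresholds = list(padj_cut = cut, lfc_cut = config$lfc_cut,
                        ms_contrast = "lateL3_damaged vs earlyL3_damaged")
    )
  })

  # --- annotate -------------------------------------------------------
  genome <- make_genome(seed = stage_seed(config$seed, "annotate"),
                        length = 2e6, gene_count = 40)
  anno_peaks <- atlas[atlas$end <= 2e6, , drop = FALSE]
  anno_peaks$chrom <- genome$genes$chrom[1]
  nearest <- annotate_nearest_genes(anno_peaks, genome$genes)
  cmap <- build_category_map(genome$genes, genome$exons)
  categories <- data.frame(peak_id = anno_peaks$peak_id,
                           category = categorize_peak(anno_peaks, cmap),
                           stringsAsFactors = FALSE)

  # --- motifs ---------------------------------------------------------
  set.seed(stage_seed(config$seed, "motifs"))
  enhancer <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                    collapse = "")
  sites <- site_map_report(enhancer, unlist(config$motifs))

  # --- outputs + manifest ---------------------------------------------
  paths <- list(
    atlas = file.path(out_dir, "atlas.bed"),
    counts = file.path(out_dir, "counts.tsv"),
    design = file.path(out_dir, "design.tsv"),
    sites = file.path(out_dir, "motif_sites.tsv")
  )
  atlas_out <- atlas
  atlas_out$name <- atlas_out$peak_id
  write_bed_peaks(atlas_out[, c("chrom", "start", "end", "name")],
                  paths$atlas)
  write_count_matrix(counts, sim$design_table, paths$counts, paths$design)
  write.table(sites, paths$sites, sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (nm in names(diffs)) {
    p <- file.path(out_dir, sprintf("diff_%s.tsv", nm))
    write.table(diffs[[nm]], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths[[paste0("diff_", nm)]] <- p
  }
  for (nm in names(callsets)) {
    tsv <- file.path(out_dir, sprintf("callset_%s.tsv", nm))
    js <- file.path(out_dir, sprintf("callset_%s.json", nm))
    write_callset(callsets[[nm]], tsv, js)
    paths[[paste0("callset_", nm)]] <- tsv
    paths[[paste0("callset_", nm, "_json")]] <- js
  }
  digests <- vapply(paths, function(p) unname(tools::md5sum(p)),
                    character(1))
  manifest <- list(
    config = config,
    stage_seeds = lapply(setNames(nm = c("simulate", "atlas", "counts",
                                         "diff", "classify", "annotate",
                                         "motifs")),
                         function(s) stage_seed(config$seed, s)),
    outputs = as.list(digests)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(design = design, truth = truth, sim = sim, atlas = atlas,
                 counts = counts, diffs = diffs, callsets = callsets,
                 nearest = nearest, categories = categories,
                 sites = sites, manifest = manifest))
}

#' Transfer per-truth-peak counts onto atlas peaks
#'
#' Each atlas peak receives the summed counts of the truth peaks it
#' overlaps by >= 1 bp (a merged atlas peak spanning several simulated
#' peaks accumulates all of them); atlas peaks overlapping none (pure
#' noise-peak regions) get zeros.
#'
#' @param atlas a `peak_atlas`.
#' @param truth a `sim_truth` data.frame (carries truth peak coordinates).
#' @param counts truth-peak x sample count matrix.
#' @return integer matrix, atlas peaks x samples.
#' @export
map_counts_to_atlas <- function(atlas, truth, counts) {
  agr <- intervals_to_granges(atlas[, c("chrom", "start", "end")])
  tgr <- intervals_to_granges(truth[, c("chrom", "start", "end")])
  hits <- GenomicRanges::findOverlaps(agr, tgr, minoverlap = 1L)
  out <- matrix(0L, nrow = nrow(atlas), ncol = ncol(counts),
                dimnames = list(atlas$peak_id, colnames(counts)))
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    agg <- rowsum(counts[sh, , drop = FALSE], group = qh)
    out[as.integer(rownames(agg)), ] <- as.integer(agg)
  }
  out
}
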