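mk_genes <- function(start, end, strand = NULL, chrom = "chr1") {
  n <- length(start)
  if (is.null(strand)) strand <- rep("+", n)
  data.frame(gene_id = sprintf("g%02d", seq_len(n)), chrom = chrom,
             start = start, end = end, strand = strand,
             tss = ifelse(strand == "+", start, end - 1L),
             stringsAsFactors = FALSE)
}

test_that("nearest_two_genes ranks by gap distance with overlap as
          zero", {
  genes <- mk_genes(start = c(100, 700, 6000), end = c(300, 900, 7000))
  peak <- data.frame(chrom = "chr1", start = 150, end = 200)
  hit <- nearest_two_genes(peak, genes)
  expect_equal(hit$gene_id, c("g01", "g02"))
  expect_equal(hit$distance, c(0L, 500L))
  # single gene on the chromosome: length-1 answer
  one <- nearest_two_genes(peak, genes[1, ])
  expect_equal(nrow(one), 1)
  expect_warning(
    none <- nearest_two_genes(data.frame(chrom = "chrX", start = 0,
                                         end = 10), genes),
    "no genes")
  expect_equal(nrow(none), 0)
})

test_that("nearest gene annotation is strand-invariant and matches the
          brute-force scan", {
  set.seed(61)
  genes <- mk_genes(start = cumsum(sample(200:800, 50)),
                    end = integer(50))
  genes$end <- genes$start + sample(100:400, 50, replace = TRUE)
  genes$strand <- sample(c("+", "-"), 50, replace = TRUE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  peaks <- random_intervals(200, chroms = "chr1", max_pos = 30000,
                            max_width = 300)
  for (i in seq_len(nrow(peaks))) {
    got <- nearest_two_genes(peaks[i, ], genes)
    want <- oracle_nearest_two(peaks[i, ], genes)
    expect_equal(got$gene_id, want$gene_id)
    expect_equal(got$distance, want$distance)
  }
  flipped <- genes
  flipped$strand <- ifelse(genes$strand == "+", "-", "+")
  flipped$tss <- ifelse(flipped$strand == "+", flipped$start,
                        flipped$end - 1L)
  p1 <- peaks[1, ]
  expect_equal(nearest_two_genes(p1, genes)$gene_id,
               nearest_two_genes(p1, flipped)$gene_id)
  # TSS mode measures to the start site, not the gene body
  g <- mk_genes(start = 1000, end = 2000)
  pk <- data.frame(chrom = "chr1", start = 1500, end = 1600)
  expect_equal(nearest_two_genes(pk, g)$distance, 0L)
  expect_equal(nearest_two_genes(pk, g, mode = "tss")$distance, 499L)
})

test_that("per-side mode returns the closest gene on each flank", {
  genes <- mk_genes(start = c(0, 300, 5000), end = c(100, 400, 6000))
  peak <- data.frame(chrom = "chr1", start = 450, end = 500)
  both <- nearest_two_genes(peak, genes)
  expect_equal(both$gene_id, c("g02", "g01"))
  sided <- nearest_two_genes(peak, genes, per_side = TRUE)
  expect_setequal(sided$gene_id, c("g02", "g03"))
})

test_that("peak categorization follows midpoint precedence and matches a
          direct lookup", {
  map <- data.frame(
    chrom = "chr1",
    start = c(0, 50, 200, 400),
    end = c(100, 150, 300, 500),
    category = c("active_promoter", "active_exon", "active_intron",
                 "other_open_chromatin"),
    stringsAsFactors = FALSE
  )
  peaks <- data.frame(chrom = "chr1",
                      start = c(60, 240, 440, 800),
                      end = c(80, 260, 460, 820))
  expect_equal(categorize_peak(peaks, map),
               c("active_promoter", "active_intron",
                 "other_open_chromatin", "other"))
  # midpoint in overlapping promoter+exon resolves to promoter
  ov <- data.frame(chrom = "chr1", start = 60, end = 90)
  expect_equal(categorize_peak(ov, map), "active_promoter")
  # random peaks equal a brute-force midpoint lookup
  set.seed(67)
  rnd <- random_intervals(150, chroms = "chr1", max_pos = 900,
                          max_width = 80)
  got <- categorize_peak(rnd, map)
  prec <- c("active_promoter", "active_exon", "active_intron",
            "other_open_chromatin", "other")
  want <- vapply(seq_len(nrow(rnd)), function(i) {
    mid <- floor((rnd$start[i] + rnd$end[i]) / 2)
    inside <- map$start <= mid & mid < map$end
    if (!any(inside)) "other" else
      prec[min(match(map$category[inside], prec))]
  }, character(1))
  expect_equal(got, want)
})

test_that("category maps built from gene models label promoters, exons
          and introns with promoter precedence at the TSS", {
  g <- make_genome(seed = 5, length = 200000, gene_count = 10)
  cmap <- build_category_map(g$genes, g$exons, promoter_window = 250)
  expect_true(all(cmap$category %in%
                    c("active_promoter", "active_exon", "active_intron")))
  # a peak centered on a TSS is a promoter even though exon 1 covers it
  gene1 <- g$genes[1, ]
  pk <- data.frame(chrom = gene1$chrom, start = gene1$tss - 10,
                   end = gene1$tss + 10)
  expect_equal(categorize_peak(pk, cmap), "active_promoter")
  # intergenic midpoint falls through to "other"
  far <- data.frame(chrom = gene1$chrom, start = 0, end = 2)
  expect_true(categorize_peak(far, cmap) %in%
                c("other", "active_promoter"))
})

test_that("category enrichment reports fisher-exact p-values and folds
          whose background-weighted mean is one", {
  map <- data.frame(chrom = "chr1", start = c(0, 1000), end = c(500, 1500),
                    category = c("active_intron", "other_open_chromatin"),
                    stringsAsFactors = FALSE)
  set.seed(71)
  bg <- random_intervals(100, chroms = "chr1", max_pos = 1900,
                         max_width = 40)
  bg$peak_id <- sprintf("b%03d", seq_len(nrow(bg)))
  sub <- bg[1:20, ]
  enr <- category_enrichment(sub, bg, map)
  expect_equal(enr$category,
               c("active_promoter", "active_exon", "active_intron",
                 "other_open_chromatin", "other"))
  # empty-in-background categories report NA fold
  expect_true(is.na(enr$fold[enr$category == "active_promoter"]))
  ok <- !is.na(enr$fold)
  w <- enr$n_background[ok] / sum(enr$n_background[ok])
  expect_equal(sum(enr$fold[ok] * w), 1, tolerance = 1e-12)
  # p-value equals the direct fisher test of the 2x2 table
  a <- enr$n_subset[3]; b <- enr$n_background[3]
  tab <- matrix(c(a, 20 - a, b - a, 80 - (b - a)), 2)
  expect_equal(enr$pvalue[3], fisher.test(tab)$p.value)
  expect_error(category_enrichment(
    data.frame(chrom = "chr1", start = 0, end = 10, peak_id = "zzz"),
    bg, map), "contained")
})

test_that("uniformly drawn subsets are almost never called enriched", {
  map <- data.frame(chrom = "chr1",
                    start = c(0, 500, 1000, 1500),
                    end = c(400, 900, 1400, 1900),
                    category = c("active_promoter", "active_exon",
                                 "active_intron", "other_open_chromatin"),
                    stringsAsFactors = FALSE)
  set.seed(73)
  bg <- random_intervals(300, chroms = "chr1", max_pos = 2200,
                         max_width = 30)
  bg$peak_id <- sprintf("b%03d", seq_len(nrow(bg)))
  n_sig <- 0L
  for (s in 1:100) {
    sub <- bg[sample(nrow(bg), 30), ]
    enr <- category_enrichment(sub, bg, map)
    if (any(enr$padj < 0.05, na.rm = TRUE)) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 5)
})

test_that("annotate_nearest_genes tabulates one row per (peak, rank)", {
  genes <- mk_genes(start = c(100, 700), end = c(300, 900))
  peaks <- data.frame(chrom = "chr1", start = c(0, 1000),
                      end = c(50, 1100),
                      peak_id = c("pkA", "pkB"),
                      stringsAsFactors = FALSE)
  tab <- annotate_nearest_genes(peaks, genes)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$gene_id[tab$peak_id == "pkB" & tab$rank == 1], "g02")
})
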