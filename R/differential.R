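# Differential accessibility: median-of-ratios normalization, replicate
# QC, method-of-moments dispersion with a trend shrink, and a
# negative-binomial Wald test per atlas peak with Benjamini-Hochberg
# correction. This engine is a transparent, self-contained analogue of the
# standard NB differential frameworks: it shares their model (variance
# m + alpha * m^2) but uses closed-form estimators throughout, so every
# number it produces can be re-derived by hand.

#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over all-positive peaks of the
#' ratio of the sample's count to the peak's geometric mean across samples.
#' If no peak is positive in every sample, falls back to total-count ratios
#' (column sum over geometric mean of column sums) with a warning.
#'
#' @param counts integer matrix, peaks x samples.
#' @return positive numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 1)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no peak has positive counts in all samples; ",
            "using total-count ratios")
    tot <- colSums(counts)
    return(tot / exp(mean(log(tot))))
  }
  lc <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lc)
  apply(lc, 2, function(col) exp(median(col - geo)))
}

#' Counts-per-million normalization
#'
#' @param counts integer matrix, peaks x samples.
#' @return numeric matrix: `counts * 1e6 / colSums(counts)`.
#' @export
cpm_normalize <- function(counts) {
  tot <- colSums(counts)
  zero <- names(tot)[tot == 0]
  if (any(tot == 0)) {
    stop("sample(s) with zero total counts: ", paste(zero, collapse = ", "))
  }
  sweep(counts, 2, tot, "/") * 1e6
}

#' Sample-sample Pearson correlation of a normalized matrix
#'
#' Used for replicate concordance QC; with a realistic peak-mean dynamic
#' range, biological replicates of the same condition correlate strongly
#' and samples cluster by condition.
#'
#' @param normalized numeric matrix, peaks x samples (e.g. CPM).
#' @param order_by_clustering reorder rows/columns by hierarchical
#'   clustering of `1 - r` for display.
#' @return symmetric sample x sample correlation matrix with unit diagonal;
#'   correlations against constant samples are `NA`.
#' @export
replicate_correlation <- function(normalized, order_by_clustering = FALSE) {
  stopifnot(ncol(normalized) >= 2)
  r <- suppressWarnings(cor(normalized, method = "pearson"))
  diag(r) <- 1
  if (order_by_clustering && !anyNA(r)) {
    ord <- stats::hclust(stats::as.dist(1 - r))$order
    r <- r[ord, ord]
  }
  r
}

#' Per-peak dispersion by method of moments with trend shrinkage
#'
#' Within each condition group with >= 2 replicates, computes the
#' method-of-moments dispersion `(s^2 - m) / m^2` on size-factor-normalized
#' counts, pools estimates across groups (weighted by residual degrees of
#' freedom), clamps at 0, fits the mean-dispersion trend
#' `alpha(mu) = a0 + a1 / mu` by least squares, and shrinks each raw
#' estimate halfway toward the fitted trend.
#'
#' @param counts integer matrix, peaks x samples.
#' @param design_table data.frame with `sample`, `stage`, `damage` matching
#'   the columns of `counts`.
#' @param sf optional size factors; estimated by [size_factors()] when
#'   omitted.
#' @return data.frame: `peak_id`, `base_mean` (mean normalized count),
#'   `alpha_raw`, `alpha_trend`, `alpha` (the shrunk estimate; `NA` for
#'   all-zero peaks, which are flagged in `excluded`), `excluded`.
#' @export
estimate_dispersion <- function(counts, design_table, sf = NULL) {
  stopifnot(identical(colnames(counts), design_table$sample))
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  group <- paste(design_table$stage, design_table$damage, sep = "_")
  num <- den <- rep(0, nrow(counts))
  for (g in unique(group)) {
    j <- which(group == g)
    if (length(j) < 2) next
    m <- rowMeans(norm[, j, drop = FALSE])
    v <- apply(norm[, j, drop = FALSE], 1, var)
    a <- (v - m) / m^2
    ok <- m > 0
    w <- length(j) - 1
    num[ok] <- num[ok] + w * a[ok]
    den[ok] <- den[ok] + w
  }
  if (all(den == 0)) stop("need >= 2 replicates in at least one condition")
  alpha_raw <- ifelse(den > 0, pmax(0, num / pmax(den, 1)), NA_real_)
  base_mean <- rowMeans(norm)
  excluded <- rowSums(counts) == 0
  alpha_raw[excluded] <- NA_real_
  # trend alpha(mu) = a0 + a1/mu on peaks with usable raw estimates
  use <- !is.na(alpha_raw) & base_mean > 0
  fit <- lm(alpha_raw[use] ~ I(1 / base_mean[use]))
  a0 <- max(coef(fit)[1], 0)
  a1 <- max(coef(fit)[2], 0)
  alpha_trend <- ifelse(base_mean > 0, a0 + a1 / base_mean, NA_real_)
  alpha <- 0.5 * alpha_raw + 0.5 * alpha_trend
  alpha[excluded] <- NA_real_
  data.frame(
    peak_id = rownames(counts), base_mean = base_mean,
    alpha_raw = alpha_raw, alpha_trend = alpha_trend, alpha = alpha,
    excluded = excluded, stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement: for p-values
#' ranked ascending, `padj_(i) = min_{k >= i} p_(k) * m / k`, capped at 1.
#' `NA` inputs propagate to `NA` and do not count toward `m`.
#'
#' @param pvalues numeric vector in \[0, 1\] (NAs allowed).
#' @return adjusted p-values, same order and length as the input.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(pvalues))
  p <- pvalues[ok]
  m <- length(p)
  if (m) {
    ord <- order(p)
    ranked <- p[ord] * m / seq_len(m)
    adj <- rev(cummin(rev(ranked)))
    adj <- pmin(adj, 1)
    res <- numeric(m)
    res[ord] <- adj
    out[ok] <- res
  }
  out
}

#' Negative-binomial Wald test for one contrast
#'
#' For each atlas peak, estimates the log2 fold change between two condition
#' groups as the log2 ratio of size-factor-normalized group means (with a
#' pseudo-mean of `pseudo` normalized counts added to each group mean to
#' stabilize zeros). The standard error comes from the NB delta method:
#' `Var(log mean_g) ~ (1 / m_g + alpha) / n_g` per group, so
#' `SE = sqrt(sum_g (1/m_g + alpha) / n_g) / log(2)`. The Wald statistic
#' `log2FC / SE` is referred to the standard normal (two-sided), and
#' p-values are BH-adjusted across all tested peaks. Peaks with zero counts
#' everywhere are excluded (`NA` statistics).
#'
#' @param counts integer matrix, peaks x samples.
#' @param design_table data.frame with `sample`, `stage`, `damage`.
#' @param contrast list with `numerator` and `denominator`, each
#'   `c(stage, damage)`; `log2FC > 0` means more accessible in the
#'   numerator condition.
#' @param sf optional size factors (estimated when omitted).
#' @param dispersion optional per-peak dispersion vector (recycled scalar
#'   allowed); estimated by [estimate_dispersion()] when omitted.
#' @param pseudo pseudo-mean added to each group mean (normalized counts).
#' @return a `diff_result` data.frame: `peak_id`, `base_mean`, `log2fc`,
#'   `se`, `stat`, `pvalue`, `padj`, plus the contrast as attributes.
#' @export
nb_wald_test <- function(counts, design_table, contrast, sf = NULL,
                         dispersion = NULL, pseudo = 0.5) {
  stopifnot(identical(colnames(counts), design_table$sample))
  if (!is.list(contrast) ||
      !all(c("numerator", "denominator") %in% names(contrast))) {
    stop("contrast must be list(numerator = c(stage, damage), ",
         "denominator = c(stage, damage))")
  }
  group <- paste(design_table$stage, design_table$damage, sep = "_")
  g_num <- paste(contrast$numerator, collapse = "_")
  g_den <- paste(contrast$denominator, collapse = "_")
  j_num <- which(group == g_num)
  j_den <- which(group == g_den)
  if (!length(j_num) || !length(j_den)) {
    stop("contrast group absent from design: ",
         if (!length(j_num)) g_num else g_den)
  }
  if (length(j_num) < 2 || length(j_den) < 2) {
    stop("both contrast groups need >= 2 samples")
  }
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(counts, design_table, sf = sf)$alpha
  }
  alpha <- rep_len(dispersion, nrow(counts))
  m_num <- rowMeans(norm[, j_num, drop = FALSE]) + pseudo
  m_den <- rowMeans(norm[, j_den, drop = FALSE]) + pseudo
  log2fc <- log2(m_num / m_den)
  se <- sqrt((1 / m_num + alpha) / length(j_num) +
             (1 / m_den + alpha) / length(j_den)) / log(2)
  stat <- log2fc / se
  pvalue <- 2 * pnorm(-abs(stat))
  excluded <- rowSums(counts) == 0 | is.na(alpha)
  log2fc[excluded] <- se[excluded] <- stat[excluded] <- NA_real_
  pvalue[excluded] <- NA_real_
  res <- data.frame(
    peak_id = rownames(counts), base_mean = rowMeans(norm),
    log2fc = log2fc, se = se, stat = stat, pvalue = pvalue,
    padj = bh_adjust(pvalue), stringsAsFactors = FALSE, row.names = NULL
  )
  attr(res, "contrast") <- c(numerator = g_num, denominator = g_den)
  class(res) <- c("diff_result", "data.frame")
  res
}
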