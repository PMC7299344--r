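# Shared synthetic fixture for this file: the default four-condition,
# three-replicate design at a reduced peak count.
diff_fixture <- local({
  d <- sim_design(n_peaks = 3000, seed = 17)
  simulate_counts(d)
})

test_that("median-of-ratios size factors recover relative depth", {
  m <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), ncol = 2,
              dimnames = list(paste0("p", 1:3), c("a", "b")))
  expect_equal(size_factors(m), c(a = 1, b = 1))
  m2 <- cbind(a = c(10L, 20L, 30L), b = c(20L, 40L, 60L))
  sf <- size_factors(m2)
  expect_equal(unname(sf["b"] / sf["a"]), 2)
  # scaling one sample by c scales its factor relative to the others by c
  # (the geometric-mean reference absorbs a c^(1/m) factor itself)
  set.seed(1)
  m3 <- matrix(rpois(300, 50) + 1L, ncol = 3)
  sf3 <- size_factors(m3)
  m3c <- m3
  m3c[, 2] <- m3c[, 2] * 3L
  sf3c <- size_factors(m3c)
  expect_equal((sf3c[2] / sf3c[1]) / (sf3[2] / sf3[1]), 3,
               tolerance = 1e-12)
  # no all-positive row: falls back to totals with a warning
  m4 <- cbind(a = c(0L, 5L), b = c(5L, 0L))
  expect_warning(sf4 <- size_factors(m4), "total-count")
  expect_true(all(sf4 > 0))
  # simulated log-normal depths are recovered almost exactly
  sf_hat <- size_factors(diff_fixture$counts)
  expect_gt(cor(sf_hat, diff_fixture$depth_factors), 0.99)
})

test_that("CPM columns sum to one million and zero-depth samples are
          rejected by name", {
  m <- matrix(c(10L, 0L), ncol = 2, dimnames = list("p1", c("a", "b")))
  expect_error(cpm_normalize(m), "b")
  one <- matrix(10L, 1, 1, dimnames = list("p1", "a"))
  expect_equal(unname(cpm_normalize(one)[1, 1]), 1e6)
  cpm <- cpm_normalize(diff_fixture$counts)
  expect_equal(unname(colSums(cpm)), rep(1e6, ncol(cpm)))
})

test_that("replicates correlate strongly on CPM and samples cluster by
          stage before damage", {
  cpm <- cpm_normalize(diff_fixture$counts)
  r <- replicate_correlation(cpm)
  expect_true(isSymmetric(r))
  expect_equal(unname(diag(r)), rep(1, ncol(cpm)))
  dup <- replicate_correlation(cbind(a = cpm[, 1], b = cpm[, 1]))
  expect_equal(dup["a", "b"], 1)
  dt <- diff_fixture$design_table
  same_cond <- outer(dt$stage, dt$stage, "==") &
    outer(dt$damage, dt$damage, "==")
  same_stage <- outer(dt$stage, dt$stage, "==")
  off <- !diag(ncol(r))
  expect_gt(min(r[same_cond & off]), 0.9)
  expect_gt(mean(r[same_stage & off]), mean(r[!same_stage]))
})

test_that("dispersion estimation recovers the simulated value and is zero
          for replicate-constant counts", {
  disp <- estimate_dispersion(diff_fixture$counts,
                              diff_fixture$design_table)
  expect_true(all(disp$alpha[!disp$excluded] >= 0, na.rm = TRUE))
  expect_gt(median(disp$alpha, na.rm = TRUE), 0.02)
  expect_lt(median(disp$alpha, na.rm = TRUE), 0.10)
  # constant counts across replicates: raw MoM clamps to zero
  m <- matrix(50L, nrow = 4, ncol = 6,
              dimnames = list(paste0("p", 1:4), paste0("s", 1:6)))
  dt <- data.frame(sample = paste0("s", 1:6),
                   stage = rep("earlyL3", 6),
                   damage = rep(c("damaged", "undamaged"), each = 3),
                   replicate = rep(1:3, 2))
  d0 <- estimate_dispersion(m, dt, sf = rep(1, 6))
  expect_equal(d0$alpha_raw, rep(0, 4))
  # Poisson counts: median estimate near zero
  set.seed(31)
  mp <- matrix(rpois(4000 * 6, 200), ncol = 6,
               dimnames = list(paste0("p", 1:4000), paste0("s", 1:6)))
  dp <- estimate_dispersion(mp, dt, sf = rep(1, 6))
  expect_lt(median(dp$alpha_raw), 0.01)
})

test_that("BH adjustment matches the hand computation and the stats
          reference on random inputs", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(19)
  for (rep in 1:100) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"))
  }
  # order invariance and monotonicity in p
  p <- runif(30)
  perm <- sample(30)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  # NAs pass through without affecting the rest
  pna <- c(0.01, NA, 0.04)
  expect_equal(bh_adjust(pna), p.adjust(pna, method = "BH"))
})

test_that("the NB Wald test recovers planted fold changes and reports no
          effect for identical groups", {
  dt <- data.frame(sample = paste0("s", 1:6),
                   stage = rep("earlyL3", 6),
                   damage = rep(c("damaged", "undamaged"), each = 3),
                   replicate = rep(1:3, 2))
  set.seed(23)
  n <- 500
  cts <- cbind(
    sapply(1:3, function(j) rnbinom(n, mu = 400, size = 20)),
    sapply(1:3, function(j) rnbinom(n, mu = 200, size = 20))
  )
  storage.mode(cts) <- "integer"
  dimnames(cts) <- list(paste0("p", 1:n), dt$sample)
  res <- nb_wald_test(cts, dt,
                      list(numerator = c("earlyL3", "damaged"),
                           denominator = c("earlyL3", "undamaged")),
                      sf = rep(1, 6), dispersion = 0.05)
  expect_equal(mean(res$log2fc), 1, tolerance = 0.2)
  expect_true(all(res$padj >= res$pvalue, na.rm = TRUE))
  # identical group means at tiny dispersion: log2FC concentrates at 0
  cts0 <- cbind(
    sapply(1:3, function(j) rnbinom(n, mu = 5000, size = 1e4)),
    sapply(1:3, function(j) rnbinom(n, mu = 5000, size = 1e4))
  )
  storage.mode(cts0) <- "integer"
  dimnames(cts0) <- list(paste0("p", 1:n), dt$sample)
  res0 <- nb_wald_test(cts0, dt,
                       list(numerator = c("earlyL3", "damaged"),
                            denominator = c("earlyL3", "undamaged")),
                       sf = rep(1, 6), dispersion = 1e-4)
  expect_lt(max(abs(res0$log2fc)), 0.1)
  # contrast validation
  expect_error(
    nb_wald_test(cts, dt, list(numerator = c("lateL3", "damaged"),
                               denominator = c("earlyL3", "undamaged"))),
    "absent")
  # all-zero peaks are excluded with NA statistics
  ctsz <- cts
  ctsz[1, ] <- 0L
  resz <- nb_wald_test(ctsz, dt,
                       list(numerator = c("earlyL3", "damaged"),
                            denominator = c("earlyL3", "undamaged")),
                       sf = rep(1, 6), dispersion = 0.05)
  expect_true(is.na(resz$padj[1]))
})

test_that("detection power rises with effect size and with the responding
          fraction", {
  power_at <- function(f, delta) {
    d <- sim_design(n_peaks = 1200, dilution_fraction = f,
                    effect_lfc = delta, seed = 29,
                    label_props = c(null = 0.75,
                                    damage_responsive_early = 0.25,
                                    damage_responsive_late = 0,
                                    damage_responsive_both = 0,
                                    maturity_silenced = 0, drms = 0))
    sim <- simulate_counts(d)
    res <- nb_wald_test(sim$counts, sim$design_table,
                        list(numerator = c("earlyL3", "damaged"),
                             denominator = c("earlyL3", "undamaged")))
    called <- call_set(res, "up", 0.1, 0.5)
    planted <- sim$truth$peak_id[sim$truth$label != "null"]
    mean(planted %in% called)
  }
  p_delta <- c(power_at(1, 0.5), power_at(1, 2), power_at(1, 4))
  expect_true(all(diff(p_delta) >= 0))
  p_f <- c(power_at(0.1, 3), power_at(0.5, 3), power_at(1, 3))
  expect_true(all(diff(p_f) >= 0))
})

test_that("z-score tracks standardize coverage and difference tracks
          highlight planted damage-responsive silencing", {
  chrlen <- c(chrT = 400L)
  # uniform coverage standardizes to zero everywhere
  unif <- data.frame(chrom = "chrT", start = seq(0, 390, 10),
                     end = seq(10, 400, 10))
  tz <- signal_track(unif, chrlen, bin_size = 10)
  expect_true(all(tz$z == 0))
  expect_true(all(subtract_tracks(tz, tz)$z == 0))
  # a peak covered only in "early damaged" shows up positive in both
  # difference tracks (vs early undamaged and vs late damaged)
  peak_frags <- data.frame(chrom = "chrT",
                           start = rep(c(100, 105, 110), 4),
                           end = rep(c(140, 145, 150), 4))
  bg <- data.frame(chrom = "chrT", start = c(300, 320), end = c(310, 330))
  t_ed <- signal_track(list(peak_frags, bg), chrlen, bin_size = 10)
  t_eu <- signal_track(bg, chrlen, bin_size = 10)
  t_ld <- signal_track(bg, chrlen, bin_size = 10)
  d1 <- subtract_tracks(t_ed, t_eu)
  d2 <- subtract_tracks(t_ed, t_ld)
  in_peak <- d1$start >= 100 & d1$end <= 150
  expect_true(all(d1$z[in_peak] > 0))
  expect_true(all(d2$z[in_peak] > 0))
  # mismatched binning is refused
  t5 <- signal_track(bg, chrlen, bin_size = 5)
  expect_error(subtract_tracks(t_ed, t5), "binned identically")
  # bedGraph round trip
  f <- tempfile(fileext = ".bedGraph")
  write_bedgraph(t_ed, f)
  back <- read.delim(f, skip = 1, header = FALSE)
  expect_equal(back$V4, t_ed$z, tolerance = 1e-6)
})
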