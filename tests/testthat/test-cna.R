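# Deterministic bin builder: exact counts, no sampling noise.
flat_bins <- function(n = 100, chrom = "chr1", tumor = 100, normal = 100,
                      gc = 0.45, bin = 1e5) {
  data.frame(chrom = chrom, start = (seq_len(n) - 1) * bin,
             end = seq_len(n) * bin, gc = gc,
             tumor_count = tumor, normal_count = normal,
             stringsAsFactors = FALSE)
}

test_that("logR recovers known coverage ratios", {
  b <- flat_bins(200)
  lr <- compute_logr(b)
  expect_true(all(abs(lr$logr) < 1e-9))
  # a chromosome at 1.5x coverage sits at log2(1.5)
  b2 <- rbind(flat_bins(400, "chr1"), flat_bins(100, "chr2", tumor = 150))
  lr2 <- compute_logr(b2)
  expect_equal(median(lr2$logr[lr2$chrom == "chr2"]), log2(1.5),
               tolerance = 1e-6)
  expect_lt(abs(median(lr2$logr[lr2$chrom == "chr1"])), 1e-6)
  # zero normal coverage is masked, not divided by
  b3 <- flat_bins(50)
  b3$normal_count[10] <- 0
  expect_true(is.na(compute_logr(b3)$logr[10]))
  expect_error(compute_logr(flat_bins(5)[, -4]), "missing")
})

test_that("a linear GC confound is removed by decile correction", {
  set.seed(18)
  n <- 600
  b <- flat_bins(n)
  b$gc <- runif(n, 0.35, 0.6)
  gcf <- 1 + 2 * (b$gc - 0.45)
  b$tumor_count <- round(100 * gcf)   # coverage linear in GC, no real CNA
  b$normal_count <- 100
  lr <- compute_logr(b)
  # corrected track is flat: spread well below the raw confound amplitude
  raw_spread <- diff(range(log2(gcf)))
  expect_lt(stats::sd(lr$logr), raw_spread / 8)
  expect_lt(abs(median(lr$logr)), 0.01)
})

# Brute-force optimal segmentation by exhaustive enumeration of
# changepoint sets (tiny tracks only).
brute_segment <- function(x, gamma, sigma2, k_min) {
  n <- length(x)
  best <- NULL; best_cost <- Inf
  all_cuts <- function(cuts) {
    bounds <- c(0, cuts, n)
    if (any(diff(bounds) < k_min)) return()
    cost <- gamma * sigma2 * length(cuts)
    for (k in seq_len(length(bounds) - 1)) {
      seg <- x[(bounds[k] + 1):bounds[k + 1]]
      cost <- cost + sum((seg - mean(seg))^2)
    }
    if (cost < best_cost) { best_cost <<- cost; best <<- bounds }
  }
  for (ncut in 0:(n - 1)) {
    if (ncut == 0) { all_cuts(integer(0)); next }
    cmb <- utils::combn(n - 1, ncut)
    for (j in seq_len(ncol(cmb))) all_cuts(cmb[, j])
  }
  best
}

test_that("the segmentation DP matches exhaustive search on tiny tracks", {
  set.seed(19)
  for (rep in 1:5) {
    x <- c(rnorm(sample(3:5, 1), 0, 0.1), rnorm(sample(3:5, 1), 1, 0.1),
           rnorm(sample(2:4, 1), -1, 0.1))
    sigma2 <- 0.01
    for (gamma in c(2, 10, 50)) {
      dp <- clonesel:::segment_one(x, gamma, sigma2, 2)
      bf <- brute_segment(x, gamma, sigma2, 2)
      expect_equal(dp, bf)
    }
  }
})

test_that("noiseless steps are recovered exactly and gamma is monotone", {
  b <- flat_bins(300)
  b$logr <- c(rep(0, 100), rep(0.585, 80), rep(0, 120))
  b$logr <- b$logr + rnorm(300, 0, 1e-4)  # noise floor for the scale estimate
  seg <- segment_logr(b, gamma = 30, k_min = 3)
  expect_equal(nrow(seg), 3)
  expect_equal(seg$start, c(0, 100, 180) * 1e5)
  expect_equal(seg$end, c(100, 180, 300) * 1e5)
  # large gamma collapses to one segment per chromosome
  set.seed(20)
  b$logr <- rnorm(300, 0, 0.2)
  segs <- vapply(c(10, 30, 50, 100), function(g)
    nrow(segment_logr(b, gamma = g, k_min = 3)), numeric(1))
  expect_true(all(diff(segs) <= 0))
  huge <- segment_logr(b, gamma = 1e6, k_min = 3)
  expect_equal(nrow(huge), 1)
  # a track shorter than k_min yields a single segment
  short <- flat_bins(2)
  short$logr <- c(0, 5)
  expect_equal(nrow(segment_logr(short, gamma = 10, k_min = 3)), 1)
})

test_that("gain/loss calling and the altered fraction are as defined", {
  seg <- data.frame(chrom = "chr1", start = c(0, 15e6), end = c(15e6, 150e6),
                    n_bins = c(150, 1350),
                    median_logr = c(0.585, 0.0), stringsAsFactors = FALSE)
  cs <- call_segments(seg)
  expect_equal(cs$segments$class, c("gain", "normal"))
  expect_equal(cs$fraction_altered, 15e6 / 150e6)
  zero <- transform(seg, median_logr = 0)
  expect_equal(call_segments(zero)$fraction_altered, 0)
  expect_error(call_segments(seg, gain_threshold = -0.1), "positive")
})

test_that("sweep metrics summarise length and class composition", {
  one <- data.frame(chrom = "chr1", start = 0, end = 200e6, n_bins = 2000,
                    median_logr = 0, class = "normal",
                    stringsAsFactors = FALSE)
  m <- sweep_metrics(list(a = one, b = one))
  expect_equal(m$pct_gt50mb, c(100, 100))
  tri <- data.frame(chrom = "chr1", start = c(0, 0.5e6, 5.5e6),
                    end = c(0.5e6, 5.5e6, 65.5e6), n_bins = 1,
                    median_logr = c(0.3, 0, -0.3),
                    class = c("gain", "normal", "loss"),
                    stringsAsFactors = FALSE)
  m2 <- sweep_metrics(list(a = tri, b = tri))
  tot <- 65.5e6
  expect_equal(m2$pct_lt1mb[1], 0.5e6 / tot * 100, tolerance = 1e-9)
  expect_equal(m2$pct_1_10mb[1], 5e6 / tot * 100, tolerance = 1e-9)
  expect_equal(m2$pct_gt50mb[1], 60e6 / tot * 100, tolerance = 1e-9)
  expect_equal(m2$pct_lt1mb + m2$pct_1_10mb + m2$pct_10_50mb + m2$pct_gt50mb,
               c(100, 100))
  expect_equal(m2$pct_gain + m2$pct_loss + m2$pct_normal, c(100, 100))
  expect_warning(sweep_metrics(list(a = tri, b = tri[0, ], c = tri)),
                 "empty")
  expect_error(sweep_metrics(list(a = tri)), "at least 2")
})

test_that("the full CNA chain recovers simulated chromosome-scale events", {
  set.seed(21)
  ev <- data.frame(chrom = c("chr2", "chr3"), start = c(0, 20e6),
                   end = c(15e6, 60e6), cn = c(3, 1),
                   stringsAsFactors = FALSE)
  bins <- simulate_coverage_bins(ev, purity = 0.8, base_depth = 400)
  lr <- compute_logr(bins)
  seg <- segment_logr(lr, gamma = 30, k_min = 3)
  cs <- call_segments(seg)
  gains <- cs$segments[cs$segments$class == "gain", ]
  losses <- cs$segments[cs$segments$class == "loss", ]
  expect_equal(nrow(gains), 1)
  expect_equal(nrow(losses), 1)
  # breakpoints within 2 bins of the planted events
  expect_lte(abs(gains$end - 15e6), 2e5)
  expect_lte(abs(losses$start - 20e6), 2e5)
  expect_equal(gains$chrom, "chr2")
  expect_equal(losses$chrom, "chr3")
})
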