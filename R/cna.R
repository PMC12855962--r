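# Copy-number analysis from binned coverage: GC-corrected log ratio of
# tumor to matched normal, exact penalized least-squares segmentation
# (penalty gamma per changepoint, scaled by a robust noise estimate),
# median-logR gain/loss calling, and the gamma/k_min parameter-sweep
# robustness metrics.

#' Compute the GC-corrected logR track
#'
#' logR is log2(tumor/normal) per bin, median-centred, then GC-corrected by
#' subtracting the median logR within GC deciles and re-centring. Bins with
#' zero normal coverage are masked (logR = NA).
#'
#' @param bins Data frame (chrom, start, end, gc, tumor_count,
#'   normal_count) on a single common bin grid; an error is raised if the
#'   tumor and normal columns come from different grids (here: any NA after
#'   merging).
#' @return The input with a \code{logr} column added (NA for masked bins).
#' @export
compute_logr <- function(bins) {
  stopifnot_cols(bins, c("chrom", "start", "end", "gc", "tumor_count",
                         "normal_count"), "bins")
  if (any(bins$end <= bins$start)) stop("malformed bin grid")
  lr <- rep(NA_real_, nrow(bins))
  ok <- bins$normal_count > 0 & bins$tumor_count > 0
  lr[ok] <- log2(bins$tumor_count[ok] / bins$normal_count[ok])
  lr <- lr - stats::median(lr, na.rm = TRUE)
  brk <- unique(stats::quantile(bins$gc, probs = seq(0, 1, 0.1), na.rm = TRUE))
  if (length(brk) > 2) {
    dec <- cut(bins$gc, breaks = brk, include.lowest = TRUE)
    med <- tapply(lr, dec, stats::median, na.rm = TRUE)
    lr <- lr - med[dec]
    lr <- lr - stats::median(lr, na.rm = TRUE)
  }
  bins$logr <- as.numeric(lr)
  bins
}

# Robust noise estimate: MAD of first differences over sqrt(2).
logr_noise_sd <- function(x) {
  d <- diff(x[!is.na(x)])
  if (length(d) < 2) return(0)
  stats::mad(d) / sqrt(2)
}

# Exact DP for one chromosome: minimize sum of within-segment squared
# deviations + gamma * sigma2 per changepoint, segments >= k_min bins.
segment_one <- function(x, gamma, sigma2, k_min) {
  n <- length(x)
  if (n < 2 * k_min) return(c(0L, n))  # single segment
  s1 <- c(0, cumsum(x)); s2 <- c(0, cumsum(x^2))
  pen <- gamma * sigma2
  dp <- rep(Inf, n + 1); dp[1] <- -pen  # first segment pays no penalty
  back <- integer(n + 1)
  for (j in seq_len(n)) {
    if (j < k_min) next
    i <- seq_len(j - k_min + 1)          # candidate segment starts (1-based)
    i <- i[j - i + 1 >= k_min]
    if (!length(i)) next
    len <- j - i + 1
    sse <- (s2[j + 1] - s2[i]) - (s1[j + 1] - s1[i])^2 / len
    tot <- dp[i] + sse + pen
    b <- which.min(tot)
    dp[j + 1] <- tot[b]
    back[j + 1] <- i[b] - 1L             # 0-based segment start
  }
  # recover breakpoints
  cuts <- integer(0)
  j <- n
  while (j > 0) {
    st <- back[j + 1]
    cuts <- c(st, cuts)
    j <- st
  }
  c(cuts, n)
}

#' Segment a logR track
#'
#' Exact dynamic-programming minimisation, per chromosome, of the within-
#' segment squared deviation plus a penalty of \code{gamma * sigma^2} per
#' changepoint, where sigma^2 is a robust (MAD of first differences) noise
#' estimate of the whole track. Segments have at least \code{k_min} bins.
#' Masked bins (NA logR) are skipped; each segment is summarised by its
#' median logR.
#'
#' @param bins Output of \code{\link{compute_logr}} (single sample).
#' @param gamma Penalty weight (>= 0); larger values give fewer segments.
#' @param k_min Minimum bins per segment (>= 1).
#' @return Data frame of unclassed segments: chrom, start, end (bp),
#'   n_bins, median_logr.
#' @export
segment_logr <- function(bins, gamma = 30, k_min = 3) {
  stopifnot_cols(bins, c("chrom", "start", "end", "logr"), "logr track")
  if (gamma < 0 || k_min < 1) stop("invalid segmentation parameters")
  sigma2 <- logr_noise_sd(bins$logr)^2
  if (sigma2 == 0) sigma2 <- 1e-8
  out <- list()
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch & !is.na(bins$logr), , drop = FALSE]
    if (!nrow(b)) next
    cuts <- segment_one(b$logr, gamma, sigma2, k_min)
    for (k in seq_len(length(cuts) - 1)) {
      ix <- (cuts[k] + 1):cuts[k + 1]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = b$start[ix[1]], end = b$end[ix[length(ix)]],
        n_bins = length(ix), median_logr = stats::median(b$logr[ix]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify segments and compute the fraction of genome altered
#'
#' A segment is a gain when its median logR exceeds \code{gain_threshold},
#' a loss when below \code{loss_threshold}, normal otherwise. The fraction
#' altered is the summed length of gain and loss segments over the summed
#' length of all segments.
#'
#' @param segments Output of \code{\link{segment_logr}}.
#' @param gain_threshold,loss_threshold logR thresholds (defaults +0.2 and
#'   -0.2; a one-copy gain in a pure diploid sits at log2(3/2) = 0.585).
#' @return List: \code{segments} (with a \code{class} column) and
#'   \code{fraction_altered}.
#' @export
call_segments <- function(segments, gain_threshold = 0.2,
                          loss_threshold = -0.2) {
  if (gain_threshold <= 0 || loss_threshold >= 0) {
    stop("gain threshold must be positive and loss threshold negative")
  }
  cls <- ifelse(segments$median_logr > gain_threshold, "gain",
                ifelse(segments$median_logr < loss_threshold, "loss",
                       "normal"))
  segments$class <- cls
  len <- segments$end - segments$start
  fa <- sum(len[cls != "normal"]) / sum(len)
  list(segments = segments, fraction_altered = fa)
}

#' Run a segmentation parameter sweep
#'
#' Segments the same track under several (gamma, k_min) settings and
#' returns both the segment lists and the per-run robustness metrics.
#'
#' @param bins Output of \code{\link{compute_logr}}.
#' @param settings Data frame with columns gamma and k_min, one row per
#'   run (default: the gamma 10/30/50/100 sweep plus k_min = 2 at the
#'   default gamma).
#' @param gain_threshold,loss_threshold Passed to
#'   \code{\link{call_segments}}.
#' @return List: \code{runs} (named list of classed segment tables) and
#'   \code{metrics} (see \code{\link{sweep_metrics}}).
#' @export
sweep_segmentation <- function(bins,
                               settings = data.frame(
                                 gamma = c(10, 30, 50, 100, 30),
                                 k_min = c(3, 3, 3, 3, 2)),
                               gain_threshold = 0.2, loss_threshold = -0.2) {
  runs <- list()
  for (i in seq_len(nrow(settings))) {
    seg <- segment_logr(bins, gamma = settings$gamma[i],
                        k_min = settings$k_min[i])
    cs <- call_segments(seg, gain_threshold, loss_threshold)
    runs[[sprintf("gamma%g_kmin%d", settings$gamma[i], settings$k_min[i])]] <-
      cs$segments
  }
  list(runs = runs, metrics = sweep_metrics(runs))
}

#' Per-run segmentation sweep metrics
#'
#' For each run: the number of segments, the segment-length class
#' composition over \{<1 Mb, 1-10 Mb, 10-50 Mb, >50 Mb\} as percent of
#' summed length, and the gain/loss/normal composition by summed length.
#' Empty runs are excluded with a warning.
#'
#' @param runs Named list of classed segment tables (chrom, start, end,
#'   class).
#' @return Data frame, one row per run.
#' @export
sweep_metrics <- function(runs) {
  if (length(runs) < 2) stop("a sweep needs at least 2 runs")
  empty <- vapply(runs, function(r) is.null(r) || !nrow(r), logical(1))
  if (any(empty)) {
    warning(sprintf("excluding %d empty run(s)", sum(empty)))
    runs <- runs[!empty]
  }
  rows <- lapply(names(runs), function(nm) {
    r <- runs[[nm]]
    len <- r$end - r$start
    tot <- sum(len)
    lc <- c(lt1 = sum(len[len < 1e6]),
            m1_10 = sum(len[len >= 1e6 & len < 1e7]),
            m10_50 = sum(len[len >= 1e7 & len < 5e7]),
            gt50 = sum(len[len >= 5e7])) / tot * 100
    cc <- vapply(c("gain", "loss", "normal"), function(cl)
      sum(len[r$class == cl]) / tot * 100, numeric(1))
    data.frame(run = nm, n_segments = nrow(r),
               pct_lt1mb = lc[["lt1"]], pct_1_10mb = lc[["m1_10"]],
               pct_10_50mb = lc[["m10_50"]], pct_gt50mb = lc[["gt50"]],
               pct_gain = cc[["gain"]], pct_loss = cc[["loss"]],
               pct_normal = cc[["normal"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
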