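# Context-normalized selection analysis. The mutation-rate spectrum is
# fitted from synonymous calls (which are selectively neutral), expected
# counts per consequence class follow from exhaustive enumeration of the
# coding territory, and per-gene dN/dS ratios are tested with a Poisson
# likelihood-ratio test. This is a deliberate simplification of the
# negative-binomial gene-rate model used by dNdScv: per-gene rate
# covariates are out of scope here.

#' Fit a trinucleotide mutation spectrum from synonymous calls
#'
#' The rate of each of the 96 channels is the synonymous call count in that
#' channel divided by the synonymous opportunity (number of possible
#' synonymous substitutions in that channel across the panel). Zero-count
#' channels receive a pseudocount of 0.5 so no channel has rate exactly
#' zero. A global indel rate per bp is estimated from indel calls.
#'
#' @param calls Annotated call data frame (class and channel columns).
#' @param genes A \code{gene_set}.
#' @param enum Optional precomputed enumeration table.
#' @param pseudocount Added to zero-count channels.
#' @return Object of class \code{"spectrum_model"}: list with \code{rates}
#'   (named numeric, 96 channels), \code{opportunities}, \code{indel_rate}.
#' @export
fit_spectrum <- function(calls, genes, enum = NULL, pseudocount = 0.5) {
  if (is.null(enum)) enum <- enumerate_substitutions(genes)
  syn <- calls[calls$class == "synonymous", , drop = FALSE]
  if (!nrow(syn)) stop("fit_spectrum requires at least one synonymous call")
  ch <- sbs96_channels()
  opp <- table(factor(enum$channel[enum$class == "synonymous"], levels = ch))
  opp <- as.numeric(opp); names(opp) <- ch
  cnt <- as.numeric(table(factor(syn$channel, levels = ch)))
  cnt[cnt == 0] <- pseudocount
  rates <- ifelse(opp > 0, cnt / opp, NA_real_)
  # channels with no synonymous opportunity borrow their substitution
  # type's average rate (hierarchical fallback; the global average would
  # leak the dominant channels' rate into rare contexts)
  if (any(is.na(rates))) {
    type <- substr(ch, 3, 5)
    for (tp in unique(type[is.na(rates)])) {
      sel <- type == tp
      tot_opp <- sum(opp[sel])
      rates[sel & is.na(rates)] <- if (tot_opp > 0)
        sum(cnt[sel & opp > 0]) / tot_opp else sum(cnt) / max(sum(opp), 1)
    }
  }
  names(rates) <- ch
  n_indel <- sum(calls$class == "indel")
  out <- list(rates = rates, opportunities = opp,
              indel_rate = n_indel / footprint_bp(genes))
  class(out) <- "spectrum_model"
  out
}

#' @export
print.spectrum_model <- function(x, ...) {
  top <- sort(x$rates, decreasing = TRUE)[1:5]
  cat("spectrum_model: 96 channels; top channels:\n")
  print(round(top, 4))
  cat(sprintf("indel rate: %.3g per bp\n", x$indel_rate))
  invisible(x)
}

#' Expected mutation counts per gene and class
#'
#' Enumerates all possible substitutions at coding positions of each gene
#' (plus essential splice bases), weights each by its fitted spectrum rate
#' and sums by consequence class. Nonsense and essential splice are pooled
#' into one class. The expected indel count is the indel rate times the
#' gene footprint.
#'
#' @param genes A \code{gene_set} (an error is raised if any CDS carries an
#'   internal stop codon).
#' @param spectrum A \code{\link{fit_spectrum}} model.
#' @param enum Optional precomputed enumeration table.
#' @return Data frame: gene, E_syn, E_mis, E_non_splice, E_indel.
#' @export
expected_counts <- function(genes, spectrum, enum = NULL) {
  for (g in genes$genes$gene) {
    aa <- translate_cds(cds_sequence(genes, g))
    body <- substr(aa, 1, nchar(aa) - 1)
    if (grepl("\\*", body)) {
      stop(sprintf("gene %s has an internal stop codon", g))
    }
  }
  if (is.null(enum)) enum <- enumerate_substitutions(genes)
  enum$rate <- spectrum$rates[enum$channel]
  enum$cls3 <- ifelse(enum$class %in% c("nonsense", "essential_splice"),
                      "non_splice", enum$class)
  agg <- stats::aggregate(rate ~ gene + cls3, data = enum, FUN = sum)
  wide <- stats::reshape(agg, idvar = "gene", timevar = "cls3",
                         direction = "wide")
  names(wide) <- sub("^rate\\.", "E_", names(wide))
  for (cl in c("E_synonymous", "E_missense", "E_non_splice")) {
    if (!cl %in% names(wide)) wide[[cl]] <- 0
    wide[[cl]][is.na(wide[[cl]])] <- 0
  }
  out <- data.frame(gene = wide$gene,
                    E_syn = wide$E_synonymous,
                    E_mis = wide$E_missense,
                    E_non_splice = wide$E_non_splice,
                    stringsAsFactors = FALSE)
  glen <- nchar(genes$seq)[out$gene]
  out$E_indel <- spectrum$indel_rate * glen
  out[order(out$gene), , drop = FALSE]
}

#' Observed mutation counts per gene and class
#'
#' @param calls Annotated call (or clone) data frame with gene and class.
#' @param genes A \code{gene_set} providing the gene universe.
#' @return Data frame: gene, n_syn, n_mis, n_non_splice, n_indel.
#' @export
gene_counts <- function(calls, genes) {
  gl <- genes$genes$gene
  cnt <- function(cls) {
    vapply(gl, function(g) sum(calls$gene == g & calls$class %in% cls),
           numeric(1))
  }
  data.frame(gene = gl,
             n_syn = cnt("synonymous"),
             n_mis = cnt("missense"),
             n_non_splice = cnt(c("nonsense", "essential_splice")),
             n_indel = cnt("indel"),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Poisson LRT of H0: omega = 1 given (n_c, E_c) vs (n_s, E_s).
# Returns list(omega, p). lam_fallback is used when n_s is 0.
dnds_lrt <- function(n_c, E_c, n_s, E_s, lam_fallback) {
  plog <- function(n, mu) ifelse(n > 0, n * log(mu), 0) - mu
  if (n_s > 0) {
    lam1 <- n_s / E_s
    om <- (n_c / E_c) / lam1
    ll1 <- plog(n_s, lam1 * E_s) + plog(n_c, max(om, 1e-12) * lam1 * E_c)
    lam0 <- (n_s + n_c) / (E_s + E_c)
    ll0 <- plog(n_s, lam0 * E_s) + plog(n_c, lam0 * E_c)
    syn_zero <- FALSE
  } else {
    # no synonymous calls in this gene: baseline from the global rate
    om <- (n_c / E_c) / lam_fallback
    ll1 <- plog(n_c, max(n_c, 1e-12))
    ll0 <- plog(n_c, lam_fallback * E_c)
    syn_zero <- TRUE
  }
  stat <- max(0, 2 * (ll1 - ll0))
  list(omega = om, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       syn_zero = syn_zero)
}

#' Context-normalized dN/dS per gene with selection classification
#'
#' For each gene and mutation class (missense, nonsense + essential splice,
#' indel), the normalized ratio is
#' \deqn{dN/dS = (n_{class}/E_{class}) / (n_{syn}/E_{syn})}
#' with expected counts from the fitted trinucleotide spectrum. P-values
#' come from a Poisson likelihood-ratio test of ratio = 1, adjusted by
#' Benjamini-Hochberg per class across genes. Only the nonsense/splice
#' ratio drives the positive/negative labels (missense and indel ratios
#' are reported but unlabeled): positive when dN/dS > \code{pos_threshold}
#' and q < \code{q_threshold}; negative when dN/dS < \code{neg_threshold}
#' and q < \code{q_threshold}.
#'
#' @param calls Annotated call data frame, or a precomputed
#'   \code{\link{gene_counts}} table.
#' @param genes A \code{gene_set}.
#' @param spectrum Optional \code{\link{fit_spectrum}} model; fitted from
#'   \code{calls} when absent.
#' @param enum Optional precomputed enumeration table.
#' @param pos_threshold,neg_threshold,q_threshold Classification
#'   thresholds (defaults 1.3, 0.6, 0.01).
#' @return Object of class \code{"dnds_fit"} with per-gene results
#'   (\code{$genes}), global ratios with 95\% confidence intervals
#'   (\code{$global}) and the thresholds used. Supports \code{print},
#'   \code{summary}, \code{coef} and \code{plot}.
#' @examples
#' gs <- generate_gene_models(4, 60, seed = 2)
#' sim <- simulate_epidermis(sim_params(seed = 2, n_grids = 12), genes = gs)
#' ann <- annotate_calls(sim$counts, gs)
#' ann$vaf <- (ann$alt_fwd + ann$alt_rev) / ann$depth
#' fit <- dnds(ann, gs)
#' fit
#' @export
dnds <- function(calls, genes, spectrum = NULL, enum = NULL,
                 pos_threshold = 1.3, neg_threshold = 0.6,
                 q_threshold = 0.01) {
  if (is.null(enum)) enum <- enumerate_substitutions(genes)
  if (all(c("n_syn", "n_mis", "n_non_splice") %in% names(calls))) {
    obs <- calls
    if (is.null(spectrum)) {
      stop("a spectrum model is required when passing precomputed counts")
    }
  } else {
    if (is.null(spectrum)) spectrum <- fit_spectrum(calls, genes, enum = enum)
    obs <- gene_counts(calls, genes)
  }
  if (!"n_indel" %in% names(obs)) obs$n_indel <- 0
  exp <- expected_counts(genes, spectrum, enum = enum)
  tab <- merge(obs, exp, by = "gene")
  if (any(tab$E_syn <= 0)) stop("every gene must have positive E_syn")
  lam_glob <- sum(tab$n_syn) / sum(tab$E_syn)

  classes <- c(missense = "mis", non_splice = "non_splice", indel = "indel")
  res <- list()
  for (cl in names(classes)) {
    suf <- classes[[cl]]
    ncol_ <- paste0("n_", suf); ecol <- paste0("E_", suf)
    rows <- lapply(seq_len(nrow(tab)), function(i) {
      E_c <- tab[[ecol]][i]
      if (E_c <= 0) {
        # degenerate opportunity (pseudo-opportunity flag)
        return(data.frame(gene = tab$gene[i], class = cl, n_obs = tab[[ncol_]][i],
                          E = E_c, dnds = NA_real_, p = NA_real_,
                          syn_zero = FALSE, no_opportunity = TRUE,
                          stringsAsFactors = FALSE))
      }
      lt <- dnds_lrt(tab[[ncol_]][i], E_c, tab$n_syn[i], tab$E_syn[i], lam_glob)
      data.frame(gene = tab$gene[i], class = cl, n_obs = tab[[ncol_]][i],
                 E = E_c, dnds = lt$omega, p = lt$p, syn_zero = lt$syn_zero,
                 no_opportunity = FALSE, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df$q <- NA_real_
    ok <- !is.na(df$p)
    df$q[ok] <- stats::p.adjust(df$p[ok], method = "BH")
    res[[cl]] <- df
  }
  per_gene <- do.call(rbind, res)
  rownames(per_gene) <- NULL

  ns <- per_gene[per_gene$class == "non_splice", , drop = FALSE]
  lab <- rep("neutral", nrow(ns))
  lab[!is.na(ns$dnds) & ns$dnds > pos_threshold &
        !is.na(ns$q) & ns$q < q_threshold] <- "positive"
  lab[!is.na(ns$dnds) & ns$dnds < neg_threshold &
        !is.na(ns$q) & ns$q < q_threshold] <- "negative"
  labels <- data.frame(gene = ns$gene, label = lab, stringsAsFactors = FALSE)
  per_gene$label <- NA_character_
  m <- per_gene$class == "non_splice"
  per_gene$label[m] <- lab

  glob <- do.call(rbind, lapply(names(classes), function(cl) {
    suf <- classes[[cl]]
    n_c <- sum(tab[[paste0("n_", suf)]]); E_c <- sum(tab[[paste0("E_", suf)]])
    n_s <- sum(tab$n_syn); E_s <- sum(tab$E_syn)
    om <- (n_c / E_c) / (n_s / E_s)
    se <- sqrt(1 / max(n_c, 0.5) + 1 / max(n_s, 0.5))
    data.frame(class = cl, n_obs = n_c, dnds = om,
               lower = om * exp(-1.96 * se), upper = om * exp(1.96 * se),
               stringsAsFactors = FALSE)
  }))

  out <- list(genes = per_gene, labels = labels, global = glob,
              counts = tab, spectrum = spectrum,
              thresholds = c(pos = pos_threshold, neg = neg_threshold,
                             q = q_threshold))
  class(out) <- "dnds_fit"
  out
}

#' @export
print.dnds_fit <- function(x, ...) {
  cat("Context-normalized dN/dS fit\n")
  cat(sprintf("  %d genes; thresholds: positive > %.2f, negative < %.2f, q < %.2g\n",
              nrow(x$labels), x$thresholds["pos"], x$thresholds["neg"],
              x$thresholds["q"]))
  cat("  global ratios:\n")
  print(transform(x$global, dnds = round(dnds, 3), lower = round(lower, 3),
                  upper = round(upper, 3)), row.names = FALSE)
  np <- sum(x$labels$label == "positive"); nn <- sum(x$labels$label == "negative")
  cat(sprintf("  %d positively and %d negatively selected gene(s)\n", np, nn))
  invisible(x)
}

#' @export
summary.dnds_fit <- function(object, ...) {
  sel <- object$genes[object$genes$class == "non_splice", , drop = FALSE]
  sel <- sel[order(sel$q), c("gene", "n_obs", "dnds", "p", "q", "label")]
  structure(list(global = object$global, selection = sel,
                 thresholds = object$thresholds),
            class = "summary.dnds_fit")
}

#' @export
print.summary.dnds_fit <- function(x, ...) {
  cat("Global dN/dS:\n"); print(x$global, row.names = FALSE)
  cat("\nPer-gene nonsense/essential-splice selection (ordered by q):\n")
  print(utils::head(x$selection, 15), row.names = FALSE)
  invisible(x)
}

#' @export
coef.dnds_fit <- function(object, class = "non_splice", ...) {
  g <- object$genes[object$genes$class == class, , drop = FALSE]
  stats::setNames(g$dnds, g$gene)
}

#' @export
plot.dnds_fit <- function(x, class = "non_splice", ...) {
  g <- x$genes[x$genes$class == class, , drop = FALSE]
  g <- g[order(g$dnds), ]
  graphics::dotchart(g$dnds, labels = g$gene, xlab = "dN/dS",
                     main = paste("dN/dS,", class), ...)
  graphics::abline(v = 1, lty = 2)
  graphics::abline(v = x$thresholds[c("pos", "neg")], lty = 3, col = "red")
  invisible(x)
}

#' VAF_ns/VAF_s selection statistic per gene
#'
#' The ratio of summed variant allele frequencies of nonsynonymous
#' (missense, nonsense, essential splice, indel) to synonymous clone
#' records in a gene, plus a per-clone-normalized version
#' (mean VAF_ns / mean VAF_s) whose neutral expectation is 1 even when the
#' two classes differ in mutational opportunity. Significance is a
#' two-tailed Wilcoxon rank-sum test comparing the per-clone VAF lists
#' (exact when both classes have at most 25 clones and no ties, normal
#' approximation with continuity correction otherwise).
#'
#' @param calls Annotated clone records (gene, class, vaf).
#' @param genes Optional \code{gene_set} restricting the gene universe.
#' @return Data frame: gene, n_ns, n_s, sum_vaf_ns, sum_vaf_s, ratio,
#'   ratio_per_clone, p, defined (FALSE when a class is missing).
#' @export
vaf_ratio <- function(calls, genes = NULL) {
  stopifnot_cols(calls, c("gene", "class", "vaf"), "calls")
  ns_classes <- c("missense", "nonsense", "essential_splice", "indel")
  gl <- if (!is.null(genes)) genes$genes$gene else sort(unique(calls$gene))
  rows <- lapply(gl, function(g) {
    cc <- calls[calls$gene == g, , drop = FALSE]
    x <- cc$vaf[cc$class %in% ns_classes]
    y <- cc$vaf[cc$class == "synonymous"]
    defined <- length(x) >= 1 && length(y) >= 1 && sum(y) > 0
    ratio <- if (defined) sum(x) / sum(y) else NA_real_
    rpc <- if (defined) mean(x) / mean(y) else NA_real_
    p <- if (length(x) >= 1 && length(y) >= 1) {
      exact <- length(x) <= 25 && length(y) <= 25 &&
        !any(duplicated(c(x, y)))
      suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                          correct = TRUE)$p.value)
    } else NA_real_
    data.frame(gene = g, n_ns = length(x), n_s = length(y),
               sum_vaf_ns = sum(x), sum_vaf_s = sum(y), ratio = ratio,
               ratio_per_clone = rpc, p = p, defined = defined,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
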