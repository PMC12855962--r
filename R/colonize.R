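# Tissue-colonization estimates. In a diploid tissue the summed VAF of
# protein-altering mutations in a gene is proportional to the area occupied
# by mutant cells: each heterozygous mutant cell contributes half its reads.
# The point/upper estimate doubles the summed VAF (heterozygous, disjoint
# clones); the lower bound takes it at face value (homozygous and/or fully
# nested clones). Both are capped at 100%.

PROTEIN_ALTERING <- c("missense", "nonsense", "essential_splice", "indel")

#' Percent of tissue colonized by mutants of a gene
#'
#' Per aggregation unit, the summed VAF over protein-altering calls is the
#' area-weighted mean across samples of the per-sample summed VAF; the
#' colonized percentage follows with copy-number/nesting uncertainty
#' bounds.
#'
#' @param calls Annotated call data frame (sample, gene, class, vaf);
#'   protein-altering classes only -- other classes raise an error unless
#'   \code{drop_other = TRUE}.
#' @param samples Sample table (sample, area_mm2 and the \code{unit}
#'   column). Missing areas give equal weights.
#' @param gene Gene to estimate (default: all genes present).
#' @param unit Name of the column of \code{samples} defining the
#'   aggregation unit (e.g. "timepoint" or "tumor").
#' @param drop_other Silently drop non-protein-altering calls instead of
#'   erroring.
#' @return Data frame: gene, unit, sigma_vaf, point, lower, upper
#'   (percentages in [0, 100], lower <= point <= upper).
#' @export
colonized_fraction <- function(calls, samples, gene = NULL,
                               unit = "timepoint", drop_other = FALSE) {
  stopifnot_cols(calls, c("sample", "gene", "class", "vaf"), "calls")
  stopifnot_cols(samples, c("sample", unit), "sample table")
  bad <- !calls$class %in% PROTEIN_ALTERING
  if (any(bad)) {
    if (!drop_other) {
      stop("colonized_fraction expects protein-altering calls only; ",
           "set drop_other = TRUE to discard others")
    }
    calls <- calls[!bad, , drop = FALSE]
  }
  if ("area_mm2" %in% names(samples) && any(samples$area_mm2 <= 0)) {
    stop("areas must be positive")
  }
  genes <- gene %||% sort(unique(calls$gene))
  w <- if ("area_mm2" %in% names(samples)) samples$area_mm2 else
    rep(1, nrow(samples))
  units <- unique(samples[[unit]])
  rows <- list()
  for (g in genes) {
    for (u in units) {
      sm <- samples[samples[[unit]] == u, , drop = FALSE]
      wu <- w[samples[[unit]] == u]
      sv <- vapply(sm$sample, function(s) {
        sum(calls$vaf[calls$sample == s & calls$gene == g])
      }, numeric(1))
      sigma <- sum(wu * sv) / sum(wu)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, unit = u, sigma_vaf = sigma,
        point = min(100, 2 * sigma * 100),
        lower = min(100, sigma * 100),
        upper = min(100, 2 * sigma * 100),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stratify tumors by mutant Trp53 content relative to the epidermis
#'
#' A tumor is labeled low when its summed VAF of nonsynonymous mutations in
#' the stratification gene is strictly below the matched same-animal
#' epidermis value; ties are labeled high. Tumors without a matched
#' epidermis estimate are excluded with a warning.
#'
#' @param tumor_est Data frame (tumor, animal, sigma_vaf) of per-tumor
#'   estimates for the gene.
#' @param epidermis_est Data frame (animal, sigma_vaf) of per-animal
#'   epidermis estimates for the same gene.
#' @param gene Label recorded in the output (informational).
#' @return Data frame: tumor, animal, sigma_vaf_tumor, sigma_vaf_epidermis,
#'   label ("high"/"low").
#' @export
trp53_stratify <- function(tumor_est, epidermis_est, gene = "Trp53") {
  stopifnot_cols(tumor_est, c("tumor", "animal", "sigma_vaf"), "tumor_est")
  stopifnot_cols(epidermis_est, c("animal", "sigma_vaf"), "epidermis_est")
  m <- match(tumor_est$animal, epidermis_est$animal)
  miss <- is.na(m)
  if (any(miss)) {
    warning(sprintf("%d tumor(s) without matched epidermis excluded",
                    sum(miss)))
  }
  te <- tumor_est[!miss, , drop = FALSE]
  ev <- epidermis_est$sigma_vaf[m[!miss]]
  data.frame(tumor = te$tumor, animal = te$animal, gene = gene,
             sigma_vaf_tumor = te$sigma_vaf, sigma_vaf_epidermis = ev,
             label = ifelse(te$sigma_vaf < ev, "low", "high"),
             stringsAsFactors = FALSE)
}

#' Compare per-gene summed VAF between two tumor groups
#'
#' Per gene, a two-sample two-tailed Z-test on the mean summed VAF with
#' group variances estimated from the per-tumor values, followed by
#' Benjamini-Hochberg correction across genes; outliers are genes with
#' q < \code{outlier_q}.
#'
#' @param gene_vafs Data frame (tumor, gene, sigma_vaf), one row per tumor
#'   and gene.
#' @param groups Named character vector (or data frame tumor/group) mapping
#'   each tumor to one of two group labels.
#' @param outlier_q q-value threshold flagging outlier genes.
#' @return Data frame: gene, mean1, mean2, z, p, q, outlier. Genes where a
#'   group has fewer than 2 tumors are flagged NA (test skipped).
#' @export
compare_gene_groups <- function(gene_vafs, groups, outlier_q = 0.05) {
  stopifnot_cols(gene_vafs, c("tumor", "gene", "sigma_vaf"), "gene_vafs")
  if (is.data.frame(groups)) {
    groups <- stats::setNames(groups$group, groups$tumor)
  }
  gene_vafs$group <- groups[gene_vafs$tumor]
  lv <- unique(stats::na.omit(gene_vafs$group))
  if (length(lv) != 2) stop("exactly two non-empty groups are required")
  rows <- lapply(sort(unique(gene_vafs$gene)), function(g) {
    gg <- gene_vafs[gene_vafs$gene == g, , drop = FALSE]
    x <- gg$sigma_vaf[gg$group == lv[1]]
    y <- gg$sigma_vaf[gg$group == lv[2]]
    if (length(x) < 2 || length(y) < 2) {
      return(data.frame(gene = g, mean1 = mean(x), mean2 = mean(y),
                        z = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
    }
    se <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
    d <- mean(x) - mean(y)
    z <- if (se == 0) { if (d == 0) 0 else sign(d) * Inf } else d / se
    data.frame(gene = g, mean1 = mean(x), mean2 = mean(y), z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out$outlier <- !is.na(out$q) & out$q < outlier_q
  rownames(out) <- NULL
  out
}

#' Cohort-level statistical tests
#'
#' Thin contract wrappers delegating to the standard routines: Wilcoxon
#' rank-sum, Kruskal-Wallis, nested ANOVA (group effect with animal as the
#' nesting error stratum), two-group F test of variances, and simple
#' linear regression (reporting r-squared). Two-tailed throughout.
#'
#' @param values Numeric response (for \code{"linregress"}, the y values).
#' @param grouping Group factor; for \code{"linregress"}, the numeric x.
#' @param kind One of "wilcoxon", "kruskal", "anova_nested", "f_var",
#'   "linregress".
#' @param animal Animal factor, required for \code{"anova_nested"}.
#' @return List with \code{statistic}, \code{p} and, for regression,
#'   \code{effect} (r-squared).
#' @export
cohort_test <- function(values, grouping,
                        kind = c("wilcoxon", "kruskal", "anova_nested",
                                 "f_var", "linregress"),
                        animal = NULL) {
  kind <- match.arg(kind)
  switch(kind,
    wilcoxon = {
      g <- factor(grouping)
      if (nlevels(g) != 2) stop("wilcoxon requires exactly two groups")
      x <- values[g == levels(g)[1]]; y <- values[g == levels(g)[2]]
      if (all(x %in% y) && all(y %in% x) && length(x) == length(y)) {
        # degenerate identical samples
        return(list(statistic = length(x) * length(y) / 2, p = 1))
      }
      w <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
      list(statistic = unname(w$statistic), p = w$p.value)
    },
    kruskal = {
      if (length(unique(values)) == 1) return(list(statistic = 0, p = 1))
      k <- stats::kruskal.test(values, factor(grouping))
      list(statistic = unname(k$statistic), p = k$p.value)
    },
    anova_nested = {
      if (is.null(animal)) stop("anova_nested requires the animal factor")
      d <- data.frame(y = values, g = factor(grouping), a = factor(animal))
      fit <- stats::aov(y ~ g + Error(a), data = d)
      tab <- summary(fit)[["Error: a"]][[1]]
      list(statistic = tab["g", "F value"], p = tab["g", "Pr(>F)"])
    },
    f_var = {
      g <- factor(grouping)
      if (nlevels(g) != 2) stop("f_var requires exactly two groups")
      v <- stats::var.test(values[g == levels(g)[1]],
                           values[g == levels(g)[2]])
      list(statistic = unname(v$statistic), p = v$p.value)
    },
    linregress = {
      if (stats::var(grouping) == 0) stop("regression on constant x")
      fit <- stats::lm(values ~ grouping)
      sm <- summary(fit)
      pv <- stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                      lower.tail = FALSE)
      list(statistic = unname(sm$fstatistic[1]), p = unname(pv),
           effect = sm$r.squared)
    })
}
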