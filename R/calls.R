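# Site-specific error-model variant calling and the five-rule post-calling
# filter chain. The caller fits a beta-binomial to a panel of normal
# samples per site and substitution (method of moments) and tests each
# observation for a statistical excess of mutant reads, with
# Benjamini-Hochberg control across all tested site-substitutions.

#' Fit a background error panel
#'
#' Per site and substitution, pools alt counts across normal samples and
#' fits a beta-binomial by the method of moments: the mean is the pooled
#' alt fraction, the overdispersion comes from the between-sample variance
#' of alt proportions, floored at \code{rho_floor}.
#'
#' @param panel_counts Read-count data frame (sample, chrom, pos, ref, alt,
#'   depth, alt_fwd, alt_rev) from normal samples, e.g.
#'   \code{\link{simulate_background_panel}}.
#' @param rho_floor Lower bound on the fitted overdispersion.
#' @param mu_floor Lower bound on the fitted error mean (keeps the mean
#'   inside (0,1) at sites with no observed errors).
#' @return Object of class \code{"background_panel"}: data frame with one
#'   row per (chrom, pos, ref, alt) carrying mu, rho, tot_alt, tot_depth.
#' @export
fit_background_panel <- function(panel_counts, rho_floor = 1e-9,
                                 mu_floor = 1e-6) {
  stopifnot_cols(panel_counts, c("sample", "chrom", "pos", "ref", "alt",
                                 "depth", "alt_fwd", "alt_rev"), "panel")
  pc <- panel_counts
  pc$altn <- pc$alt_fwd + pc$alt_rev
  key <- paste(pc$chrom, pc$pos, pc$ref, pc$alt, sep = ":")
  sp <- split(seq_len(nrow(pc)), key)
  rows <- lapply(sp, function(ix) {
    d <- pc$depth[ix]; a <- pc$altn[ix]
    mu <- max(sum(a) / sum(d), mu_floor)
    p <- a / d
    nbar <- mean(d)
    # moment estimator of the intra-class correlation
    s2 <- if (length(p) > 1) stats::var(p) else 0
    denom <- mu * (1 - mu) * (1 - 1 / nbar)
    rho <- if (denom > 0) (s2 - mu * (1 - mu) / nbar) / denom else 0
    data.frame(chrom = pc$chrom[ix[1]], pos = pc$pos[ix[1]],
               ref = pc$ref[ix[1]], alt = pc$alt[ix[1]],
               mu = min(mu, 0.5), rho = min(max(rho, rho_floor), 0.9),
               tot_alt = sum(a), tot_depth = sum(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("background_panel", class(out))
  out
}

#' Call variants against a background panel
#'
#' For every row of the read-count table, computes the one-sided upper-tail
#' beta-binomial p-value of the observed alt count under the panel's error
#' model at that site and substitution, adjusts across all tested
#' site-substitutions by Benjamini-Hochberg, and emits calls with
#' \code{q <= fdr_alpha} supported by at least one read on each strand.
#'
#' @param counts Read-count data frame (sample, chrom, pos, ref, alt,
#'   depth, alt_fwd, alt_rev).
#' @param panel A \code{\link{fit_background_panel}} object.
#' @param fdr_alpha FDR threshold in (0, 1).
#' @return Data frame of calls (sample, chrom, pos, ref, alt, depth,
#'   alt_fwd, alt_rev, vaf, p, q). Sites absent from the panel are not
#'   silently dropped: they are returned in the \code{"untested"}
#'   attribute.
#' @export
call_variants <- function(counts, panel, fdr_alpha = 0.05) {
  stopifnot_cols(counts, c("sample", "chrom", "pos", "ref", "alt",
                           "depth", "alt_fwd", "alt_rev"), "counts")
  if (fdr_alpha <= 0 || fdr_alpha >= 1) stop("fdr_alpha must be in (0, 1)")
  key <- paste(counts$chrom, counts$pos, counts$ref, counts$alt, sep = ":")
  pkey <- paste(panel$chrom, panel$pos, panel$ref, panel$alt, sep = ":")
  m <- match(key, pkey)
  untested <- counts[is.na(m), , drop = FALSE]
  tested <- counts[!is.na(m), , drop = FALSE]
  pm <- panel[m[!is.na(m)], , drop = FALSE]
  altn <- tested$alt_fwd + tested$alt_rev
  pv <- vapply(seq_len(nrow(tested)), function(i) {
    pbetabinom_upper(altn[i], tested$depth[i], pm$mu[i], pm$rho[i])
  }, numeric(1))
  qv <- stats::p.adjust(pv, method = "BH")
  keep <- qv <= fdr_alpha & tested$alt_fwd >= 1 & tested$alt_rev >= 1
  out <- tested[keep, , drop = FALSE]
  out$vaf <- (out$alt_fwd + out$alt_rev) / out$depth
  out$p <- pv[keep]
  out$q <- qv[keep]
  rownames(out) <- NULL
  attr(out, "untested") <- untested
  attr(out, "n_tested") <- nrow(tested)
  out
}

#' Annotate calls with gene and consequence class
#'
#' Joins calls against the substitution enumeration of the gene models.
#' Single-base calls receive their enumerated class (synonymous, missense,
#' nonsense, essential_splice); multi-base alts are classed \code{"DBS"}
#' and \code{alt == "-"} is classed \code{"indel"}. Calls whose context
#' cannot be resolved are excluded with a warning count.
#'
#' @param calls Call data frame with chrom, pos, ref, alt.
#' @param genes A \code{gene_set}.
#' @param enum Optional precomputed enumeration table.
#' @return The calls with added \code{gene}, \code{class} and
#'   \code{channel} columns; attribute \code{"n_unresolved"} counts
#'   excluded rows.
#' @export
annotate_calls <- function(calls, genes, enum = NULL) {
  if (is.null(enum)) enum <- enumerate_substitutions(genes)
  is_dbs <- nchar(calls$ref) == 2 & nchar(calls$alt) == 2
  is_indel <- calls$alt == "-" | nchar(calls$ref) != nchar(calls$alt)
  is_snv <- !is_dbs & !is_indel
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
  ekey <- paste(enum$chrom, enum$pos, enum$ref, enum$alt, sep = ":")
  m <- match(key, ekey)
  calls$gene <- calls$chrom
  calls$class <- NA_character_
  calls$channel <- NA_character_
  calls$class[is_snv] <- enum$class[m[is_snv]]
  calls$channel[is_snv] <- enum$channel[m[is_snv]]
  calls$class[is_dbs & !is_snv] <- "DBS"
  calls$class[is_indel] <- "indel"
  bad <- is.na(calls$class)
  if (any(bad)) {
    warning(sprintf("%d call(s) with unresolvable context excluded", sum(bad)))
  }
  out <- calls[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unresolved") <- sum(bad)
  out
}

call_key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")

#' Apply the post-calling filter chain
#'
#' The five rules, in order: (1) drop calls at sites with depth < 100;
#' (2) drop calls matching germline variants of the same animal; (3) FDR
#' and both-strand support (enforced at calling; re-checked here);
#' (4) merge adjacent-nucleotide SNV pairs within a sample into a DBS when
#' at least 90\% of the reads covering at least one of the pair carry both;
#' (5) merge identical mutations found in contiguous biopsies into a single
#' clone record with summed alt and depth.
#'
#' Read-level co-occurrence is not available from a count table, so rule 4
#' uses the maximal-overlap bound: the joint-read fraction of a pair is
#' estimated as \code{min(alt1, alt2) / max(alt1, alt2)} unless an explicit
#' \code{joint} count column is present.
#'
#' @param calls Annotated call data frame (needs sample, chrom, pos, ref,
#'   alt, class, depth, alt_fwd, alt_rev, vaf, q).
#' @param germline Optional data frame of germline variants (chrom, pos,
#'   ref, alt) to remove.
#' @param adjacency Optional data frame (sample1, sample2) declaring which
#'   biopsies are contiguous; required for clone merging. Every sample
#'   referenced by a call must appear in the sample universe implied by the
#'   map (or in \code{samples}).
#' @param samples Optional vector of all sample ids (the universe for the
#'   adjacency check).
#' @param min_depth Rule-1 depth threshold.
#' @param dbs_frac Rule-4 joint-read fraction threshold.
#' @param fdr_alpha Rule-3 FDR threshold re-check.
#' @return List of class \code{"filtered_calls"}: \code{calls} (surviving
#'   per-sample records, DBS-merged), \code{clones} (clone-merged table
#'   across contiguous biopsies), \code{log} (records in/out per rule).
#' @export
apply_filters <- function(calls, germline = NULL, adjacency = NULL,
                          samples = NULL, min_depth = 100, dbs_frac = 0.9,
                          fdr_alpha = 0.05) {
  stopifnot_cols(calls, c("sample", "chrom", "pos", "ref", "alt", "class",
                          "depth", "alt_fwd", "alt_rev", "vaf"), "calls")
  log <- list()
  n0 <- nrow(calls)

  # (1) minimum coverage
  calls <- calls[calls$depth >= min_depth, , drop = FALSE]
  log$depth <- c(before = n0, after = nrow(calls))

  # (2) germline removal
  n1 <- nrow(calls)
  if (!is.null(germline) && nrow(germline)) {
    calls <- calls[!(call_key(calls) %in% call_key(germline)), , drop = FALSE]
  }
  log$germline <- c(before = n1, after = nrow(calls))

  # (3) FDR + both-strand support (re-check)
  n2 <- nrow(calls)
  ok <- calls$alt_fwd >= 1 & calls$alt_rev >= 1
  if ("q" %in% names(calls)) ok <- ok & (is.na(calls$q) | calls$q <= fdr_alpha)
  calls <- calls[ok, , drop = FALSE]
  log$strand_fdr <- c(before = n2, after = nrow(calls))

  # (4) merge adjacent SNV pairs into DBS
  n3 <- nrow(calls)
  calls <- merge_adjacent_dbs(calls, dbs_frac)
  log$dbs_merge <- c(before = n3, after = nrow(calls))

  # (5) clone merging across contiguous biopsies
  clones <- merge_clones(calls, adjacency, samples)
  log$clone_merge <- c(before = nrow(calls), after = nrow(clones))

  rownames(calls) <- NULL
  out <- list(calls = calls, clones = clones,
              log = do.call(rbind, log))
  class(out) <- "filtered_calls"
  out
}

#' @export
print.filtered_calls <- function(x, ...) {
  cat("filtered_calls:", nrow(x$calls), "surviving calls,",
      nrow(x$clones), "merged clones\n")
  print(x$log)
  invisible(x)
}

# Rule 4: pairs of SNVs at adjacent positions in the same sample become one
# DBS when the estimated joint-read fraction reaches dbs_frac.
merge_adjacent_dbs <- function(calls, dbs_frac = 0.9) {
  snv <- which(nchar(calls$ref) == 1 & nchar(calls$alt) == 1 &
                 calls$alt != "-")
  if (length(snv) < 2) return(calls)
  drop <- logical(nrow(calls))
  new_rows <- list()
  o <- snv[order(calls$sample[snv], calls$chrom[snv], calls$pos[snv])]
  for (i in seq_len(length(o) - 1)) {
    a <- o[i]; b <- o[i + 1]
    if (drop[a] || drop[b]) next
    if (calls$sample[a] != calls$sample[b]) next
    if (calls$chrom[a] != calls$chrom[b]) next
    if (calls$pos[b] - calls$pos[a] != 1) next
    alt_a <- calls$alt_fwd[a] + calls$alt_rev[a]
    alt_b <- calls$alt_fwd[b] + calls$alt_rev[b]
    joint <- if ("joint" %in% names(calls) && !is.na(calls$joint[a])) {
      calls$joint[a] / (alt_a + alt_b - calls$joint[a])
    } else {
      min(alt_a, alt_b) / max(alt_a, alt_b)
    }
    if (joint >= dbs_frac) {
      row <- calls[a, , drop = FALSE]
      row$ref <- paste0(calls$ref[a], calls$ref[b])
      row$alt <- paste0(calls$alt[a], calls$alt[b])
      row$depth <- round(mean(c(calls$depth[a], calls$depth[b])))
      keepmin <- if (alt_a <= alt_b) a else b
      row$alt_fwd <- calls$alt_fwd[keepmin]
      row$alt_rev <- calls$alt_rev[keepmin]
      row$vaf <- (row$alt_fwd + row$alt_rev) / row$depth
      if ("class" %in% names(row)) row$class <- "DBS"
      if ("channel" %in% names(row)) row$channel <- NA_character_
      drop[c(a, b)] <- TRUE
      new_rows[[length(new_rows) + 1L]] <- row
    }
  }
  out <- rbind(calls[!drop, , drop = FALSE], do.call(rbind, new_rows))
  out[order(out$sample, out$chrom, out$pos), , drop = FALSE]
}

# Rule 5: identical mutations in contiguous biopsies collapse to one clone
# record. Contiguity is the transitive closure of the declared adjacency,
# restricted to the samples actually carrying the mutation.
merge_clones <- function(calls, adjacency = NULL, samples = NULL) {
  if (!nrow(calls)) {
    out <- calls
    out$n_samples <- integer(0)
    return(out)
  }
  universe <- unique(c(samples,
                       if (!is.null(adjacency)) c(adjacency$sample1,
                                                  adjacency$sample2)))
  if (!is.null(adjacency)) {
    missing <- setdiff(unique(calls$sample), universe)
    if (length(missing)) {
      stop(sprintf("adjacency map missing sample(s): %s",
                   paste(missing, collapse = ", ")))
    }
  }
  key <- call_key(calls)
  out <- list()
  for (ix in split(seq_len(nrow(calls)), key)) {
    sams <- calls$sample[ix]
    comp <- if (is.null(adjacency) || length(ix) == 1) {
      seq_along(ix)  # no adjacency: every sample its own clone
    } else {
      adjacency_components(sams, adjacency)
    }
    for (cm in unique(comp)) {
      jx <- ix[comp == cm]
      row <- calls[jx[1], , drop = FALSE]
      row$depth <- sum(calls$depth[jx])
      row$alt_fwd <- sum(calls$alt_fwd[jx])
      row$alt_rev <- sum(calls$alt_rev[jx])
      row$vaf <- (row$alt_fwd + row$alt_rev) / row$depth
      row$sample <- paste(sort(unique(calls$sample[jx])), collapse = "+")
      row$n_samples <- length(jx)
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$pos, res$sample), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Connected components of 'sams' under the adjacency relation (union-find).
adjacency_components <- function(sams, adjacency) {
  parent <- seq_along(sams)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(adjacency))) {
    i <- match(adjacency$sample1[r], sams)
    j <- match(adjacency$sample2[r], sams)
    if (!is.na(i) && !is.na(j)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_along(sams), find, integer(1))
}

#' Mutational burden and density
#'
#' Burden is mutations per Mb of sequenced footprint; density is mutations
#' per mm^2 of tissue. Tumor burden is the mean across that tumor's slices.
#'
#' @param calls Annotated call data frame (needs sample, class).
#' @param samples Sample table with sample, footprint_bp and (for density)
#'   area_mm2; for \code{by = "tumor"} also a tumor column, for
#'   \code{by = "animal"} an animal column.
#' @param by Aggregation unit: \code{"sample"}, \code{"animal"} or
#'   \code{"tumor"}.
#' @return Data frame with unit, sbs_per_mb, dbs_per_mb, indel_per_mb and
#'   density_per_mm2.
#' @export
mutation_burden <- function(calls, samples, by = c("sample", "animal", "tumor")) {
  by <- match.arg(by)
  stopifnot_cols(samples, c("sample", "footprint_bp"), "sample table")
  if (any(samples$footprint_bp <= 0)) stop("footprint must be positive")
  if ("area_mm2" %in% names(samples) && any(samples$area_mm2 <= 0)) {
    stop("areas must be positive")
  }
  per_sample <- lapply(seq_len(nrow(samples)), function(i) {
    sm <- samples$sample[i]
    cc <- calls[calls$sample == sm, , drop = FALSE]
    mb <- samples$footprint_bp[i] / 1e6
    sbs <- sum(cc$class %in% c("synonymous", "missense", "nonsense",
                               "essential_splice"))
    data.frame(sample = sm,
               sbs_per_mb = sbs / mb,
               dbs_per_mb = sum(cc$class == "DBS") / mb,
               indel_per_mb = sum(cc$class == "indel") / mb,
               density_per_mm2 = if ("area_mm2" %in% names(samples))
                 nrow(cc) / samples$area_mm2[i] else NA_real_,
               stringsAsFactors = FALSE)
  })
  ps <- do.call(rbind, per_sample)
  if (by == "sample") return(ps)
  grp_col <- if (by == "animal") "animal" else "tumor"
  stopifnot_cols(samples, grp_col, "sample table")
  grp <- samples[[grp_col]][match(ps$sample, samples$sample)]
  agg <- stats::aggregate(ps[, c("sbs_per_mb", "dbs_per_mb", "indel_per_mb",
                                 "density_per_mm2")],
                          by = list(unit = grp), FUN = mean)
  agg
}

#' Mutational spectrum summaries
#'
#' The 96-channel SBS spectrum (normalized to sum 1 when non-empty), the
#' DBS table, the fraction of SBS that are C>T, and the fraction of DBS
#' that are CC>TT.
#'
#' @param calls Annotated call data frame (channel and class columns).
#' @return List with \code{sbs96} (named numeric of length 96),
#'   \code{dbs} (table of doublet changes), \code{frac_CtoT},
#'   \code{frac_CCtoTT}.
#' @export
spectrum_summary <- function(calls) {
  ch <- sbs96_channels()
  snv <- calls[calls$class %in% c("synonymous", "missense", "nonsense",
                                  "essential_splice"), , drop = FALSE]
  counts <- table(factor(snv$channel, levels = ch))
  sbs96 <- as.numeric(counts)
  names(sbs96) <- ch
  if (sum(sbs96) > 0) sbs96 <- sbs96 / sum(sbs96)
  frac_ct <- if (nrow(snv)) mean(grepl("\\[C>T\\]", snv$channel)) else NA_real_
  dbs <- calls[calls$class == "DBS", , drop = FALSE]
  dbs_tab <- if (nrow(dbs)) table(paste0(dbs$ref, ">", dbs$alt)) else table(character(0))
  frac_cc <- if (nrow(dbs)) mean(dbs$ref == "CC" & dbs$alt == "TT") else NA_real_
  list(sbs96 = sbs96, dbs = dbs_tab, frac_CtoT = frac_ct,
       frac_CCtoTT = frac_cc)
}

#' Pearson correlation of two 96-channel spectra
#'
#' @param a,b Numeric vectors over the 96 SBS channels (any common
#'   ordering).
#' @return Pearson correlation coefficient.
#' @export
spectrum_cor <- function(a, b) stats::cor(as.numeric(a), as.numeric(b))
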