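# Multi-region tumor clonality: a priority-ordered rule classifier. A
# tumor is monoclonal when its slices share a founder clone (shared SNVs
# and/or a shared large CNA), multifocal when at least two slices carry
# independent clonal expansions. Rules are tested strictly in order;
# monoclonal rules first.

seg_len <- function(s) s$end - s$start

# Reciprocal overlap between two intervals on the same chromosome.
reciprocal_overlap <- function(a_start, a_end, b_start, b_end) {
  ov <- max(0, min(a_end, b_end) - max(a_start, b_start))
  min(ov / (a_end - a_start), ov / (b_end - b_start))
}

# Does 'seg' (one row) have a same-class >=50% reciprocal-overlap match in
# segment table 'tab'?
has_match <- function(seg, tab, min_ro = 0.5) {
  tt <- tab[tab$chrom == seg$chrom & tab$class == seg$class, , drop = FALSE]
  if (!nrow(tt)) return(FALSE)
  any(vapply(seq_len(nrow(tt)), function(j) {
    reciprocal_overlap(seg$start, seg$end, tt$start[j], tt$end[j]) >= min_ro
  }, logical(1)))
}

altered_only <- function(tab) {
  if (is.null(tab) || !nrow(tab)) return(tab[0, , drop = FALSE])
  tab[tab$class %in% c("gain", "loss"), , drop = FALSE]
}

# CNAs (> min_mb) of slice i shared by every other slice.
shared_cnas <- function(cna_list, min_mb = 10) {
  n <- length(cna_list)
  alts <- lapply(cna_list, altered_only)
  hits <- list()
  for (i in seq_len(n)) {
    a <- alts[[i]]
    if (is.null(a) || !nrow(a)) next
    big <- a[seg_len(a) > min_mb * 1e6, , drop = FALSE]
    for (r in seq_len(nrow(big))) {
      everywhere <- all(vapply(setdiff(seq_len(n), i), function(j) {
        aj <- alts[[j]]
        !is.null(aj) && nrow(aj) > 0 && has_match(big[r, ], aj)
      }, logical(1)))
      if (everywhere) hits[[length(hits) + 1L]] <- big[r, , drop = FALSE]
    }
  }
  if (length(hits)) do.call(rbind, hits) else NULL
}

# Private SNVs of each slice (present in no other slice).
private_snvs <- function(snv_sets) {
  lapply(seq_along(snv_sets), function(i) {
    others <- unique(unlist(snv_sets[-i]))
    setdiff(snv_sets[[i]], others)
  })
}

# Pairs of slices carrying separate clonal expansions: both with at least
# min_snvs SNVs and with disjoint SNV sets.
disjoint_pairs <- function(snv_sets, min_snvs) {
  n <- length(snv_sets)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (length(snv_sets[[i]]) >= min_snvs &&
          length(snv_sets[[j]]) >= min_snvs &&
          !length(intersect(snv_sets[[i]], snv_sets[[j]]))) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  out
}

# Big CNAs of slice i with no same-class match in slice j.
unmatched_big_cna <- function(cna_i, cna_j, min_mb = 10) {
  a <- altered_only(cna_i)
  if (is.null(a) || !nrow(a)) return(FALSE)
  big <- a[seg_len(a) > min_mb * 1e6, , drop = FALSE]
  aj <- altered_only(cna_j)
  for (r in seq_len(nrow(big))) {
    if (is.null(aj) || !nrow(aj) || !has_match(big[r, ], aj)) return(TRUE)
  }
  FALSE
}

any_big_cna <- function(cna_list, min_mb = 10) {
  any(vapply(cna_list, function(tab) {
    a <- altered_only(tab)
    !is.null(a) && nrow(a) > 0 && any(seg_len(a) > min_mb * 1e6)
  }, logical(1)))
}

#' Classify a multi-slice tumor as monoclonal or multifocal
#'
#' Tests the priority-ordered rules. Monoclonal: (M1) at least
#' \code{min_snvs} shared SNVs and at least one shared CNA larger than
#' \code{min_cna_mb} in all slices; (M2) at least \code{many_snvs} shared
#' SNVs in all slices; (M3) at least \code{min_snvs} shared SNVs after
#' excluding edge slices with no detected SNVs or CNAs; (M4) at least
#' \code{min_snvs} shared SNVs and no CNA larger than \code{min_cna_mb}
#' anywhere. Multifocal: (F1) no shared clonal SNVs or CNAs, and at least
#' two slices with separate (pairwise-disjoint) sets of at least
#' \code{min_snvs} SNVs and separate CNAs larger than \code{min_cna_mb};
#' (F2) at least two slices with separate sets of at least
#' \code{min_snvs} SNVs and no CNA larger
#' than \code{min_cna_mb} anywhere. Remaining tumors with at least two
#' separate \code{min_snvs}-SNV clonal expansions supported by SNVs are
#' multifocal by fallback (flagged for review); otherwise indeterminate.
#'
#' @param snv_sets List (one element per slice) of SNV identifiers
#'   (e.g. "chrom:pos:ref:alt" strings).
#' @param cna_sets List (one element per slice) of classed segment tables
#'   (chrom, start, end, class) or NULL.
#' @param tumor Tumor identifier.
#' @param min_snvs,many_snvs,min_cna_mb Rule thresholds (defaults 5, 20,
#'   10 Mb).
#' @return Object of class \code{"tumor_clonality"}: list with tumor,
#'   label (monoclonal/multifocal/indeterminate), rule (M1..M4, F1, F2,
#'   F-fallback, none), and evidence (shared SNV count, shared CNA
#'   lengths, per-slice private counts).
#' @export
classify_tumor <- function(snv_sets, cna_sets = NULL, tumor = "tumor",
                           min_snvs = 5, many_snvs = 20, min_cna_mb = 10) {
  n <- length(snv_sets)
  if (is.null(cna_sets)) cna_sets <- rep(list(NULL), n)
  result <- function(label, rule, shared, shared_cna, priv) {
    out <- list(tumor = tumor, label = label, rule = rule,
                evidence = list(shared_snvs = length(shared),
                                shared_cna_mb = if (!is.null(shared_cna))
                                  seg_len(shared_cna) / 1e6 else numeric(0),
                                private_snvs = vapply(priv, length, integer(1))))
    class(out) <- "tumor_clonality"
    out
  }
  priv <- private_snvs(snv_sets)
  if (n < 2) {
    return(result("indeterminate", "none", character(0), NULL, priv))
  }
  shared <- Reduce(intersect, snv_sets)
  sh_cna <- shared_cnas(cna_sets, min_cna_mb)
  big_any <- any_big_cna(cna_sets, min_cna_mb)

  # monoclonal rules, in order
  if (length(shared) >= min_snvs && !is.null(sh_cna)) {
    return(result("monoclonal", "M1", shared, sh_cna, priv))
  }
  if (length(shared) >= many_snvs) {
    return(result("monoclonal", "M2", shared, sh_cna, priv))
  }
  informative <- vapply(seq_len(n), function(i) {
    length(snv_sets[[i]]) > 0 ||
      (!is.null(cna_sets[[i]]) && nrow(altered_only(cna_sets[[i]])) > 0)
  }, logical(1))
  if (any(!informative) && sum(informative) >= 2) {
    shared_inf <- Reduce(intersect, snv_sets[informative])
    if (length(shared_inf) >= min_snvs) {
      return(result("monoclonal", "M3", shared_inf, sh_cna, priv))
    }
  }
  if (length(shared) >= min_snvs && !big_any) {
    return(result("monoclonal", "M4", shared, sh_cna, priv))
  }

  # multifocal rules, in order. "Separate sets" means pairwise-disjoint
  # SNV sets of at least min_snvs each.
  dp <- disjoint_pairs(snv_sets, min_snvs)
  if (length(shared) == 0 && is.null(sh_cna) && !is.null(dp)) {
    sep_cna <- apply(dp, 1, function(pr) {
      unmatched_big_cna(cna_sets[[pr[1]]], cna_sets[[pr[2]]], min_cna_mb) &&
        unmatched_big_cna(cna_sets[[pr[2]]], cna_sets[[pr[1]]], min_cna_mb)
    })
    if (any(sep_cna)) {
      return(result("multifocal", "F1", shared, sh_cna, priv))
    }
  }
  if (!is.null(dp) && !big_any) {
    return(result("multifocal", "F2", shared, sh_cna, priv))
  }
  # fallback: separate clonal expansions supported by SNVs, CNAs
  # conflicting or absent; flagged so a human can review
  if (!is.null(dp)) {
    return(result("multifocal", "F-fallback", shared, sh_cna, priv))
  }
  result("indeterminate", "none", shared, sh_cna, priv)
}

#' @export
print.tumor_clonality <- function(x, ...) {
  cat(sprintf("%s: %s (rule %s); shared SNVs %d; private SNVs per slice: %s\n",
              x$tumor, x$label, x$rule, x$evidence$shared_snvs,
              paste(x$evidence$private_snvs, collapse = "/")))
  invisible(x)
}

#' Classify several tumors from call and segment tables
#'
#' Convenience wrapper grouping a filtered-calls table and a classed
#' segment table by tumor and slice, then running
#' \code{\link{classify_tumor}} on each tumor.
#'
#' @param calls Call data frame with tumor, sample, chrom, pos, ref, alt.
#' @param segments Classed segment data frame with tumor, sample, chrom,
#'   start, end, class (or NULL).
#' @param ... Thresholds passed to \code{\link{classify_tumor}}.
#' @return Data frame: tumor, label, rule, shared_snvs.
#' @export
classify_tumors <- function(calls, segments = NULL, ...) {
  stopifnot_cols(calls, c("tumor", "sample", "chrom", "pos", "ref", "alt"),
                 "calls")
  rows <- lapply(unique(calls$tumor), function(tu) {
    cc <- calls[calls$tumor == tu, , drop = FALSE]
    slices <- sort(unique(cc$sample))
    snv_sets <- lapply(slices, function(s) {
      unique(call_key(cc[cc$sample == s, , drop = FALSE]))
    })
    cna_sets <- NULL
    if (!is.null(segments)) {
      sg <- segments[segments$tumor == tu, , drop = FALSE]
      slices <- sort(unique(c(slices, sg$sample)))
      snv_sets <- lapply(slices, function(s) {
        unique(call_key(cc[cc$sample == s, , drop = FALSE]))
      })
      cna_sets <- lapply(slices, function(s) {
        sg[sg$sample == s, c("chrom", "start", "end", "class"), drop = FALSE]
      })
    }
    cl <- classify_tumor(snv_sets, cna_sets, tumor = tu, ...)
    data.frame(tumor = tu, label = cl$label, rule = cl$rule,
               shared_snvs = cl$evidence$shared_snvs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
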