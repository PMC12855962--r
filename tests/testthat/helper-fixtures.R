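# Fixtures are built in code; nothing is read from disk.

# Minimal gene_set from explicit CDS strings (one single-exon gene per
# contig, with short flanks so every coding base has a trinucleotide
# context).
make_gene_set <- function(cds, flank = "GGAC") {
  genes <- names(cds)
  seqs <- vapply(cds, function(s) paste0(flank, s, flank), "")
  names(seqs) <- genes
  fl <- nchar(flank)
  gs <- list(
    genes = data.frame(gene = genes, chrom = genes, strand = "+",
                       cds_codons = nchar(cds) / 3, stringsAsFactors = FALSE),
    seq = seqs,
    exons = data.frame(gene = genes, exon = 1L, start = fl,
                       end = fl + nchar(cds), stringsAsFactors = FALSE),
    splice = data.frame(gene = character(0), pos = integer(0)))
  class(gs) <- "gene_set"
  gs
}

# A bare annotated call record.
make_call <- function(sample = "s1", chrom = "gene01", pos = 100,
                      ref = "C", alt = "T", class = "missense",
                      depth = 900, alt_fwd = 10, alt_rev = 10,
                      q = 0.001, gene = chrom) {
  data.frame(sample = sample, chrom = chrom, pos = pos, ref = ref,
             alt = alt, class = class, depth = depth, alt_fwd = alt_fwd,
             alt_rev = alt_rev, vaf = (alt_fwd + alt_rev) / depth,
             p = q / 2, q = q, gene = gene, stringsAsFactors = FALSE)
}

# Independent pyrimidine-channel collapse used by test oracles (kept
# separate from the package implementation on purpose).
oracle_channel <- function(up, ref, alt, dn) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (ref %in% c("A", "G")) {
    tmp <- up
    up <- comp[[dn]]; dn <- comp[[tmp]]
    ref <- comp[[ref]]; alt <- comp[[alt]]
  }
  paste0(up, "[", ref, ">", alt, "]", dn)
}

# Exhaustive expected-count oracle: loops over every coding position and
# alternative base, translating with seqinr (independent of the package's
# Biostrings-based path), plus splice positions.
oracle_expected_counts <- function(gs, spectrum) {
  bases <- c("A", "C", "G", "T")
  res <- list()
  for (gi in seq_len(nrow(gs$genes))) {
    g <- gs$genes$gene[gi]
    sq <- gs$seq[[g]]
    ex <- gs$exons[gs$exons$gene == g, , drop = FALSE]
    ex <- ex[order(ex$exon), ]
    gpos <- unlist(lapply(seq_len(nrow(ex)),
                          function(e) seq(ex$start[e], ex$end[e] - 1L)))
    cds <- paste(substring(sq, ex$start + 1, ex$end), collapse = "")
    ncod <- nchar(cds) %/% 3
    E <- c(synonymous = 0, missense = 0, non_splice = 0)
    for (ci in seq_len((ncod - 1) * 3)) {
      gp <- gpos[ci]
      ref <- substr(cds, ci, ci)
      aa_old <- seqinr::translate(strsplit(cds, "")[[1]])
      for (alt in setdiff(bases, ref)) {
        cds2 <- cds
        substr(cds2, ci, ci) <- alt
        aa_new <- seqinr::translate(strsplit(cds2, "")[[1]])
        k <- ceiling(ci / 3)
        cls <- if (aa_new[k] == aa_old[k]) "synonymous"
        else if (aa_new[k] == "*") "non_splice" else "missense"
        chn <- oracle_channel(substr(sq, gp, gp), ref, alt,
                              substr(sq, gp + 2, gp + 2))
        E[cls] <- E[cls] + spectrum$rates[[chn]]
      }
    }
    sp <- gs$splice[gs$splice$gene == g, , drop = FALSE]
    for (ppos in sp$pos) {
      ref <- substr(sq, ppos + 1, ppos + 1)
      for (alt in setdiff(bases, ref)) {
        chn <- oracle_channel(substr(sq, ppos, ppos), ref, alt,
                              substr(sq, ppos + 2, ppos + 2))
        E["non_splice"] <- E["non_splice"] + spectrum$rates[[chn]]
      }
    }
    res[[g]] <- E
  }
  res
}

# Uniform spectrum over all 96 channels.
uniform_spectrum <- function(rate = 1, indel_rate = 0) {
  sp <- list(rates = stats::setNames(rep(rate, 96), sbs96_channels()),
             opportunities = NULL, indel_rate = indel_rate)
  class(sp) <- "spectrum_model"
  sp
}

# Exhaustive two-tailed rank-sum p-value by enumerating all assignments of
# the pooled values to the two groups (no ties assumed).
perm_wilcox_p <- function(x, y) {
  pool <- c(x, y)
  n <- length(x)
  r_obs <- sum(rank(pool)[seq_len(n)])
  W_obs <- r_obs - n * (n + 1) / 2
  combos <- utils::combn(length(pool), n)
  W_all <- apply(combos, 2, function(ix) {
    sum(rank(pool)[ix]) - n * (n + 1) / 2
  })
  p <- 2 * min(mean(W_all <= W_obs), mean(W_all >= W_obs))
  min(p, 1)
}

# Brute-force re-application of the five written filter rules, kept
# deliberately naive and separate from the package implementation.
brute_force_filters <- function(calls, germline, min_depth = 100,
                                dbs_frac = 0.9, fdr_alpha = 0.05) {
  keep <- rep(TRUE, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    cc <- calls[i, ]
    if (cc$depth < min_depth) keep[i] <- FALSE
    if (!is.null(germline) && nrow(germline)) {
      for (j in seq_len(nrow(germline))) {
        gg <- germline[j, ]
        if (cc$chrom == gg$chrom && cc$pos == gg$pos &&
            cc$ref == gg$ref && cc$alt == gg$alt) keep[i] <- FALSE
      }
    }
    if (cc$alt_fwd < 1 || cc$alt_rev < 1) keep[i] <- FALSE
    if (!is.na(cc$q) && cc$q > fdr_alpha) keep[i] <- FALSE
  }
  surv <- calls[keep, ]
  # DBS merging on the survivors
  merged <- rep(FALSE, nrow(surv))
  for (i in seq_len(nrow(surv))) {
    for (j in seq_len(nrow(surv))) {
      if (i >= j || merged[i] || merged[j]) next
      a <- surv[i, ]; b <- surv[j, ]
      if (a$sample == b$sample && a$chrom == b$chrom &&
          abs(a$pos - b$pos) == 1 &&
          nchar(a$ref) == 1 && nchar(b$ref) == 1 &&
          a$alt != "-" && b$alt != "-") {
        alt_a <- a$alt_fwd + a$alt_rev; alt_b <- b$alt_fwd + b$alt_rev
        if (min(alt_a, alt_b) / max(alt_a, alt_b) >= dbs_frac) {
          merged[i] <- TRUE; merged[j] <- TRUE
        }
      }
    }
  }
  list(survivor_keys = sort(paste(surv$sample[!merged], surv$chrom[!merged],
                                  surv$pos[!merged], surv$alt[!merged])),
       n_dbs_merged = sum(merged) / 2)
}

fixture_calls <- function() {
  set.seed(88)
  n <- 50
  calls <- data.frame(
    sample = sample(c("s1", "s2", "s3"), n, replace = TRUE),
    chrom = sample(c("gA", "gB"), n, replace = TRUE),
    pos = sample(1:400, n),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = NA_character_,
    class = sample(c("synonymous", "missense", "nonsense"), n, replace = TRUE),
    depth = sample(c(60, 99, 100, 500, 930), n, replace = TRUE),
    alt_fwd = sample(0:20, n, replace = TRUE),
    alt_rev = sample(0:20, n, replace = TRUE),
    q = sample(c(0.001, 0.01, 0.2), n, replace = TRUE),
    stringsAsFactors = FALSE)
  calls$alt <- vapply(calls$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  # plant an adjacent high-joint-support pair and a germline hit
  calls[1, ] <- list("s1", "gA", 200, "C", "T", "missense", 500, 12, 13, 0.001)
  calls[2, ] <- list("s1", "gA", 201, "C", "T", "missense", 500, 12, 12, 0.001)
  calls[3, ] <- list("s2", "gB", 300, "G", "A", "nonsense", 930, 10, 10, 0.001)
  calls$vaf <- (calls$alt_fwd + calls$alt_rev) / calls$depth
  calls$p <- calls$q / 3
  calls
}

germline_fixture <- data.frame(chrom = "gB", pos = 300, ref = "G", alt = "A",
                               stringsAsFactors = FALSE)

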