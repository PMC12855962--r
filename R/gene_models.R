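# Synthetic gene models: random coding sequences with exon structure, used
# both to place simulated mutations and to compute mutational opportunities
# for selection analysis. Each gene lives on its own contig so coordinates
# never collide.

STOP_CODONS <- c("TAA", "TAG", "TGA")

genetic_code <- function() Biostrings::GENETIC_CODE

#' Generate a set of synthetic gene models
#'
#' Builds \code{n_genes} random coding sequences with a valid ATG start, no
#' internal stop codons and a terminal stop, split over \code{n_exons} exons
#' separated by random introns. The two intronic bases flanking every exon
#' boundary are recorded as essential splice sites.
#'
#' @param n_genes Number of genes (a cancer panel is typically ~74).
#' @param cds_length CDS length in codons (including the terminal stop);
#'   must be at least 10.
#' @param n_exons Exons per gene (>= 1; introns only exist for >= 2).
#' @param intron_length Intron length in bp.
#' @param flank Flanking bp of random sequence either side of the gene.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class \code{"gene_set"}: a list with elements
#'   \code{genes} (data frame: gene, chrom, strand, cds_codons),
#'   \code{seq} (named character vector of contig sequences),
#'   \code{exons} (data frame: gene, exon, start, end; 0-based half-open),
#'   \code{splice} (data frame: gene, pos; 0-based positions of essential
#'   splice bases).
#' @examples
#' gs <- generate_gene_models(3, cds_length = 50, seed = 1)
#' gs$genes
#' @export
generate_gene_models <- function(n_genes, cds_length = 300, n_exons = 2,
                                 intron_length = 150, flank = 30, seed = NULL) {
  if (cds_length < 10) stop("cds_length must be at least 10 codons")
  if (n_genes < 1) stop("n_genes must be positive")
  if (!is.null(seed)) set.seed(seed)
  code <- genetic_code()
  sense <- names(code)[!names(code) %in% STOP_CODONS]

  genes <- sprintf("gene%02d", seq_len(n_genes))
  seqs <- character(n_genes)
  names(seqs) <- genes
  exon_rows <- list()
  splice_rows <- list()

  for (i in seq_len(n_genes)) {
    cds <- paste0("ATG",
                  paste(sample(sense, cds_length - 2, replace = TRUE), collapse = ""),
                  sample(STOP_CODONS, 1))
    cds_nt <- nchar(cds)
    # split CDS into n_exons nearly equal pieces
    cuts <- round(seq(0, cds_nt, length.out = n_exons + 1))
    exon_seq <- substring(cds, head(cuts, -1) + 1, cuts[-1])
    introns <- replicate(max(n_exons - 1, 0),
                         paste(sample(BASES, intron_length, replace = TRUE),
                               collapse = ""))
    left <- paste(sample(BASES, flank, replace = TRUE), collapse = "")
    right <- paste(sample(BASES, flank, replace = TRUE), collapse = "")

    pieces <- character(0)
    pos <- nchar(left)   # 0-based cursor
    ex_start <- integer(n_exons); ex_end <- integer(n_exons)
    spl <- integer(0)
    pieces <- left
    for (e in seq_len(n_exons)) {
      ex_start[e] <- pos
      pieces <- c(pieces, exon_seq[e])
      pos <- pos + nchar(exon_seq[e])
      ex_end[e] <- pos
      if (e < n_exons) {
        # donor: first two intronic bases; acceptor: last two
        spl <- c(spl, pos, pos + 1L,
                 pos + intron_length - 2L, pos + intron_length - 1L)
        pieces <- c(pieces, introns[e])
        pos <- pos + intron_length
      }
    }
    pieces <- c(pieces, right)
    seqs[i] <- paste(pieces, collapse = "")
    exon_rows[[i]] <- data.frame(gene = genes[i], exon = seq_len(n_exons),
                                 start = ex_start, end = ex_end,
                                 stringsAsFactors = FALSE)
    if (length(spl)) {
      splice_rows[[i]] <- data.frame(gene = genes[i], pos = spl,
                                     stringsAsFactors = FALSE)
    }
  }

  out <- list(
    genes = data.frame(gene = genes, chrom = genes, strand = "+",
                       cds_codons = cds_length, stringsAsFactors = FALSE),
    seq = seqs,
    exons = do.call(rbind, exon_rows),
    splice = if (length(splice_rows)) do.call(rbind, splice_rows) else
      data.frame(gene = character(0), pos = integer(0))
  )
  class(out) <- "gene_set"
  out
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set: %d genes, %d codons each, footprint %d bp\n",
              nrow(x$genes), x$genes$cds_codons[1], footprint_bp(x)))
  invisible(x)
}

#' Sequenced footprint of a gene set
#'
#' Total length in bp of all gene contigs (the targeted territory used for
#' per-megabase burden calculations).
#' @param gs A \code{gene_set}.
#' @return Integer number of base pairs.
#' @export
footprint_bp <- function(gs) sum(nchar(gs$seq))

# Concatenated coding sequence of one gene (exons in order).
cds_sequence <- function(gs, gene) {
  ex <- gs$exons[gs$exons$gene == gene, , drop = FALSE]
  sq <- gs$seq[[gene]]
  paste(substring(sq, ex$start + 1, ex$end), collapse = "")
}

# Map 0-based CDS indices to 0-based genomic positions for one gene.
cds_to_genomic <- function(gs, gene) {
  ex <- gs$exons[gs$exons$gene == gene, , drop = FALSE]
  unlist(lapply(seq_len(nrow(ex)), function(e) seq(ex$start[e], ex$end[e] - 1L)),
         use.names = FALSE)
}

#' Enumerate every possible single-base substitution in a gene set
#'
#' Lists all 3L substitutions at coding positions of each gene (the terminal
#' stop codon is excluded) plus the three substitutions at every essential
#' splice base, with their trinucleotide channel and consequence class.
#' This table is the backbone of both mutation placement in the simulator
#' and expected-count computation for selection analysis.
#'
#' @param gs A \code{gene_set}.
#' @return Data frame with columns gene, chrom, pos (0-based), ref, alt,
#'   channel, class (synonymous / missense / nonsense / essential_splice).
#' @export
enumerate_substitutions <- function(gs) {
  code <- genetic_code()
  out <- vector("list", nrow(gs$genes))
  for (i in seq_len(nrow(gs$genes))) {
    g <- gs$genes$gene[i]
    sq <- gs$seq[[g]]
    cds <- cds_sequence(gs, g)
    gpos <- cds_to_genomic(gs, g)
    ncodon <- nchar(cds) %/% 3L
    keep <- seq_len((ncodon - 1L) * 3L)     # drop terminal stop codon
    cidx <- keep - 1L                        # 0-based CDS index
    gp <- gpos[keep]
    refs <- substring(cds, keep, keep)
    codon_i <- cidx %/% 3L
    in_codon <- cidx %% 3L
    codons <- substring(cds, codon_i * 3L + 1L, codon_i * 3L + 3L)
    aa_old <- unname(code[codons])
    up <- substring(sq, gp, gp)              # 0-based gp-1 .. (substr is 1-based)
    dn <- substring(sq, gp + 2L, gp + 2L)

    rows <- lapply(1:3, function(k) {
      alts <- vapply(refs, function(r) setdiff(BASES, r)[k], "")
      newcod <- codons
      substr(newcod, in_codon + 1L, in_codon + 1L) <- alts
      aa_new <- unname(code[newcod])
      cls <- ifelse(aa_new == aa_old, "synonymous",
                    ifelse(aa_new == "*", "nonsense", "missense"))
      data.frame(gene = g, chrom = g, pos = gp, ref = refs, alt = unname(alts),
                 channel = sbs_channel(up, refs, unname(alts), dn),
                 class = cls, stringsAsFactors = FALSE, row.names = NULL)
    })
    df <- do.call(rbind, rows)

    sp <- gs$splice[gs$splice$gene == g, , drop = FALSE]
    if (nrow(sp)) {
      spos <- sp$pos
      sref <- substring(sq, spos + 1L, spos + 1L)
      sup <- substring(sq, spos, spos)
      sdn <- substring(sq, spos + 2L, spos + 2L)
      srows <- lapply(1:3, function(k) {
        alts <- vapply(sref, function(r) setdiff(BASES, r)[k], "")
        data.frame(gene = g, chrom = g, pos = spos, ref = sref,
                   alt = unname(alts),
                   channel = sbs_channel(sup, sref, unname(alts), sdn),
                   class = "essential_splice", stringsAsFactors = FALSE,
                   row.names = NULL)
      })
      df <- rbind(df, do.call(rbind, srows))
    }
    out[[i]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Translate a CDS string with the standard code; used for validity checks.
translate_cds <- function(cds) {
  n <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
  paste(unname(genetic_code()[codons]), collapse = "")
}

#' Write gene models to FASTA + exon table
#'
#' @param gs A \code{gene_set}.
#' @param fasta Path for the contig FASTA.
#' @param exons_tsv Path for the exon interval TSV (1-based inclusive).
#' @return Invisibly, the paths written.
#' @export
write_gene_models <- function(gs, fasta, exons_tsv) {
  ss <- Biostrings::DNAStringSet(gs$seq)
  Biostrings::writeXStringSet(ss, fasta)
  ex <- gs$exons
  ex$start <- ex$start + 1L   # to 1-based inclusive
  ex <- merge(ex, gs$genes[, c("gene", "strand", "cds_codons")], by = "gene")
  utils::write.table(ex[order(ex$gene, ex$exon), ], exons_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(fasta, exons_tsv))
}

#' Read gene models written by \code{write_gene_models}
#'
#' @param fasta,exons_tsv Paths as written by \code{\link{write_gene_models}}.
#' @return A \code{gene_set}.
#' @export
read_gene_models <- function(fasta, exons_tsv) {
  ss <- Biostrings::readDNAStringSet(fasta)
  seqs <- as.character(ss)
  ex <- utils::read.delim(exons_tsv, stringsAsFactors = FALSE)
  stopifnot_cols(ex, c("gene", "exon", "start", "end", "strand", "cds_codons"),
                 "exon table")
  genes <- unique(ex[, c("gene", "strand", "cds_codons")])
  ex$start <- ex$start - 1L   # back to 0-based half-open
  gs <- list(
    genes = data.frame(gene = genes$gene, chrom = genes$gene,
                       strand = genes$strand, cds_codons = genes$cds_codons,
                       stringsAsFactors = FALSE),
    seq = seqs,
    exons = ex[, c("gene", "exon", "start", "end")],
    splice = NULL
  )
  # splice sites are implied by exon boundaries (2 intronic bases each side)
  spl <- list()
  for (g in genes$gene) {
    e <- ex[ex$gene == g, , drop = FALSE]
    e <- e[order(e$exon), ]
    if (nrow(e) > 1) {
      pos <- integer(0)
      for (j in seq_len(nrow(e) - 1)) {
        pos <- c(pos, e$end[j], e$end[j] + 1L, e$start[j + 1] - 2L, e$start[j + 1] - 1L)
      }
      spl[[g]] <- data.frame(gene = g, pos = pos, stringsAsFactors = FALSE)
    }
  }
  gs$splice <- if (length(spl)) do.call(rbind, spl) else
    data.frame(gene = character(0), pos = integer(0))
  rownames(gs$splice) <- NULL
  class(gs) <- "gene_set"
  gs
}
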