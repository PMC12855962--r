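# Synthetic-data generator. Emulates the statistical structure of deep
# targeted sequencing of UV-exposed mouse epidermis (1-2 mm^2 grids at
# ~931x) and multi-slice tumors: a UV mutation spectrum dominated by C>T at
# dipyrimidines with CC>TT doublets, clone sizes drawn from an exponential
# law (inflated for positively selected gene classes), binomial read
# sampling with strand split, a beta-binomial background-error panel, and
# chromosome-scale copy-number events. Every output carries a ground-truth
# record so downstream estimators can be validated.

#' Simulation parameters
#'
#' Validated container of generator settings. Defaults reflect the targeted
#' sequencing study conditions this package models: ~931x median depth, a
#' 74-gene cancer panel, a UV spectrum with ~85\% C>T and 35\% of double-base
#' substitutions being CC>TT, and 1-2 mm^2 epidermal grids.
#'
#' @param seed Master integer seed; all stage streams derive from it.
#' @param n_grids Number of epidermal grid samples.
#' @param grid_area Area of each grid in mm^2.
#' @param depth_mean Mean sequencing depth (reads).
#' @param panel_footprint Targeted footprint in bp (default: taken from the
#'   gene models at simulation time).
#' @param sbs_rate Single-base substitutions per Mb per grid.
#' @param frac_CtoT Fraction of SBS that are C>T at dipyrimidines.
#' @param dbs_rate Double-base substitutions per Mb per grid.
#' @param frac_CCtoTT_of_DBS Fraction of DBS that are CC>TT.
#' @param indel_rate Indels per Mb per grid.
#' @param seq_error_rate Per-base per-substitution sequencing error rate.
#' @param error_rho Beta-binomial overdispersion of the error process.
#' @param clone_mean_frac Mean cell fraction of a neutral clone.
#' @param zygosity 1 for heterozygous clones (VAF = cf/2), 2 for homozygous.
#' @param gene_fitness Named list mapping gene to a named numeric vector of
#'   per-class selection coefficients s; selected classes are enriched
#'   exp(s)-fold in detected mutation counts and in mean clone size.
#' @param n_tumor_slices Slices per simulated tumor (>= 2).
#' @param n_founder_snvs SNVs carried by each tumor founder clone.
#' @param cna_events Data frame (chrom, start, end, cn) of founder
#'   copy-number events; coordinates in bp, 0-based half-open.
#' @param timepoints Weeks of UV exposure represented among the grids.
#' @return An object of class \code{"sim_params"} (a validated list).
#' @examples
#' p <- sim_params(seed = 1, n_grids = 4)
#' @export
sim_params <- function(seed = 1L,
                       n_grids = 40,
                       grid_area = 1.5,
                       depth_mean = 931,
                       panel_footprint = NULL,
                       sbs_rate = 30,
                       frac_CtoT = 0.85,
                       dbs_rate = 0.7,
                       frac_CCtoTT_of_DBS = 0.35,
                       indel_rate = 0.15,
                       seq_error_rate = 1e-4,
                       error_rho = 1e-3,
                       clone_mean_frac = 0.01,
                       zygosity = 1,
                       gene_fitness = list(),
                       n_tumor_slices = 3,
                       n_founder_snvs = 8,
                       cna_events = data.frame(chrom = "chr2", start = 0,
                                               end = 15e6, cn = 3),
                       timepoints = c(8, 16, 24)) {
  p <- list(seed = as.integer(seed), n_grids = n_grids, grid_area = grid_area,
            depth_mean = depth_mean, panel_footprint = panel_footprint,
            sbs_rate = sbs_rate, frac_CtoT = frac_CtoT, dbs_rate = dbs_rate,
            frac_CCtoTT_of_DBS = frac_CCtoTT_of_DBS, indel_rate = indel_rate,
            seq_error_rate = seq_error_rate, error_rho = error_rho,
            clone_mean_frac = clone_mean_frac, zygosity = zygosity,
            gene_fitness = gene_fitness, n_tumor_slices = n_tumor_slices,
            n_founder_snvs = n_founder_snvs, cna_events = cna_events,
            timepoints = timepoints)
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  num <- c("n_grids", "grid_area", "depth_mean", "sbs_rate", "frac_CtoT",
           "dbs_rate", "frac_CCtoTT_of_DBS", "indel_rate", "seq_error_rate",
           "error_rho", "clone_mean_frac", "n_tumor_slices")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      stop(sprintf("sim_params: '%s' must be a finite non-negative number", f))
    }
  }
  for (f in c("frac_CtoT", "frac_CCtoTT_of_DBS", "seq_error_rate", "error_rho")) {
    if (p[[f]] > 1) stop(sprintf("sim_params: '%s' must lie in [0, 1]", f))
  }
  if (p$depth_mean <= 0) stop("sim_params: depth_mean must be positive")
  if (p$grid_area <= 0) stop("sim_params: grid_area must be positive")
  if (!p$zygosity %in% c(1, 2)) stop("sim_params: zygosity must be 1 or 2")
  invisible(p)
}

# Per-row sampling weights over the enumeration table: C>T channels carry
# total mass frac_CtoT, with dipyrimidine contexts preferred 4:1 within
# the class (UV photoproduct spectrum); the remainder is spread over all
# other substitutions. Selected gene classes are re-weighted exp(s)-fold.
uv_row_weights <- function(enum, frac_CtoT, gene_fitness) {
  ct <- grepl("\\[C>T\\]", enum$channel)
  dipyr <- substr(enum$channel, 1, 1) %in% c("C", "T") |
    substr(enum$channel, 7, 7) %in% c("C", "T")
  w <- numeric(nrow(enum))
  if (any(ct)) {
    wct <- ifelse(dipyr[ct], 4, 1)
    w[ct] <- frac_CtoT * wct / sum(wct)
  }
  if (any(!ct)) w[!ct] <- (1 - frac_CtoT) / sum(!ct)
  if (length(gene_fitness)) {
    for (g in names(gene_fitness)) {
      s <- gene_fitness[[g]]
      for (cl in names(s)) {
        sel <- enum$gene == g & enum$class == cl
        w[sel] <- w[sel] * exp(s[[cl]])
      }
    }
  }
  w
}

fitness_of <- function(gene_fitness, gene, cls) {
  s <- gene_fitness[[gene]]
  if (is.null(s) || is.na(match(cls, names(s)))) 0 else s[[cls]]
}

true_gene_classes <- function(genes, gene_fitness) {
  lab <- setNames(rep("neutral", length(genes)), genes)
  for (g in names(gene_fitness)) {
    s <- gene_fitness[[g]][setdiff(names(gene_fitness[[g]]), "synonymous")]
    if (!length(s)) next
    if (any(s > 0)) lab[g] <- "positive" else if (any(s < 0)) lab[g] <- "negative"
  }
  lab
}

# Draw read support for a set of true VAFs: depth, alt (clone + error
# reads, capped at depth), and an unbiased strand split.
draw_reads <- function(vaf, depth_mean, err) {
  n <- length(vaf)
  depth <- stats::rpois(n, depth_mean)
  depth[depth == 0] <- 1L
  alt <- stats::rbinom(n, depth, pmin(vaf, 1)) + stats::rbinom(n, depth, err)
  alt <- pmin(alt, depth)
  fwd <- stats::rbinom(n, alt, 0.5)
  data.frame(depth = depth, alt_fwd = fwd, alt_rev = alt - fwd)
}

#' Simulate an epidermal grid experiment
#'
#' Each grid sample receives a Poisson number of single-base substitutions
#' (mean \code{sbs_rate} x footprint in Mb), placed over the gene models
#' according to a UV-like spectrum; clone cell fractions follow an
#' exponential law whose mean is inflated exp(s)-fold for selected gene
#' classes. Double-base substitutions and indels are added at their own
#' rates. Read support is binomial at Poisson depth with an unbiased strand
#' split plus independent error reads.
#'
#' @param params A \code{\link{sim_params}} object.
#' @param genes Optional \code{gene_set}; generated from the master seed
#'   when absent (74 genes of 300 codons).
#' @param enum Optional precomputed \code{\link{enumerate_substitutions}}
#'   table for \code{genes}.
#' @return A list of class \code{"epidermis_sim"} with elements
#'   \code{samples} (grid table), \code{counts} (site read-count table),
#'   \code{truth} (clone-level ground truth), and \code{genes}.
#' @export
simulate_epidermis <- function(params, genes = NULL, enum = NULL) {
  validate_sim_params(params)
  if (is.null(genes)) {
    genes <- generate_gene_models(74, 300, seed = stage_seed(params$seed, "genes"))
  }
  if (is.null(enum)) enum <- enumerate_substitutions(genes)
  set.seed(stage_seed(params$seed, "epidermis"))

  fp <- params$panel_footprint %||% footprint_bp(genes)
  fp_mb <- fp / 1e6
  n_tp <- length(params$timepoints)
  samples <- data.frame(
    sample = sprintf("grid%03d", seq_len(params$n_grids)),
    animal = sprintf("m%d", ((seq_len(params$n_grids) - 1) %% 4) + 1),
    timepoint = params$timepoints[pmin(
      ceiling(seq_len(params$n_grids) / max(1, params$n_grids / n_tp)), n_tp)],
    tissue = "dorsal",
    area_mm2 = params$grid_area,
    footprint_bp = fp,
    stringsAsFactors = FALSE
  )

  w <- uv_row_weights(enum, params$frac_CtoT, params$gene_fitness)
  clones <- list()
  counts <- list()
  clone_id <- 0L
  for (i in seq_len(nrow(samples))) {
    sm <- samples$sample[i]
    n_sbs <- stats::rpois(1, params$sbs_rate * fp_mb)
    rows <- if (n_sbs > 0 && sum(w) > 0)
      sample.int(nrow(enum), n_sbs, replace = TRUE, prob = w) else integer(0)
    recs <- list()
    if (length(rows)) {
      mut <- enum[rows, , drop = FALSE]
      s_size <- mapply(fitness_of, mut$gene, mut$class,
                       MoreArgs = list(gene_fitness = params$gene_fitness))
      cf <- pmin(stats::rexp(n_sbs, rate = 1 /
                               (params$clone_mean_frac * exp(s_size))), 1)
      vaf <- pmin(params$zygosity * cf / 2, 1)
      recs[[length(recs) + 1L]] <- data.frame(
        sample = sm, chrom = mut$chrom, pos = mut$pos, ref = mut$ref,
        alt = mut$alt, class = mut$class, cell_fraction = cf,
        stringsAsFactors = FALSE)
    }
    # DBS: CC>TT with probability frac_CCtoTT_of_DBS, otherwise a random
    # doublet; placed at a random dinucleotide of the gene contigs.
    n_dbs <- stats::rpois(1, params$dbs_rate * fp_mb)
    if (n_dbs > 0) {
      g <- sample(genes$genes$gene, n_dbs, replace = TRUE)
      dpos <- integer(n_dbs); dref <- character(n_dbs); dalt <- character(n_dbs)
      for (k in seq_len(n_dbs)) {
        sq <- genes$seq[[g[k]]]
        is_cc <- stats::runif(1) < params$frac_CCtoTT_of_DBS
        if (is_cc) {
          hits <- gregexpr("CC", sq)[[1]]
          if (hits[1] > 0) {
            p1 <- hits[sample.int(length(hits), 1)]
            dpos[k] <- p1 - 1L; dref[k] <- "CC"; dalt[k] <- "TT"
            next
          }
        }
        repeat {
          p1 <- sample.int(nchar(sq) - 1L, 1)
          dref[k] <- substr(sq, p1, p1 + 1)
          if (dref[k] != "CC") break
        }
        dpos[k] <- p1 - 1L
        dalt[k] <- paste0(sample(setdiff(BASES, substr(dref[k], 1, 1)), 1),
                          sample(setdiff(BASES, substr(dref[k], 2, 2)), 1))
      }
      cf <- pmin(stats::rexp(n_dbs, 1 / params$clone_mean_frac), 1)
      recs[[length(recs) + 1L]] <- data.frame(
        sample = sm, chrom = g, pos = dpos, ref = dref, alt = dalt,
        class = "DBS", cell_fraction = cf, stringsAsFactors = FALSE)
    }
    n_ind <- stats::rpois(1, params$indel_rate * fp_mb)
    if (n_ind > 0) {
      rows2 <- sample.int(nrow(enum), n_ind, replace = TRUE)
      cf <- pmin(stats::rexp(n_ind, 1 / params$clone_mean_frac), 1)
      recs[[length(recs) + 1L]] <- data.frame(
        sample = sm, chrom = enum$chrom[rows2], pos = enum$pos[rows2],
        ref = enum$ref[rows2], alt = "-", class = "indel",
        cell_fraction = cf, stringsAsFactors = FALSE)
    }
    if (!length(recs)) next
    rec <- do.call(rbind, recs)
    rec$zygosity <- params$zygosity
    rec$vaf_true <- pmin(rec$zygosity * rec$cell_fraction / 2, 1)
    rec$clone <- sprintf("c%06d", clone_id + seq_len(nrow(rec)))
    clone_id <- clone_id + nrow(rec)
    rd <- draw_reads(rec$vaf_true, params$depth_mean, params$seq_error_rate)
    counts[[length(counts) + 1L]] <- cbind(
      rec[, c("sample", "chrom", "pos", "ref", "alt")], rd)
    clones[[length(clones) + 1L]] <- rec
  }
  clones <- if (length(clones)) do.call(rbind, clones) else
    empty_truth_clones()
  counts <- if (length(counts)) do.call(rbind, counts) else
    empty_counts()
  rownames(clones) <- rownames(counts) <- NULL
  out <- list(samples = samples, counts = counts,
              truth = list(clones = clones,
                           gene_class = true_gene_classes(genes$genes$gene,
                                                          params$gene_fitness),
                           cna = NULL, clonality = NA_character_),
              genes = genes)
  class(out) <- "epidermis_sim"
  out
}

empty_counts <- function() {
  data.frame(sample = character(0), chrom = character(0), pos = integer(0),
             ref = character(0), alt = character(0), depth = integer(0),
             alt_fwd = integer(0), alt_rev = integer(0),
             stringsAsFactors = FALSE)
}

empty_truth_clones <- function() {
  data.frame(sample = character(0), chrom = character(0), pos = integer(0),
             ref = character(0), alt = character(0), class = character(0),
             cell_fraction = numeric(0), zygosity = numeric(0),
             vaf_true = numeric(0), clone = character(0),
             stringsAsFactors = FALSE)
}

#' Simulate a multi-slice tumor
#'
#' A monoclonal tumor plants one founder clone -- a shared SNV set at high
#' cell fraction plus the founder copy-number events -- in every slice, with
#' private low-frequency subclones per slice. A multifocal tumor plants two
#' founders with disjoint SNV sets (and copy-number events on different
#' chromosomes) in disjoint slice subsets.
#'
#' @param params A \code{\link{sim_params}} object (\code{n_tumor_slices >= 2}).
#' @param architecture \code{"monoclonal"} or \code{"multifocal"}.
#' @param genes,enum As in \code{\link{simulate_epidermis}}.
#' @param tumor Tumor identifier used in sample names.
#' @return List of class \code{"tumor_sim"}: \code{samples} (slice table),
#'   \code{counts}, \code{bins} (binned coverage per slice for CNA calling),
#'   \code{truth} (founder SNV sets, CNA segments, intended clonality label),
#'   \code{genes}.
#' @export
simulate_tumor <- function(params, architecture = c("monoclonal", "multifocal"),
                           genes = NULL, enum = NULL, tumor = "tumor1") {
  validate_sim_params(params)
  architecture <- match.arg(architecture)
  if (params$n_tumor_slices < 2) {
    stop("simulate_tumor requires at least 2 slices")
  }
  if (is.null(genes)) {
    genes <- generate_gene_models(74, 300, seed = stage_seed(params$seed, "genes"))
  }
  if (is.null(enum)) enum <- enumerate_substitutions(genes)
  set.seed(stage_seed(params$seed, "tumor"))

  n_sl <- params$n_tumor_slices
  fp <- params$panel_footprint %||% footprint_bp(genes)
  samples <- data.frame(
    sample = sprintf("%s_s%d", tumor, seq_len(n_sl)),
    tumor = tumor, slice = seq_len(n_sl), animal = "m1",
    area_mm2 = params$grid_area, footprint_bp = fp, stringsAsFactors = FALSE)

  w <- uv_row_weights(enum, params$frac_CtoT, params$gene_fitness)
  pick_snvs <- function(n, exclude = integer(0)) {
    ok <- setdiff(seq_len(nrow(enum)), exclude)
    ok[sample.int(length(ok), n, prob = w[ok])]
  }

  founders <- list()
  if (architecture == "monoclonal") {
    founders[[1]] <- list(rows = pick_snvs(params$n_founder_snvs),
                          slices = seq_len(n_sl), cna = params$cna_events)
  } else {
    r1 <- pick_snvs(params$n_founder_snvs)
    r2 <- pick_snvs(params$n_founder_snvs, exclude = r1)
    half <- max(1L, floor(n_sl / 2))
    cna1 <- params$cna_events
    # second founder gets events shifted to a different chromosome
    cna2 <- params$cna_events
    cna2$chrom <- "chr3"
    founders[[1]] <- list(rows = r1, slices = seq_len(half), cna = cna1)
    founders[[2]] <- list(rows = r2, slices = seq((half + 1), n_sl), cna = cna2)
  }

  clones <- list(); counts <- list()
  clone_id <- 0L
  purity <- stats::runif(n_sl, 0.7, 0.9)
  for (f in seq_along(founders)) {
    fo <- founders[[f]]
    mut <- enum[fo$rows, , drop = FALSE]
    for (sl in fo$slices) {
      cf <- purity[sl]
      rec <- data.frame(sample = samples$sample[sl], chrom = mut$chrom,
                        pos = mut$pos, ref = mut$ref, alt = mut$alt,
                        class = mut$class, cell_fraction = cf,
                        zygosity = params$zygosity, stringsAsFactors = FALSE)
      rec$vaf_true <- pmin(rec$zygosity * rec$cell_fraction / 2, 1)
      rec$clone <- sprintf("founder%d", f)
      rd <- draw_reads(rec$vaf_true, params$depth_mean, params$seq_error_rate)
      counts[[length(counts) + 1L]] <- cbind(
        rec[, c("sample", "chrom", "pos", "ref", "alt")], rd)
      clones[[length(clones) + 1L]] <- rec
    }
  }
  # private subclones per slice
  used <- unlist(lapply(founders, `[[`, "rows"))
  for (sl in seq_len(n_sl)) {
    n_priv <- stats::rpois(1, 3)
    if (n_priv == 0) next
    rows <- pick_snvs(n_priv, exclude = used)
    used <- c(used, rows)
    mut <- enum[rows, , drop = FALSE]
    cf <- pmin(stats::rexp(n_priv, 1 / 0.05), purity[sl])
    rec <- data.frame(sample = samples$sample[sl], chrom = mut$chrom,
                      pos = mut$pos, ref = mut$ref, alt = mut$alt,
                      class = mut$class, cell_fraction = cf,
                      zygosity = params$zygosity, stringsAsFactors = FALSE)
    rec$vaf_true <- pmin(rec$zygosity * rec$cell_fraction / 2, 1)
    rec$clone <- sprintf("priv_s%d_%03d", sl, seq_len(n_priv))
    clone_id <- clone_id + n_priv
    rd <- draw_reads(rec$vaf_true, params$depth_mean, params$seq_error_rate)
    counts[[length(counts) + 1L]] <- cbind(
      rec[, c("sample", "chrom", "pos", "ref", "alt")], rd)
    clones[[length(clones) + 1L]] <- rec
  }

  truth_cna <- do.call(rbind, lapply(seq_along(founders), function(f) {
    ev <- founders[[f]]$cna
    if (is.null(ev) || !nrow(ev)) return(NULL)
    cbind(ev, founder = f, slices = paste(founders[[f]]$slices, collapse = ","))
  }))

  bins <- do.call(rbind, lapply(seq_len(n_sl), function(sl) {
    evs <- do.call(rbind, lapply(founders, function(fo) {
      if (sl %in% fo$slices) fo$cna else NULL
    }))
    b <- simulate_coverage_bins(cna_events = evs, purity = purity[sl])
    cbind(sample = samples$sample[sl], b, stringsAsFactors = FALSE)
  }))

  out <- list(samples = samples,
              counts = do.call(rbind, counts),
              bins = bins,
              truth = list(clones = do.call(rbind, clones),
                           founder_snvs = lapply(founders, function(fo)
                             with(enum[fo$rows, ],
                                  paste(chrom, pos, ref, alt, sep = ":"))),
                           cna = truth_cna,
                           clonality = architecture),
              genes = genes)
  rownames(out$counts) <- rownames(out$truth$clones) <- NULL
  class(out) <- "tumor_sim"
  out
}

#' Simulate binned coverage for copy-number analysis
#'
#' Tumor and matched-normal read counts over a fixed 100 Kb bin grid with a
#' linear GC confound; copy-number events scale the tumor counts by
#' \code{(2(1 - purity) + purity * cn) / 2}.
#'
#' @param cna_events Data frame (chrom, start, end, cn) or NULL for a flat
#'   genome.
#' @param purity Tumor cell fraction carrying the events.
#' @param chrom_sizes Named vector of chromosome lengths in bp.
#' @param bin_size Bin width in bp (100 Kb by default).
#' @param base_depth Mean reads per bin in the normal.
#' @param gc_coef Slope of the linear GC effect on coverage.
#' @return Data frame: chrom, start, end (0-based half-open), gc,
#'   tumor_count, normal_count.
#' @export
simulate_coverage_bins <- function(cna_events = NULL, purity = 0.8,
                                   chrom_sizes = c(chr1 = 60e6, chr2 = 60e6,
                                                   chr3 = 60e6),
                                   bin_size = 1e5, base_depth = 100,
                                   gc_coef = 2) {
  out <- lapply(names(chrom_sizes), function(ch) {
    n <- floor(chrom_sizes[[ch]] / bin_size)
    start <- (seq_len(n) - 1) * bin_size
    gc <- stats::runif(n, 0.35, 0.6)
    gcf <- pmax(1 + gc_coef * (gc - 0.45), 0.1)
    cnf <- rep(1, n)
    if (!is.null(cna_events) && nrow(cna_events)) {
      ev <- cna_events[cna_events$chrom == ch, , drop = FALSE]
      for (j in seq_len(nrow(ev))) {
        hit <- start >= ev$start[j] & start < ev$end[j]
        cnf[hit] <- (2 * (1 - purity) + purity * ev$cn[j]) / 2
      }
    }
    data.frame(chrom = ch, start = start, end = start + bin_size, gc = gc,
               tumor_count = stats::rpois(n, base_depth * gcf * cnf),
               normal_count = stats::rpois(n, base_depth * gcf),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a panel of normal samples
#'
#' Pure sequencing error: per site and substitution, alt counts follow a
#' beta-binomial with mean \code{seq_error_rate} and overdispersion
#' \code{error_rho}; no somatic variants are planted.
#'
#' @param params A \code{\link{sim_params}} object.
#' @param n_normals Number of normal samples (>= 2).
#' @param sites Data frame (chrom, pos, ref) of sites to cover; defaults to
#'   \code{n_sites} positions drawn from the gene models.
#' @param genes Optional \code{gene_set} used when \code{sites} is NULL.
#' @param n_sites Number of sites when drawing from the gene models.
#' @return Read-count data frame: sample, chrom, pos, ref, alt, depth,
#'   alt_fwd, alt_rev -- one row per normal, site and alternative base.
#' @export
simulate_background_panel <- function(params, n_normals, sites = NULL,
                                      genes = NULL, n_sites = 100) {
  validate_sim_params(params)
  if (n_normals < 2) stop("a panel requires at least 2 normal samples")
  set.seed(stage_seed(params$seed, "panel"))
  if (is.null(sites)) {
    if (is.null(genes)) {
      genes <- generate_gene_models(74, 300,
                                    seed = stage_seed(params$seed, "genes"))
    }
    enum <- enumerate_substitutions(genes)
    u <- unique(enum[, c("chrom", "pos", "ref")])
    sites <- u[sample.int(nrow(u), min(n_sites, nrow(u))), , drop = FALSE]
  }
  sites <- sites[nchar(sites$ref) == 1, , drop = FALSE]  # SNV sites only
  alts <- t(vapply(sites$ref, function(r) setdiff(BASES, r), character(3)))
  grid <- data.frame(
    chrom = rep(sites$chrom, each = 3),
    pos = rep(sites$pos, each = 3),
    ref = rep(sites$ref, each = 3),
    alt = as.vector(t(alts)),
    stringsAsFactors = FALSE)
  out <- lapply(seq_len(n_normals), function(i) {
    depth <- stats::rpois(nrow(grid), params$depth_mean)
    depth[depth == 0] <- 1L
    alt <- if (params$seq_error_rate > 0)
      rbetabinom(nrow(grid), depth, params$seq_error_rate, params$error_rho)
    else rep(0L, nrow(grid))
    fwd <- stats::rbinom(nrow(grid), alt, 0.5)
    cbind(data.frame(sample = sprintf("normal%02d", i),
                     stringsAsFactors = FALSE),
          grid,
          data.frame(depth = depth, alt_fwd = fwd, alt_rev = alt - fwd))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
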