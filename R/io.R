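# On-disk formats. All files are 1-based inclusive; in-memory tables are
# 0-based half-open. The variant TSV dialect has exactly the columns
# sample, chrom, pos, ref, alt, class, depth, alt_fwd, alt_rev, vaf, p, q.

VARIANT_COLS <- c("sample", "chrom", "pos", "ref", "alt", "class", "depth",
                  "alt_fwd", "alt_rev", "vaf", "p", "q")

#' Write variant calls
#'
#' @param calls Call data frame (0-based positions in memory).
#' @param path Output path.
#' @param dialect \code{"tsv"} (the package's 12-column dialect) or
#'   \code{"vcf"} (single-sample VCF with GT:AD:DP).
#' @return Invisibly, \code{path}.
#' @export
write_variants <- function(calls, path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  x <- calls
  for (cl in VARIANT_COLS) if (!cl %in% names(x)) x[[cl]] <- NA
  x <- x[, VARIANT_COLS, drop = FALSE]
  x$pos <- x$pos + 1L  # 1-based inclusive on disk
  if (dialect == "tsv") {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  sm <- unique(x$sample)
  if (length(sm) != 1) stop("VCF output is single-sample; got ", length(sm))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sm))
  alt_n <- x$alt_fwd + x$alt_rev
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD:DP\t0/1:%d,%d:%d",
                  x$chrom, x$pos, x$ref, x$alt,
                  x$depth - alt_n, alt_n, x$depth)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read variant calls
#'
#' Reads the package TSV dialect or a single-sample VCF with AD/DP fields;
#' positions are converted to the in-memory 0-based convention and VAF is
#' reconstructed as AD_alt/DP where absent. Malformed records raise an
#' error naming the offending line.
#'
#' @param path Input path.
#' @param dialect \code{"tsv"} or \code{"vcf"}.
#' @return Call data frame.
#' @export
read_variants <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    x <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot_cols(x, VARIANT_COLS, basename(path))
    bad <- which(!is.finite(x$pos) | x$pos < 1)
    if (length(bad)) {
      stop(sprintf("malformed record at line %d of %s", bad[1] + 1L, path))
    }
    x$pos <- x$pos - 1L
    return(x)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, "AD")
  dp <- suppressWarnings(as.integer(vcfR::extract.gt(v, "DP")))
  sm <- colnames(ad)[1]
  alt_n <- vapply(strsplit(ad[, 1], ","), function(z) as.integer(z[2]),
                  integer(1))
  pos <- as.integer(fx$POS)
  bad <- which(!is.finite(pos) | is.na(alt_n) | is.na(dp))
  if (length(bad)) {
    stop(sprintf("malformed record %d in %s", bad[1], path))
  }
  fwd <- alt_n %/% 2L
  data.frame(sample = sm, chrom = fx$CHROM, pos = pos - 1L, ref = fx$REF,
             alt = fx$ALT, class = NA_character_, depth = dp,
             alt_fwd = fwd, alt_rev = alt_n - fwd, vaf = alt_n / dp,
             p = NA_real_, q = NA_real_, stringsAsFactors = FALSE)
}

#' Write / read segment tables
#'
#' BED-like TSV with columns chrom, start, end, n_bins, median_logr, class
#' (plus any extra columns present), 1-based inclusive on disk.
#'
#' @param segments Segment data frame (0-based half-open in memory).
#' @param path File path.
#' @return \code{write_segments}: invisibly, the path;
#'   \code{read_segments}: the segment data frame.
#' @export
write_segments <- function(segments, path) {
  x <- segments
  x$start <- x$start + 1
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot_cols(x, c("chrom", "start", "end"), basename(path))
  bad <- which(!is.finite(x$start) | !is.finite(x$end) | x$end < x$start)
  if (length(bad)) {
    stop(sprintf("malformed record at line %d of %s", bad[1] + 1L, path))
  }
  x$start <- x$start - 1
  x
}

#' Read a run configuration (JSON or YAML)
#'
#' Missing fields are filled with the package defaults (caller FDR 0.05,
#' minimum depth 100, DBS joint-read fraction 0.9, selection thresholds
#' 1.3/0.6 at q < 0.01, segmentation gamma 30 with k_min 3 over 100 Kb
#' bins and gain/loss calls at +/-0.2, clonality thresholds 5/20 SNVs and
#' 10 Mb).
#'
#' @param path Path to a .json or .yaml/.yml file, or a list of overrides.
#' @return A complete configuration list of class \code{"run_config"}.
#' @export
read_config <- function(path = NULL) {
  user <- if (is.null(path)) list()
  else if (is.list(path)) path
  else if (grepl("\\.(yaml|yml)$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- list(seed = 1L, n_grids = 12, n_tumors = 2, fdr_alpha = 0.05,
              min_depth = 100, dbs_frac = 0.9,
              pos_threshold = 1.3, neg_threshold = 0.6, q_threshold = 0.01,
              gamma = 30, k_min = 3, bin_size = 1e5,
              gain_threshold = 0.2, loss_threshold = -0.2,
              min_snvs = 5, many_snvs = 20, min_cna_mb = 10,
              n_genes = 12, cds_length = 120, n_normals = 12,
              sim = list())
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages in order -- simulate, call, filter, select,
#' colonize, cna, clonality, report -- writing every stage output as TSV
#' under \code{out_dir} plus a manifest (package version, seed, config
#' hash). A stage failure aborts with the stage name; outputs of completed
#' stages are preserved.
#'
#' @param config A \code{\link{read_config}} list (or path / overrides
#'   accepted by it).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("clonesel_run")) {
  cfg <- if (inherits(config, "run_config")) config else read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "init"
  res <- list(config = cfg)
  wt <- function(x, nm) {
    utils::write.table(x, file.path(out_dir, nm), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  run <- tryCatch({
    stage <- "simulate"
    sim_args <- cfg$sim
    sim_args$seed <- cfg$seed
    sim_args$n_grids <- cfg$n_grids
    params <- do.call(sim_params, sim_args)
    genes <- generate_gene_models(cfg$n_genes, cfg$cds_length,
                                  seed = stage_seed(cfg$seed, "genes"))
    enum <- enumerate_substitutions(genes)
    epi <- simulate_epidermis(params, genes = genes, enum = enum)
    tumors <- lapply(seq_len(cfg$n_tumors), function(i) {
      arch <- if (i %% 2 == 1) "monoclonal" else "multifocal"
      pi_ <- params
      pi_$seed <- (stage_seed(cfg$seed, "tumor") + i) %% 2147483647
      simulate_tumor(pi_, arch, genes = genes, enum = enum,
                     tumor = sprintf("tumor%d", i))
    })
    wt(epi$samples, "samples.tsv")
    wt(transform(epi$counts, pos = pos + 1L), "counts.tsv")
    res$epi <- epi; res$tumors <- tumors

    stage <- "call"
    all_counts <- rbind(epi$counts,
                        do.call(rbind, lapply(tumors, `[[`, "counts")))
    # the error-model caller handles single-base substitutions; DBS and
    # indel records enter the chain as already-typed calls
    is_snv <- nchar(all_counts$ref) == 1 & nchar(all_counts$alt) == 1 &
      all_counts$alt != "-"
    sites <- unique(all_counts[is_snv, c("chrom", "pos", "ref")])
    panel_counts <- simulate_background_panel(params, cfg$n_normals,
                                              sites = sites)
    panel <- fit_background_panel(panel_counts)
    calls <- call_variants(all_counts[is_snv, , drop = FALSE], panel,
                           fdr_alpha = cfg$fdr_alpha)
    others <- all_counts[!is_snv, , drop = FALSE]
    if (nrow(others)) {
      others$vaf <- (others$alt_fwd + others$alt_rev) / others$depth
      others$p <- NA_real_
      others$q <- NA_real_
      calls <- rbind(calls[, names(others)], others)
    }
    calls <- annotate_calls(calls, genes, enum = enum)
    res$calls <- calls

    stage <- "filter"
    grids <- epi$samples$sample
    adjacency <- if (length(grids) > 1) {
      data.frame(sample1 = grids[-length(grids)], sample2 = grids[-1])
    } else NULL
    all_samples <- c(grids, unlist(lapply(tumors, function(t) t$samples$sample)))
    filt <- apply_filters(calls, adjacency = adjacency,
                          samples = all_samples,
                          min_depth = cfg$min_depth, dbs_frac = cfg$dbs_frac,
                          fdr_alpha = cfg$fdr_alpha)
    write_variants(filt$calls, file.path(out_dir, "calls.tsv"))
    write_variants(filt$clones, file.path(out_dir, "clones.tsv"))
    res$filtered <- filt

    stage <- "select"
    epi_calls <- filt$calls[filt$calls$sample %in% grids, , drop = FALSE]
    sel <- dnds(epi_calls, genes, enum = enum,
                pos_threshold = cfg$pos_threshold,
                neg_threshold = cfg$neg_threshold,
                q_threshold = cfg$q_threshold)
    vr <- vaf_ratio(epi_calls, genes)
    wt(sel$genes, "selection.tsv")
    wt(vr, "vaf_ratio.tsv")
    res$selection <- sel; res$vaf_ratio <- vr

    stage <- "colonize"
    pa <- epi_calls[epi_calls$class %in% PROTEIN_ALTERING, , drop = FALSE]
    colo <- colonized_fraction(pa, epi$samples, unit = "timepoint")
    wt(colo, "colonization.tsv")
    res$colonization <- colo

    stage <- "cna"
    seg_all <- list(); sweep <- NULL
    for (t in tumors) {
      for (s in unique(t$bins$sample)) {
        b <- compute_logr(t$bins[t$bins$sample == s, , drop = FALSE])
        seg <- segment_logr(b, gamma = cfg$gamma, k_min = cfg$k_min)
        cs <- call_segments(seg, cfg$gain_threshold, cfg$loss_threshold)
        sg <- cs$segments
        sg$tumor <- t$samples$tumor[1]; sg$sample <- s
        sg$fraction_altered <- cs$fraction_altered
        seg_all[[length(seg_all) + 1L]] <- sg
        if (is.null(sweep)) sweep <- sweep_segmentation(b)
      }
    }
    segments <- do.call(rbind, seg_all)
    write_segments(segments, file.path(out_dir, "segments.tsv"))
    wt(sweep$metrics, "sweep_metrics.tsv")
    res$segments <- segments; res$sweep <- sweep

    stage <- "clonality"
    tum_calls <- filt$calls[!filt$calls$sample %in% grids, , drop = FALSE]
    tum_calls$tumor <- sub("_s[0-9]+$", "", tum_calls$sample)
    clo <- classify_tumors(tum_calls,
                           segments[, c("tumor", "sample", "chrom", "start",
                                        "end", "class")],
                           min_snvs = cfg$min_snvs, many_snvs = cfg$many_snvs,
                           min_cna_mb = cfg$min_cna_mb)
    wt(clo, "clonality.tsv")
    res$clonality <- clo

    stage <- "report"
    manifest <- list(package = "clonesel",
                     version = as.character(utils::packageVersion("clonesel")),
                     seed = cfg$seed, config_hash = config_hash(cfg),
                     stages = c("simulate", "call", "filter", "select",
                                "colonize", "cna", "clonality", "report"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    burden <- mutation_burden(filt$calls[filt$calls$sample %in% grids, ],
                              epi$samples)
    summary_lines <- c(
      "clonesel pipeline summary",
      sprintf("grids: %d  tumors: %d  genes: %d", cfg$n_grids, cfg$n_tumors,
              cfg$n_genes),
      sprintf("filtered calls: %d  clones: %d", nrow(filt$calls),
              nrow(filt$clones)),
      sprintf("mean epidermal burden: %.2f SBS/Mb", mean(burden$sbs_per_mb)),
      sprintf("positively selected genes: %s",
              paste(res$selection$labels$gene[
                res$selection$labels$label == "positive"], collapse = ", ")),
      sprintf("tumor clonality: %s",
              paste(sprintf("%s=%s(%s)", clo$tumor, clo$label, clo$rule),
                    collapse = "  ")))
    writeLines(summary_lines, file.path(out_dir, "summary.txt"))
    res$manifest <- manifest
    res
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(run)
}
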