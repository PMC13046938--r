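# End-to-end orchestration: from a bundle of in-memory inputs to selected
# motifs, differential binding verdicts, and carrier differential
# expression of target genes.

#' Extract region sequences from a genome
#'
#' @param genome Named character vector from [read_fasta()].
#' @param regions Region `data.frame`.
#' @return Named character vector (region_id -> sequence).
#' @export
region_sequences <- function(genome, regions) {
  miss <- setdiff(unique(regions$contig), names(genome))
  if (length(miss) > 0L) stop("contig(s) absent from genome: ",
                              paste(utils::head(miss, 5L), collapse = ", "))
  out <- vapply(seq_len(nrow(regions)), function(i) {
    substr(genome[[regions$contig[i]]], regions$start[i] + 1L, regions$end[i])
  }, character(1))
  names(out) <- regions$region_id
  out
}

#' GC fraction of sequences
#'
#' @param seqs Character vector of DNA sequences.
#' @return Numeric vector of (G+C)/(A+C+G+T) fractions.
#' @export
gc_fraction <- function(seqs) {
  x <- Biostrings::DNAStringSet(seqs)
  acgt <- Biostrings::letterFrequency(x, BASES)
  tot <- rowSums(acgt)
  tot[tot == 0] <- 1
  as.numeric((acgt[, "C"] + acgt[, "G"]) / tot)
}

#' Validate in-memory GWAS records
#'
#' The in-memory counterpart of [read_gwas()]: takes a raw summary-
#' statistics `data.frame` (`rsid`, `chrom`, `pos`, `allele_other`,
#' `allele_effect`, `beta`, `pvalue`) and returns validated variant
#' records with 0-based positions.
#'
#' @param df Raw summary-statistics `data.frame`.
#' @return Variant `data.frame` (see [read_gwas()]).
#' @export
gwas_records <- function(df) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  read_gwas(tmp)
}

#' Read a bundle directory written by [write_bundle()]
#'
#' @param dir Bundle directory.
#' @return List in the shape consumed by [run_pipeline()].
#' @export
read_bundle <- function(dir) {
  fp <- function(f) file.path(dir, f)
  calls_df <- utils::read.delim(fp("peak_calls.tsv"), stringsAsFactors = FALSE)
  list(
    genome = read_fasta(fp("genome.fa")),
    regions = read_bed(fp("peaks.bed")),
    motifs = read_motifs(fp("motifs.jaspar"), "jaspar"),
    gwas = utils::read.delim(fp("gwas.tsv"), stringsAsFactors = FALSE),
    genotypes = read_genotypes(fp("genotypes.tsv")),
    atac = read_count_matrix(fp("atac.mtx"), fp("atac_cells.tsv"),
                             fp("atac_peaks.tsv"), fp("atac_annot.tsv")),
    rna = read_count_matrix(fp("rna.mtx"), fp("rna_cells.tsv"),
                            fp("rna_genes.tsv"), fp("rna_annot.tsv")),
    covariates = utils::read.delim(fp("covariates.tsv"), stringsAsFactors = FALSE),
    celltype_peak_calls = split(calls_df$region_id, calls_df$cell_type),
    genes = utils::read.delim(fp("genes.tsv"), stringsAsFactors = FALSE),
    interaction_pairs = utils::read.delim(fp("interaction_pairs.tsv"),
                                          stringsAsFactors = FALSE)
  )
}

#' Run the full differential-binding pipeline on a bundle
#'
#' Stages: background estimation from the scanned regions; PWM and exact
#' p-value table construction; per-cell-type marker peaks; motif presence
#' annotation; hypergeometric enrichment, accessibility deviation and
#' expression filters; scCRE definition; GWAS filtering and risk
#' recoding; allele-pair construction; differential binding scores and
#' per-motif verdicts; SNP-to-gene mapping and carrier differential
#' expression for SNPs in consistently altered motifs.
#'
#' @param bundle List of inputs (see [simulate_bundle()] /
#'   [read_bundle()]).
#' @param granularity P-value table bins per column. Default 1000.
#' @param pseudocount PWM pseudocount. Default 0.1.
#' @param p_scan Near-inclusive scan threshold for binding scores.
#'   Default 0.99.
#' @param p_match Match threshold for presence annotation. Default 5e-5.
#' @param p_enrich Strict enrichment cutoff. Default 1e-10.
#' @param z_min Deviation cutoff. Default 1.0.
#' @param gwas_threshold Genome-wide significance. Default 5e-8.
#' @param delta_threshold Gain/loss cutoff on `|delta|`. Default 3.
#' @param min_diff Consistency margin. Default 5.
#' @param window_bp SNP-to-gene promoter window. Default 10000.
#' @param fdr_max DE significance threshold. Default 0.1.
#' @param deviation_seed Seed for background-set sampling. Default 1.
#' @param uniform_background Use a uniform background instead of the
#'   estimated one. Default FALSE.
#' @return List with per-stage results: `models`, `markers`, `presence`,
#'   `motif_sets`, `sccres`, `variants`, `pairs`, `delta`, `verdicts`,
#'   `links`, `de`.
#' @export
run_pipeline <- function(bundle,
                         granularity = 1000L,
                         pseudocount = 0.1,
                         p_scan = 0.99,
                         p_match = 5e-5,
                         p_enrich = 1e-10,
                         z_min = 1.0,
                         gwas_threshold = 5e-8,
                         delta_threshold = 3,
                         min_diff = 5,
                         window_bp = 10000,
                         fdr_max = 0.1,
                         deviation_seed = 1,
                         uniform_background = FALSE) {
  seqs <- region_sequences(bundle$genome, bundle$regions)
  background <- if (uniform_background) rep(0.25, 4) else estimate_background(seqs)
  models <- lapply(bundle$motifs, function(m) {
    score_pvalue_table(
      build_pwm(m$pfm, background, pseudocount, m$motif_id, m$tf_name),
      granularity
    )
  })
  names(models) <- vapply(models, `[[`, character(1), "motif_id")
  cell_types <- sort(unique(bundle$atac$cell_type))

  markers <- lapply(cell_types, function(ct) call_marker_peaks(bundle$atac, ct))
  names(markers) <- cell_types
  presence <- annotate_motif_presence(models, seqs, p_match)
  peak_gc <- gc_fraction(seqs[bundle$atac$feature_ids])

  motif_sets <- lapply(cell_types, function(ct) {
    enr <- enrich_motifs(presence, markers[[ct]]$marker, ct, p_enrich)
    dev <- motif_deviation(bundle$atac, presence, peak_gc, ct,
                           seed = deviation_seed)
    expr <- lapply(names(models), function(mid) {
      expression_filter(bundle$rna, ct, models[[mid]]$tf_name)
    })
    names(expr) <- names(models)
    select_motifs(ct, enr, dev, expr, p_enrich, z_min)
  })
  names(motif_sets) <- cell_types

  variants <- recode_risk(
    filter_genomewide(gwas_records(bundle$gwas), gwas_threshold)
  )
  pairs_all <- build_allele_pairs(bundle$regions, bundle$genome, variants)
  sccres <- lapply(cell_types, function(ct) {
    define_sccres(bundle$atac, bundle$celltype_peak_calls, ct)
  })
  names(sccres) <- cell_types

  delta <- list()
  verdicts <- list()
  for (ct in cell_types) {
    mods <- models[motif_sets[[ct]]$motifs]
    if (length(mods) == 0L) next
    keep <- names(pairs_all) %in% sccres[[ct]]$region_id
    res <- delta_binding_analysis(pairs_all[keep], mods, ct,
                                  p_scan, delta_threshold, min_diff)
    delta[[ct]] <- res$results
    verdicts[[ct]] <- res$summary
  }
  delta <- do.call(rbind, c(delta, list(make.row.names = FALSE)))
  verdicts <- do.call(rbind, c(verdicts, list(make.row.names = FALSE)))

  # SNPs in consistently altered motifs, within scCREs called gained/lost
  tuples <- NULL
  if (!is.null(verdicts) && any(verdicts$verdict != "none")) {
    hit_rows <- merge(
      delta[delta$call != "unchanged", , drop = FALSE],
      verdicts[verdicts$verdict != "none", c("cell_type", "motif_id")],
      by = c("cell_type", "motif_id")
    )
    tuple_list <- lapply(seq_len(nrow(hit_rows)), function(i) {
      pair <- pairs_all[[hit_rows$region_id[i]]]
      snps_here <- variants[variants$rsid %in% pair$snps_applied, , drop = FALSE]
      links <- map_snps_to_genes(snps_here, bundle$genes, window_bp,
                                 bundle$interaction_pairs)
      if (nrow(links) == 0L) return(NULL)
      data.frame(cell_type = hit_rows$cell_type[i], rsid = links$rsid,
                 gene_id = links$gene_id, stringsAsFactors = FALSE)
    })
    tuples <- unique(do.call(rbind, tuple_list))
  }
  de <- NULL
  if (!is.null(tuples) && nrow(tuples) > 0L) {
    de <- link_expression(tuples, bundle$rna, bundle$genotypes,
                          bundle$covariates, fdr_max)
  }
  list(
    background = background, models = models, markers = markers,
    presence = presence, motif_sets = motif_sets, sccres = sccres,
    variants = variants, pairs = pairs_all, delta = delta,
    verdicts = verdicts, tuples = tuples, de = de
  )
}
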