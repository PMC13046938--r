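# GWAS variant filtering, risk-allele orientation, assignment of SNPs to
# regulatory regions, and construction of the risk / non-risk sequence pair
# for each SNP-containing region.

#' Filter variants to genome-wide significance
#'
#' Keeps records with `pvalue <= threshold` (inclusive bound).
#'
#' @param snps Variant `data.frame` (see [read_gwas()]).
#' @param threshold Significance threshold. Default `5e-8`.
#' @return The filtered `data.frame`.
#' @export
filter_genomewide <- function(snps, threshold = 5e-8) {
  snps[snps$pvalue <= threshold, , drop = FALSE]
}

#' Orient variants so the risk allele carries a non-negative effect
#'
#' Records with negative `beta` have their alleles swapped and the effect
#' size negated, so that `allele_risk` always denotes the risk-increasing
#' allele. `beta == 0` is left in its original orientation. Idempotent.
#'
#' @param snps Variant `data.frame`.
#' @return The recoded `data.frame`; `recoded` flags swapped rows.
#' @export
recode_risk <- function(snps) {
  if (any(!is.finite(snps$beta))) stop("beta must be finite for all variants")
  flip <- snps$beta < 0
  if (any(flip)) {
    tmp <- snps$allele_nonrisk[flip]
    snps$allele_nonrisk[flip] <- snps$allele_risk[flip]
    snps$allele_risk[flip] <- tmp
    snps$beta[flip] <- -snps$beta[flip]
    snps$recoded[flip] <- TRUE
  }
  snps
}

#' Summarize a GWAS file: significant, risk and protective counts
#'
#' Applies the genome-wide filter and splits the surviving variants by
#' effect-size sign (`beta > 0` risk, `beta < 0` protective).
#'
#' @param path Path to a GWAS TSV (see [read_gwas()]).
#' @param threshold Significance threshold. Default `5e-8`.
#' @return Named list: `n_significant`, `n_risk`, `n_protective`.
#' @export
gwas_filter_summary <- function(path, threshold = 5e-8) {
  snps <- filter_genomewide(read_gwas(path), threshold)
  list(
    n_significant = nrow(snps),
    n_risk = sum(snps$beta > 0),
    n_protective = sum(snps$beta < 0)
  )
}

#' Drop variants inside the extended MHC region
#'
#' Sensitivity-analysis helper removing variants within a contiguous
#' interval (default chr6:26-34 Mb, 1-based inclusive bounds on input,
#' applied to internal 0-based positions).
#'
#' @param snps Variant `data.frame`.
#' @param contig Contig name. Default `"chr6"`.
#' @param start,end 1-based inclusive bounds. Defaults 26,000,000 and
#'   34,000,000.
#' @return Variants outside the interval.
#' @export
exclude_mhc <- function(snps, contig = "chr6", start = 26000000, end = 34000000) {
  inside <- snps$contig == contig & snps$pos0 >= start - 1 & snps$pos0 <= end - 1
  snps[!inside, , drop = FALSE]
}

#' Assign SNPs to the regions that contain them
#'
#' A SNP belongs to a region iff `start <= pos0 < end` (0-based half-open);
#' a SNP overlapping several regions appears under each. Regions without
#' SNPs are absent from the result.
#'
#' @param snps Variant `data.frame` with 0-based `pos0`.
#' @param regions Region `data.frame` (see [read_bed()]).
#' @return Named list: `region_id` -> variant `data.frame`.
#' @export
assign_snps_to_regions <- function(snps, regions) {
  if (nrow(snps) == 0L || nrow(regions) == 0L) return(list())
  snp_gr <- GenomicRanges::GRanges(
    snps$contig, IRanges::IRanges(start = snps$pos0 + 1L, width = 1L)
  )
  reg_gr <- GenomicRanges::GRanges(
    regions$contig, IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
  ov <- GenomicRanges::findOverlaps(snp_gr, reg_gr)
  if (length(ov) == 0L) return(list())
  by_region <- split(
    S4Vectors::queryHits(ov),
    regions$region_id[S4Vectors::subjectHits(ov)]
  )
  lapply(by_region, function(i) {
    out <- snps[i, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Build the non-risk / risk allele sequence pair for one region
#'
#' All SNPs falling in the region are substituted simultaneously:
#' `seq_risk` carries every risk allele, `seq_nonrisk` every non-risk
#' allele; other positions equal the genome. When the genome base matches
#' neither allele of a SNP, that SNP is dropped with a warning (the summary
#' statistics' alleles, not the local genome, define the comparison; a
#' genome base equal to the risk allele is fine).
#'
#' @param region Single-row region `data.frame`.
#' @param genome Named character vector from [read_fasta()].
#' @param snps Variant `data.frame`, risk-oriented (see [recode_risk()]),
#'   all with positions inside the region.
#' @return List with `region_id`, `seq_nonrisk`, `seq_risk`,
#'   `snps_applied` (rsids), `snp_offsets` (0-based within the region) and
#'   `n_dropped`.
#' @export
build_allele_pair <- function(region, genome, snps) {
  stopifnot(nrow(region) == 1L)
  if (!region$contig %in% names(genome)) {
    stop("contig ", region$contig, " absent from genome")
  }
  seq0 <- substr(genome[[region$contig]], region$start + 1L, region$end)
  if (nchar(seq0) != region$end - region$start) {
    stop("region ", region$region_id, " extends beyond contig ", region$contig)
  }
  if (any(snps$pos0 < region$start | snps$pos0 >= region$end)) {
    stop("SNP outside region ", region$region_id)
  }
  ref_chars <- strsplit(seq0, "")[[1L]]
  off <- snps$pos0 - region$start
  genome_base <- ref_chars[off + 1L]
  ok <- genome_base == snps$allele_nonrisk | genome_base == snps$allele_risk
  if (any(!ok)) {
    warning(
      sum(!ok), " SNP(s) dropped in region ", region$region_id,
      ": genome base matches neither allele (",
      paste(snps$rsid[!ok], collapse = ", "), ")"
    )
  }
  snps <- snps[ok, , drop = FALSE]
  off <- off[ok]
  nr <- rc <- ref_chars
  nr[off + 1L] <- snps$allele_nonrisk
  rc[off + 1L] <- snps$allele_risk
  list(
    region_id = region$region_id,
    seq_nonrisk = paste0(nr, collapse = ""),
    seq_risk = paste0(rc, collapse = ""),
    snps_applied = snps$rsid,
    snp_offsets = off,
    n_dropped = sum(!ok)
  )
}

#' Build allele pairs for every SNP-containing region
#'
#' @param regions Region `data.frame`.
#' @param genome Named character vector from [read_fasta()].
#' @param snps Risk-oriented variant `data.frame`.
#' @return Named list of allele pairs (see [build_allele_pair()]), one per
#'   region that contains at least one SNP.
#' @export
build_allele_pairs <- function(regions, genome, snps) {
  assigned <- assign_snps_to_regions(snps, regions)
  out <- lapply(names(assigned), function(rid) {
    build_allele_pair(
      regions[regions$region_id == rid, , drop = FALSE], genome, assigned[[rid]]
    )
  })
  names(out) <- names(assigned)
  out
}
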