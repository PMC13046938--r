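# Linking binding-altering SNPs to target genes and testing pseudobulk
# differential expression between risk-allele carriers and non-carriers
# with a negative-binomial generalized linear model.

#' Map SNPs to candidate target genes
#'
#' A SNP is linked to a gene when it lies within `window_bp` of the gene's
#' TSS (promoter-window evidence), or when it falls in one anchor of an
#' interaction pair whose other anchor contains the TSS (interaction-pair
#' evidence). Links are deduplicated per (rsid, gene); evidence types are
#' `";"`-joined when both apply.
#'
#' @param snps Variant `data.frame` with `rsid`, `contig`, `pos0`.
#' @param genes Gene `data.frame` with `gene_id`, `symbol`, `contig`,
#'   `tss_pos0`, `strand`.
#' @param window_bp Promoter window half-width in bp. Default 10000.
#' @param interaction_pairs Optional `data.frame` with `contig1`,
#'   `start1`, `end1`, `contig2`, `start2`, `end2` (0-based half-open).
#' @return `data.frame` with `rsid`, `gene_id`, `evidence`.
#' @export
map_snps_to_genes <- function(snps, genes, window_bp = 10000,
                              interaction_pairs = NULL) {
  links <- list()
  for (i in seq_len(nrow(snps))) {
    near <- genes$contig == snps$contig[i] &
      abs(genes$tss_pos0 - snps$pos0[i]) <= window_bp
    if (any(near)) {
      links[[length(links) + 1L]] <- data.frame(
        rsid = snps$rsid[i], gene_id = genes$gene_id[near],
        evidence = "promoter-window", stringsAsFactors = FALSE
      )
    }
  }
  if (!is.null(interaction_pairs) && nrow(interaction_pairs) > 0L) {
    in_anchor <- function(contig, pos0, acontig, astart, aend) {
      contig == acontig & pos0 >= astart & pos0 < aend
    }
    for (i in seq_len(nrow(snps))) {
      for (k in seq_len(nrow(interaction_pairs))) {
        p <- interaction_pairs[k, ]
        snp_in_1 <- in_anchor(snps$contig[i], snps$pos0[i], p$contig1, p$start1, p$end1)
        snp_in_2 <- in_anchor(snps$contig[i], snps$pos0[i], p$contig2, p$start2, p$end2)
        if (!snp_in_1 && !snp_in_2) next
        tss_in <- if (snp_in_1) {
          in_anchor(genes$contig, genes$tss_pos0, p$contig2, p$start2, p$end2)
        } else {
          in_anchor(genes$contig, genes$tss_pos0, p$contig1, p$start1, p$end1)
        }
        if (any(tss_in)) {
          links[[length(links) + 1L]] <- data.frame(
            rsid = snps$rsid[i], gene_id = genes$gene_id[tss_in],
            evidence = "interaction-pair", stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(links) == 0L) {
    return(data.frame(rsid = character(), gene_id = character(),
                      evidence = character(), stringsAsFactors = FALSE))
  }
  all_links <- do.call(rbind, links)
  agg <- stats::aggregate(
    evidence ~ rsid + gene_id, data = all_links,
    FUN = function(e) paste(sort(unique(e)), collapse = ";")
  )
  agg[order(agg$rsid, agg$gene_id), , drop = FALSE]
}

#' Split donors into risk-allele carriers and non-carriers
#'
#' @param genotypes SNPs x donors dosage matrix from [read_genotypes()].
#' @param rsid Variant id (must be a rowname of `genotypes`).
#' @return List with `carriers` (dosage >= 1), `noncarriers` (dosage 0)
#'   and `n_excluded` (NA dosages).
#' @export
carrier_split <- function(genotypes, rsid) {
  if (!rsid %in% rownames(genotypes)) stop("rsid ", rsid, " absent from genotypes")
  d <- genotypes[rsid, ]
  list(
    carriers = names(d)[!is.na(d) & d >= 1],
    noncarriers = names(d)[!is.na(d) & d == 0],
    n_excluded = sum(is.na(d))
  )
}

#' Pseudobulk expression per donor for one cell type
#'
#' Raw counts are summed over each donor's cells of the target cell type;
#' donors without such cells are omitted. Column sums over donors equal
#' the cell-level column sums for the cell type.
#'
#' @param rna A [count_matrix()] of cells x genes.
#' @param cell_type Target cell type.
#' @return Integer matrix, donors x genes.
#' @export
pseudobulk_counts <- function(rna, cell_type) {
  stopifnot(inherits(rna, "count_matrix"))
  if (!cell_type %in% rna$cell_type) stop("cell type ", cell_type, " absent")
  pseudobulk_by(rna$counts, rna$donor, rna$cell_type == cell_type)
}

#' Expression filter for testable genes
#'
#' A gene is testable when at least `min_fraction` of the pseudobulk
#' samples have at least `min_count` counts (both bounds inclusive).
#'
#' @param pb Donor x gene pseudobulk matrix.
#' @param gene Gene (column) id.
#' @param min_count Count threshold per sample. Default 10.
#' @param min_fraction Fraction of samples required. Default 0.75.
#' @return Logical.
#' @export
filter_testable <- function(pb, gene, min_count = 10, min_fraction = 0.75) {
  if (nrow(pb) < 4L) stop("need at least 4 pseudobulk samples")
  if (!gene %in% colnames(pb)) stop("gene ", gene, " absent from pseudobulk")
  mean(pb[, gene] >= min_count) >= min_fraction
}

#' Negative-binomial Wald test of carrier status on one gene
#'
#' Fits a log-link negative-binomial GLM of the gene's pseudobulk counts
#' on a carrier indicator plus the covariates, with a log library-size
#' offset. The per-gene dispersion is estimated by method of moments on
#' library-size-normalized counts with a floor of 0.01, and the Wald
#' p-value for the carrier coefficient uses a t reference with residual
#' degrees of freedom (small-sample correction at cohort-scale n).
#' Groups smaller than `min_group` give an untestable result rather than
#' an error.
#'
#' @param pb Donor x gene pseudobulk matrix.
#' @param gene Gene (column) id.
#' @param carriers,noncarriers Donor id vectors from [carrier_split()].
#' @param covariates `data.frame` with `donor`, `diagnosis`, `sex`,
#'   `age`, `pH`, `RIN`, `PMI`.
#' @param min_group Minimum donors per arm. Default 3.
#' @return One-row `data.frame` with `gene_id`, `log2_fc`, `pvalue`,
#'   `n_carriers`, `n_noncarriers`, `testable`.
#' @export
de_test <- function(pb, gene, carriers, noncarriers, covariates, min_group = 3) {
  donors <- intersect(rownames(pb), c(carriers, noncarriers))
  carriers <- intersect(donors, carriers)
  noncarriers <- intersect(donors, noncarriers)
  untestable <- data.frame(
    gene_id = gene, log2_fc = NA_real_, pvalue = NA_real_,
    n_carriers = length(carriers), n_noncarriers = length(noncarriers),
    testable = FALSE, stringsAsFactors = FALSE
  )
  if (length(carriers) < min_group || length(noncarriers) < min_group) {
    return(untestable)
  }
  use <- c(carriers, noncarriers)
  y <- pb[use, gene]
  libsize <- rowSums(pb)[use]
  if (any(libsize <= 0)) return(untestable)
  cv <- covariates[match(use, covariates$donor), , drop = FALSE]
  if (anyNA(cv$donor)) stop("covariates missing for donor(s): ",
                            paste(use[is.na(cv$donor)], collapse = ", "))
  df <- data.frame(
    y = y,
    carrier = as.numeric(use %in% carriers),
    diagnosis = factor(cv$diagnosis),
    sex = factor(cv$sex),
    age = cv$age, pH = cv$pH, RIN = cv$RIN, PMI = cv$PMI,
    off = log(libsize)
  )
  theta <- 1 / dispersion_mom(y, libsize)
  fit <- stats::glm(
    y ~ carrier + diagnosis + sex + age + pH + RIN + PMI + offset(off),
    data = df, family = MASS::negative.binomial(theta)
  )
  co <- summary(fit)$coefficients
  if (!"carrier" %in% rownames(co) || anyNA(co["carrier", 1:2])) {
    stop("singular design for gene ", gene)
  }
  est <- co["carrier", "Estimate"]
  se <- co["carrier", "Std. Error"]
  dfree <- max(fit$df.residual, 1L)
  pvalue <- 2 * stats::pt(-abs(est / se), df = dfree)
  data.frame(
    gene_id = gene, log2_fc = est / log(2), pvalue = pvalue,
    n_carriers = length(carriers), n_noncarriers = length(noncarriers),
    testable = TRUE, stringsAsFactors = FALSE
  )
}

# method-of-moments NB dispersion on library-size-normalized counts
dispersion_mom <- function(y, libsize, floor = 0.01) {
  r <- y * mean(libsize) / libsize
  m <- mean(r)
  v <- stats::var(r)
  if (!is.finite(v) || m <= 0) return(floor)
  max((v - m) / m^2, floor)
}

#' Carrier-vs-non-carrier differential expression for linked target genes
#'
#' Runs [de_test()] for every (cell type, rsid, gene) tuple, applying the
#' testability filter first; FDR is Benjamini-Hochberg across all tested
#' tuples of the run, and `significant` flags `fdr <= 0.1` (inclusive).
#'
#' @param tuples `data.frame` with `cell_type`, `rsid`, `gene_id`.
#' @param rna A [count_matrix()] of cells x genes.
#' @param genotypes Dosage matrix from [read_genotypes()].
#' @param covariates Covariate `data.frame` (see [de_test()]).
#' @param fdr_max Significance threshold on the BH FDR. Default 0.1.
#' @param min_group,min_count,min_fraction Passed to [de_test()] and
#'   [filter_testable()].
#' @return `data.frame` of results, one row per tuple, with `fdr` and
#'   `significant` for testable tuples.
#' @export
link_expression <- function(tuples, rna, genotypes, covariates, fdr_max = 0.1,
                            min_group = 3, min_count = 10, min_fraction = 0.75) {
  pbs <- list()
  rows <- lapply(seq_len(nrow(tuples)), function(i) {
    ct <- tuples$cell_type[i]
    if (is.null(pbs[[ct]])) pbs[[ct]] <<- pseudobulk_counts(rna, ct)
    pb <- pbs[[ct]]
    gene <- tuples$gene_id[i]
    rsid <- tuples$rsid[i]
    base <- data.frame(
      cell_type = ct, rsid = rsid, stringsAsFactors = FALSE
    )
    if (!gene %in% colnames(pb) ||
        !filter_testable(pb, gene, min_count, min_fraction)) {
      return(cbind(base, data.frame(
        gene_id = gene, log2_fc = NA_real_, pvalue = NA_real_,
        n_carriers = NA_integer_, n_noncarriers = NA_integer_,
        testable = FALSE, stringsAsFactors = FALSE
      )))
    }
    split <- carrier_split(genotypes, rsid)
    cbind(base, de_test(pb, gene, split$carriers, split$noncarriers,
                        covariates, min_group))
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  tested <- which(out$testable)
  out$fdr[tested] <- stats::p.adjust(out$pvalue[tested], method = "BH")
  out$significant <- !is.na(out$fdr) & out$fdr <= fdr_max
  rownames(out) <- NULL
  out
}
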