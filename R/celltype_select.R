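# Per-cell-type motif selection: marker-peak calling on donor pseudobulks,
# hypergeometric motif enrichment in marker peaks, a bias-matched
# accessibility deviation statistic, and a TF gene expression filter.

#' Call cell type-specific marker peaks
#'
#' For each donor, counts are pseudobulked separately over the donor's
#' cells inside and outside the target cell type and CPM-normalized.
#' `log2_fc = log2((mean_in + c) / (mean_out + c))` with `c` = 1 CPM;
#' the p-value is a two-sided Wilcoxon rank-sum over donor pseudobulk CPMs,
#' and FDR is Benjamini-Hochberg across peaks. A peak is a marker when
#' `log2_fc >= 1` and `fdr <= 0.05`.
#'
#' @param atac A [count_matrix()] of cells x peaks.
#' @param cell_type Target cell type label.
#' @param log2fc_min,fdr_max Marker thresholds. Defaults 1 and 0.05.
#' @param cpm_pseudocount Stabilizing constant `c` in CPM units. Default 1.
#' @return `data.frame` with `cell_type`, `region_id`, `log2_fc`, `pvalue`,
#'   `fdr`, `marker`.
#' @export
call_marker_peaks <- function(atac, cell_type, log2fc_min = 1, fdr_max = 0.05,
                              cpm_pseudocount = 1) {
  stopifnot(inherits(atac, "count_matrix"))
  if (!cell_type %in% atac$cell_type) stop("cell type ", cell_type, " absent")
  in_cells <- atac$cell_type == cell_type
  donors <- sort(unique(atac$donor))
  pb_in <- pseudobulk_by(atac$counts, atac$donor, in_cells)
  pb_out <- pseudobulk_by(atac$counts, atac$donor, !in_cells)
  if (nrow(pb_in) < 2L || nrow(pb_out) < 2L) {
    stop("need at least 2 donors with cells inside and outside the cell type")
  }
  cpm_in <- cpm_rows(pb_in)
  cpm_out <- cpm_rows(pb_out)
  mean_in <- colMeans(cpm_in)
  mean_out <- colMeans(cpm_out)
  log2_fc <- log2((mean_in + cpm_pseudocount) / (mean_out + cpm_pseudocount))
  pvalue <- vapply(seq_along(atac$feature_ids), function(j) {
    stats::wilcox.test(cpm_in[, j], cpm_out[, j], exact = FALSE)$p.value
  }, numeric(1))
  pvalue[is.na(pvalue)] <- 1  # all-tied peaks carry no evidence
  fdr <- stats::p.adjust(pvalue, method = "BH")
  data.frame(
    cell_type = cell_type,
    region_id = atac$feature_ids,
    log2_fc = log2_fc,
    pvalue = pvalue,
    fdr = fdr,
    marker = log2_fc >= log2fc_min & fdr <= fdr_max,
    stringsAsFactors = FALSE
  )
}

# sum counts per donor over a cell subset; drops donors with no such cells
pseudobulk_by <- function(counts, donor, subset) {
  donors <- sort(unique(donor[subset]))
  ind <- Matrix::sparseMatrix(
    i = match(donor[subset], donors),
    j = which(subset),
    x = 1,
    dims = c(length(donors), nrow(counts))
  )
  pb <- as.matrix(ind %*% counts)
  rownames(pb) <- donors
  colnames(pb) <- colnames(counts)
  pb
}

cpm_rows <- function(pb) {
  totals <- rowSums(pb)
  totals[totals == 0] <- 1
  pb / totals * 1e6
}

#' Annotate motif presence across regions
#'
#' A motif is present in a region when scanning either strand yields at
#' least one window with match p-value at or below `p_match`. This match
#' cutoff is deliberately stricter than the near-inclusive threshold used
#' for binding scores: presence feeds the enrichment test, which needs
#' bona fide matches.
#'
#' @param models List of motif models with p-value tables.
#' @param sequences Named character vector of region sequences.
#' @param p_match Match p-value cutoff. Default `5e-5`.
#' @return Logical matrix, regions x motifs.
#' @export
annotate_motif_presence <- function(models, sequences, p_match = 5e-5) {
  ids <- vapply(models, `[[`, character(1), "motif_id")
  out <- matrix(
    FALSE, nrow = length(sequences), ncol = length(models),
    dimnames = list(names(sequences), ids)
  )
  for (m in seq_along(models)) {
    for (r in seq_along(sequences)) {
      hits <- scan_region(models[[m]], sequences[[r]], p_threshold = p_match,
                          region_id = names(sequences)[r])
      out[r, m] <- nrow(hits) > 0L
    }
  }
  out
}

#' Hypergeometric motif enrichment in marker peaks
#'
#' Upper-tail hypergeometric test `P(X >= n_motif_marker)` with population
#' `n_universe` peaks, `n_motif_universe` motif-containing peaks, and
#' `n_marker` draws. A motif is enriched when `pvalue_hypergeom <
#' p_enrich` (strict).
#'
#' @param presence Logical regions x motifs matrix from
#'   [annotate_motif_presence()].
#' @param marker Logical vector (length = regions) flagging marker peaks.
#' @param cell_type Label copied into the result.
#' @param p_enrich Strict enrichment cutoff. Default `1e-10`.
#' @return `data.frame` with counts, `pvalue_hypergeom` and `enriched`.
#' @export
enrich_motifs <- function(presence, marker, cell_type = "celltype",
                          p_enrich = 1e-10) {
  stopifnot(nrow(presence) == length(marker))
  n_universe <- nrow(presence)
  n_marker <- sum(marker)
  if (n_marker == 0L) stop("no marker peaks: enrichment undefined")
  n_motif_universe <- colSums(presence)
  n_motif_marker <- colSums(presence & marker)
  pv <- stats::phyper(
    n_motif_marker - 1, n_motif_universe,
    n_universe - n_motif_universe, n_marker,
    lower.tail = FALSE
  )
  data.frame(
    cell_type = cell_type,
    motif_id = colnames(presence),
    n_universe = n_universe,
    n_marker = n_marker,
    n_motif_universe = as.integer(n_motif_universe),
    n_motif_marker = as.integer(n_motif_marker),
    pvalue_hypergeom = pv,
    enriched = pv < p_enrich,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Bias-matched accessibility deviation per motif and cell type
#'
#' For each cell, the raw deviation of a peak set is
#' `(observed - expected) / expected`, where `expected` is the cell's
#' total count times the peak set's global accessibility fraction. The
#' raw deviation of the motif's peaks is standardized against the same
#' statistic computed on `n_background` random peak sets in which each
#' motif peak is replaced by one of its nearest neighbors in the
#' 2-D space of (GC content, mean accessibility). The reported
#' `deviation_z` is the mean standardized deviation over the target cell
#' type's cells.
#'
#' @param atac A [count_matrix()] of cells x peaks.
#' @param presence Logical regions x motifs matrix (rows must match the
#'   peak order of `atac`).
#' @param peak_gc Numeric GC fraction per peak.
#' @param cell_type Target cell type.
#' @param n_background Number of matched background sets (>= 10).
#'   Default 50.
#' @param seed Integer seed for background sampling.
#' @param k_neighbors Neighborhood size for matching. Default 50.
#' @return `data.frame` with `cell_type`, `motif_id`, `deviation_z`.
#' @export
motif_deviation <- function(atac, presence, peak_gc, cell_type,
                            n_background = 50, seed = 1, k_neighbors = 50) {
  stopifnot(inherits(atac, "count_matrix"))
  if (n_background < 10) stop("insufficient background sets (require >= 10)")
  n_peaks <- length(atac$feature_ids)
  stopifnot(nrow(presence) == n_peaks, length(peak_gc) == n_peaks)
  if (!cell_type %in% atac$cell_type) stop("cell type ", cell_type, " absent")
  X <- atac$counts
  cell_tot <- Matrix::rowSums(X)
  use_cell <- atac$cell_type == cell_type & cell_tot > 0
  peak_tot <- Matrix::colSums(X)
  global_frac <- peak_tot / sum(peak_tot)
  mean_acc <- peak_tot / nrow(X)
  feat <- cbind(scale(peak_gc), scale(mean_acc))
  feat[is.na(feat)] <- 0
  k <- min(k_neighbors, n_peaks - 1L)
  d2 <- as.matrix(stats::dist(feat))
  nn <- t(apply(d2, 1L, function(row) order(row)[2:(k + 1L)]))
  set.seed(seed)
  out <- lapply(colnames(presence), function(mid) {
    idx <- which(presence[, mid])
    if (length(idx) == 0L) stop("motif ", mid, " annotated in 0 peaks")
    raw <- raw_deviation(X, idx, cell_tot, global_frac, use_cell)
    bg <- matrix(0, nrow = sum(use_cell), ncol = n_background)
    for (b in seq_len(n_background)) {
      bset <- nn[cbind(idx, sample.int(k, length(idx), replace = TRUE))]
      bg[, b] <- raw_deviation(X, bset, cell_tot, global_frac, use_cell)
    }
    mu <- rowMeans(bg)
    sd_bg <- apply(bg, 1L, stats::sd)
    sd_bg[sd_bg == 0 | !is.finite(sd_bg)] <- NA
    z <- (raw - mu) / sd_bg
    data.frame(
      cell_type = cell_type, motif_id = mid,
      deviation_z = mean(z, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

raw_deviation <- function(X, idx, cell_tot, global_frac, use_cell) {
  obs <- Matrix::rowSums(X[, idx, drop = FALSE])[use_cell]
  expd <- cell_tot[use_cell] * sum(global_frac[idx])
  (obs - expd) / expd
}

#' TF gene expression filter
#'
#' A motif passes when every component gene of its TF name (dimers and
#' trimers are `"::"`-joined) has a nonzero count in at least
#' `min_fraction` of the target cell type's cells (inclusive). Genes
#' absent from the matrix count as unexpressed.
#'
#' @param rna A [count_matrix()] of cells x genes (feature ids are gene
#'   symbols).
#' @param cell_type Target cell type.
#' @param tf_name TF name, possibly `"::"`-joined for complexes.
#' @param min_fraction Expressed-cell fraction required. Default 0.05.
#' @return List with `pass` (logical) and `fractions` (named per gene).
#' @export
expression_filter <- function(rna, cell_type, tf_name, min_fraction = 0.05) {
  stopifnot(inherits(rna, "count_matrix"))
  genes <- strsplit(tf_name, "::", fixed = TRUE)[[1L]]
  cells <- which(rna$cell_type == cell_type)
  if (length(cells) == 0L) stop("cell type ", cell_type, " absent")
  fractions <- vapply(genes, function(g) {
    j <- match(g, rna$feature_ids)
    if (is.na(j)) return(0)
    sum(rna$counts[cells, j] > 0) / length(cells)
  }, numeric(1))
  missing <- genes[!genes %in% rna$feature_ids]
  if (length(missing) > 0L) {
    message("gene(s) absent from expression matrix, treated as unexpressed: ",
            paste(missing, collapse = ", "))
  }
  list(pass = all(fractions >= min_fraction), fractions = fractions)
}

#' Combine the three per-cell-type motif filters
#'
#' A motif survives when it is enriched (`pvalue_hypergeom < p_enrich`,
#' strict), its accessibility deviation is at least `z_min`, and its TF
#' gene(s) pass the expression filter. Provenance for every enriched motif
#' is kept in the result.
#'
#' @param cell_type Cell type label.
#' @param enrichments Output of [enrich_motifs()] for this cell type.
#' @param deviations Output of [motif_deviation()] for this cell type.
#' @param expression Named list of [expression_filter()] results, one per
#'   motif id.
#' @param p_enrich Strict enrichment cutoff. Default `1e-10`.
#' @param z_min Minimum deviation z. Default 1.0.
#' @return List with `cell_type`, `motifs` (surviving motif ids) and
#'   `provenance` (`data.frame` over enriched motifs).
#' @export
select_motifs <- function(cell_type, enrichments, deviations, expression,
                          p_enrich = 1e-10, z_min = 1.0) {
  enr <- enrichments[enrichments$pvalue_hypergeom < p_enrich, , drop = FALSE]
  dev_z <- deviations$deviation_z[match(enr$motif_id, deviations$motif_id)]
  expr_pass <- vapply(enr$motif_id, function(m) {
    isTRUE(expression[[m]]$pass)
  }, logical(1))
  expr_frac <- vapply(enr$motif_id, function(m) {
    f <- expression[[m]]$fractions
    if (is.null(f)) NA_character_ else paste(sprintf("%s=%.3f", names(f), f), collapse = ";")
  }, character(1))
  provenance <- data.frame(
    cell_type = rep(cell_type, nrow(enr)),
    motif_id = enr$motif_id,
    pvalue_hypergeom = enr$pvalue_hypergeom,
    deviation_z = dev_z,
    expression_pass = expr_pass,
    expression_fractions = expr_frac,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  keep <- !is.na(dev_z) & dev_z >= z_min & expr_pass
  list(
    cell_type = cell_type,
    motifs = enr$motif_id[keep],
    provenance = provenance
  )
}
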