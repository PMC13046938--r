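# The analysis core: candidate cis-regulatory elements per cell type,
# per-allele binding scores, differential binding classification, and the
# consistently-disrupted / consistently-enhanced motif verdict.

#' Define single-cell candidate cis-regulatory elements for a cell type
#'
#' A peak from the merged set qualifies as an scCRE of a cell type when it
#' satisfies at least one of: (1) it was called as a peak in that cell
#' type's pseudobulk; (2) it is accessible (count > 0) in at least 5% of
#' that cell type's cells (inclusive).
#'
#' @param atac A [count_matrix()] of cells x peaks (the merged peak set).
#' @param celltype_peak_calls Named list: cell type -> character vector of
#'   called region ids.
#' @param cell_type Target cell type.
#' @param min_fraction Accessible-cell fraction for criterion 2.
#'   Default 0.05.
#' @return `data.frame` with `cell_type`, `region_id`, `source`
#'   (`"called-in-celltype"`, `"accessible-fraction"` or `"both"`).
#' @export
define_sccres <- function(atac, celltype_peak_calls, cell_type,
                          min_fraction = 0.05) {
  stopifnot(inherits(atac, "count_matrix"))
  if (!cell_type %in% atac$cell_type) stop("cell type ", cell_type, " absent")
  cells <- which(atac$cell_type == cell_type)
  acc_frac <- Matrix::colSums(atac$counts[cells, , drop = FALSE] > 0) / length(cells)
  called <- atac$feature_ids %in% (celltype_peak_calls[[cell_type]] %||% character())
  accessible <- acc_frac >= min_fraction
  keep <- called | accessible
  source <- ifelse(
    called & accessible, "both",
    ifelse(called, "called-in-celltype", "accessible-fraction")
  )
  data.frame(
    cell_type = cell_type,
    region_id = atac$feature_ids[keep],
    source = source[keep],
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Binding score of a peak from its motif hits
#'
#' The sum of `-log10(pvalue)` over all hits (both strands, all offsets);
#' a peak with no hits scores 0.
#'
#' @param hits Hit `data.frame` from [scan_region()].
#' @return Non-negative scalar.
#' @export
peak_binding_score <- function(hits) {
  if (nrow(hits) == 0L) return(0)
  if (any(hits$pvalue <= 0)) stop("hit with non-positive p-value")
  sum(-log10(hits$pvalue))
}

#' Differential binding score of one motif on one allele pair
#'
#' Both allele sequences are scanned with the same model (hence the same
#' background and p-value table) at the near-inclusive threshold, and the
#' binding scores differenced. By default `delta = score_risk -
#' score_nonrisk`, so a positive delta means binding gained through the
#' risk allele; `sign = "ref-minus-alt"` restores the opposite
#' orientation. `|delta| > delta_threshold` (strict) calls gained or lost
#' binding.
#'
#' @param pair Allele pair from [build_allele_pair()].
#' @param model Motif model with p-value table.
#' @param p_threshold Scan threshold. Default 0.99.
#' @param delta_threshold Gain/loss cutoff on `|delta|`, strict.
#'   Default 3.
#' @param sign `"risk-minus-nonrisk"` (default) or `"ref-minus-alt"`.
#' @param cell_type Label copied into the result.
#' @return One-row `data.frame`: `cell_type`, `motif_id`, `region_id`,
#'   `score_nonrisk`, `score_risk`, `delta`, `call`.
#' @export
delta_score <- function(pair, model, p_threshold = 0.99, delta_threshold = 3,
                        sign = c("risk-minus-nonrisk", "ref-minus-alt"),
                        cell_type = NA_character_) {
  sign <- match.arg(sign)
  if (nchar(pair$seq_nonrisk) != nchar(pair$seq_risk)) {
    stop("allele pair sequences differ in length for region ", pair$region_id)
  }
  s_nr <- peak_binding_score(
    scan_region(model, pair$seq_nonrisk, p_threshold, pair$region_id)
  )
  s_r <- peak_binding_score(
    scan_region(model, pair$seq_risk, p_threshold, pair$region_id)
  )
  delta <- if (sign == "risk-minus-nonrisk") s_r - s_nr else s_nr - s_r
  call <- classify_delta(delta, delta_threshold)
  data.frame(
    cell_type = cell_type,
    motif_id = model$motif_id,
    region_id = pair$region_id,
    score_nonrisk = s_nr,
    score_risk = s_r,
    delta = delta,
    call = call,
    stringsAsFactors = FALSE
  )
}

#' Classify a differential binding score
#'
#' `gained` iff `delta > threshold`, `lost` iff `delta < -threshold`
#' (both strict), else `unchanged`; a delta exactly at the threshold is
#' unchanged.
#'
#' @param delta Differential binding score(s).
#' @param threshold Strict cutoff on `|delta|`. Default 3.
#' @return Character vector of calls.
#' @export
classify_delta <- function(delta, threshold = 3) {
  ifelse(delta > threshold, "gained",
         ifelse(delta < -threshold, "lost", "unchanged"))
}

#' Consistency verdict for one motif in one cell type
#'
#' A motif is `enhanced` when `n_gained - n_lost >= min_diff`, `disrupted`
#' when `n_lost - n_gained >= min_diff` (both inclusive), else `none`.
#'
#' @param results `data.frame` of [delta_score()] rows for one
#'   (cell type, motif).
#' @param min_diff Required gained-vs-lost difference. Default 5.
#' @return One-row `data.frame`: `cell_type`, `motif_id`, `n_gained`,
#'   `n_lost`, `n_unchanged`, `verdict`.
#' @export
motif_consistency <- function(results, min_diff = 5) {
  n_gained <- sum(results$call == "gained")
  n_lost <- sum(results$call == "lost")
  verdict <- if (n_gained - n_lost >= min_diff) "enhanced"
    else if (n_lost - n_gained >= min_diff) "disrupted"
    else "none"
  data.frame(
    cell_type = results$cell_type[1],
    motif_id = results$motif_id[1],
    n_gained = n_gained,
    n_lost = n_lost,
    n_unchanged = sum(results$call == "unchanged"),
    verdict = verdict,
    stringsAsFactors = FALSE
  )
}

#' Differential binding analysis for one cell type
#'
#' Scores every SNP-containing scCRE of the cell type against every
#' selected motif and summarizes per-motif consistency.
#'
#' @param pairs Named list of allele pairs (region id -> pair), restricted
#'   to the cell type's scCREs by the caller.
#' @param models Named list of motif models (with p-value tables) for the
#'   cell type's selected motifs.
#' @param cell_type Cell type label.
#' @param p_threshold,delta_threshold,min_diff,sign Passed through to
#'   [delta_score()] and [motif_consistency()].
#' @return List with `results` (per region x motif) and `summary`
#'   (per motif).
#' @export
delta_binding_analysis <- function(pairs, models, cell_type,
                                   p_threshold = 0.99, delta_threshold = 3,
                                   min_diff = 5,
                                   sign = c("risk-minus-nonrisk", "ref-minus-alt")) {
  sign <- match.arg(sign)
  results <- do.call(rbind, lapply(models, function(model) {
    do.call(rbind, lapply(pairs, function(pair) {
      delta_score(pair, model, p_threshold, delta_threshold, sign, cell_type)
    }))
  }))
  rownames(results) <- NULL
  summary <- do.call(rbind, lapply(split(results, results$motif_id), function(df) {
    motif_consistency(df, min_diff)
  }))
  rownames(summary) <- NULL
  list(results = results, summary = summary)
}
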