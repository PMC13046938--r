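# Readers and writers for the external formats the pipeline touches.
# All coordinates are converted to 0-based half-open at read time; every
# other module operates on the in-memory objects returned here.

#' Read a FASTA file into a genome source
#'
#' Sequences are uppercased and any character outside `ACGTN` is coerced to
#' `N` with a warning. Contig names must be unique.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase DNA sequences (one per contig).
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    stop("empty FASTA file: ", path)
  }
  nm <- sub("\\s.*$", "", names(seqs))
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0L) {
    stop("duplicate contig ", dup[[1L]], " in ", path)
  }
  out <- toupper(as.character(seqs))
  names(out) <- nm
  if (any(nchar(out) == 0L)) {
    stop("empty sequence for contig ", nm[nchar(out) == 0L][[1L]])
  }
  n_bad <- sum(vapply(
    strsplit(out, ""),
    function(ch) sum(!ch %in% c("A", "C", "G", "T", "N")),
    integer(1)
  ))
  if (n_bad > 0L) {
    out <- vapply(out, function(s) gsub("[^ACGTN]", "N", s), character(1))
    warning(n_bad, " non-ACGTN base(s) coerced to N in ", path)
  }
  out
}

#' Write a genome source to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a BED3/BED4 file
#'
#' Coordinates are BED-standard 0-based half-open and kept that way
#' internally. When a fourth column is absent, region ids default to
#' `"contig:start-end"`.
#'
#' @param path Path to a tab-separated BED file (no header).
#' @return A `data.frame` with columns `contig`, `start`, `end`, `region_id`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(
      contig = character(), start = integer(), end = integer(),
      region_id = character(), stringsAsFactors = FALSE
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- min(lengths(fields))
  if (ncol_min < 3L) {
    stop("BED line ", which(lengths(fields) < 3L)[[1L]], ": fewer than 3 columns")
  }
  contig <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("BED line ", which(is.na(start) | is.na(end))[[1L]], ": non-integer coordinate")
  }
  bad <- which(start >= end | start < 0L)
  if (length(bad) > 0L) {
    stop("BED line ", bad[[1L]], ": start >= end or negative start")
  }
  region_id <- ifelse(
    lengths(fields) >= 4L,
    vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else "", character(1)),
    paste0(contig, ":", start, "-", end)
  )
  if (anyDuplicated(region_id)) {
    stop("duplicate region_id ", region_id[duplicated(region_id)][[1L]])
  }
  data.frame(
    contig = contig, start = start, end = end, region_id = region_id,
    stringsAsFactors = FALSE
  )
}

#' Write regions as BED4
#'
#' @param regions Region `data.frame` as returned by [read_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  stopifnot(all(c("contig", "start", "end", "region_id") %in% names(regions)))
  utils::write.table(
    regions[, c("contig", "start", "end", "region_id")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read transcription factor motifs
#'
#' Supports the JASPAR text dialect (`>ID NAME` header plus four `A [ ... ]`
#' rows) and the MEME minimal motif format (letter-probability matrices).
#' Matrices are returned as raw 4 x w numerics in A,C,G,T row order;
#' log-odds conversion happens in [build_pwm()]. Dimer names containing
#' `"::"` are kept verbatim.
#'
#' @param path Path to the motif file.
#' @param format `"jaspar"` or `"meme"`.
#' @return List of motifs; each element has `motif_id`, `tf_name`, `pfm`.
#' @export
read_motifs <- function(path, format = c("jaspar", "meme")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "jaspar") parse_jaspar(lines) else parse_meme(lines)
}

parse_jaspar <- function(lines) {
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no JASPAR records found")
  out <- vector("list", length(hdr))
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    head_line <- sub("^>\\s*", "", lines[hdr[i]])
    parts <- strsplit(head_line, "\\s+")[[1L]]
    motif_id <- parts[[1L]]
    tf_name <- if (length(parts) >= 2L) parts[[2L]] else parts[[1L]]
    body <- lines[(hdr[i] + 1L):(bounds[i + 1L] - 1L)]
    body <- body[nzchar(trimws(body))]
    if (length(body) != 4L) {
      stop("motif ", motif_id, ": expected 4 matrix rows, got ", length(body))
    }
    rows <- lapply(body, function(l) {
      nums <- regmatches(l, gregexpr("-?[0-9.eE+]+", l))[[1L]]
      as.numeric(nums)
    })
    if (length(unique(lengths(rows))) != 1L) {
      stop("motif ", motif_id, ": ragged matrix rows")
    }
    pfm <- do.call(rbind, rows)
    rownames(pfm) <- c("A", "C", "G", "T")
    if (any(pfm < 0)) stop("motif ", motif_id, ": negative entries")
    if (ncol(pfm) < 1L) stop("motif ", motif_id, ": zero-width matrix")
    out[[i]] <- list(motif_id = motif_id, tf_name = tf_name, pfm = pfm)
  }
  out
}

parse_meme <- function(lines) {
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0L) stop("no MEME MOTIF records found")
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    parts <- strsplit(trimws(lines[starts[i]]), "\\s+")[[1L]]
    motif_id <- parts[[2L]]
    tf_name <- if (length(parts) >= 3L) parts[[3L]] else motif_id
    j <- starts[i]
    lp <- grep("^letter-probability matrix", lines[j:length(lines)])[1L]
    if (is.na(lp)) stop("motif ", motif_id, ": no letter-probability matrix")
    j <- j + lp - 1L
    k <- j + 1L
    rows <- list()
    while (k <= length(lines) && grepl("^\\s*[0-9.]", lines[k])) {
      rows[[length(rows) + 1L]] <- as.numeric(strsplit(trimws(lines[k]), "\\s+")[[1L]])
      k <- k + 1L
    }
    if (length(rows) == 0L) stop("motif ", motif_id, ": empty matrix")
    if (any(lengths(rows) != 4L)) {
      stop("motif ", motif_id, ": expected 4 columns (A C G T) per position")
    }
    pfm <- t(do.call(rbind, rows))  # MEME rows are positions; transpose to 4 x w
    rownames(pfm) <- c("A", "C", "G", "T")
    if (any(pfm < 0)) stop("motif ", motif_id, ": negative entries")
    out[[i]] <- list(motif_id = motif_id, tf_name = tf_name, pfm = pfm)
  }
  out
}

#' Write motifs in JASPAR text format
#'
#' @param motifs List of motifs as returned by [read_motifs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motifs_jaspar <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(paste0(">", m$motif_id, " ", m$tf_name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(
        paste0(b, " [ ", paste(format(m$pfm[b, ], trim = TRUE), collapse = " "), " ]"),
        con
      )
    }
  }
  invisible(path)
}

#' Read a GWAS summary-statistics table
#'
#' Expects a tab-separated file with header columns `rsid`, `chrom`, `pos`
#' (1-based), `allele_other`, `allele_effect`, `beta`, `pvalue`. Positions
#' are converted to 0-based once, here. Rows whose alleles are not single
#' `ACGT` bases (indels, multi-allelic encodings) are skipped and counted
#' in the `n_skipped` attribute of the result.
#'
#' @param path Path to the GWAS TSV.
#' @return A `data.frame` of variant records with columns `rsid`, `contig`,
#'   `pos0`, `allele_nonrisk`, `allele_risk`, `beta`, `pvalue`, `recoded`;
#'   the effect allele is carried in `allele_risk` until [recode_risk()]
#'   establishes risk orientation. Attribute `n_skipped` counts dropped rows.
#' @export
read_gwas <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("rsid", "chrom", "pos", "allele_other", "allele_effect", "beta", "pvalue")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("GWAS table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1)) {
    stop("GWAS p-values must lie in (0, 1]")
  }
  base_ok <- function(a) a %in% c("A", "C", "G", "T")
  keep <- base_ok(df$allele_other) & base_ok(df$allele_effect) &
    df$allele_other != df$allele_effect
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    warning(n_skipped, " non-SNP (indel/multi-allelic) row(s) skipped")
  }
  df <- df[keep, , drop = FALSE]
  out <- data.frame(
    rsid = df$rsid,
    contig = df$chrom,
    pos0 = as.integer(df$pos) - 1L,
    allele_nonrisk = df$allele_other,
    allele_risk = df$allele_effect,
    beta = as.numeric(df$beta),
    pvalue = as.numeric(df$pvalue),
    recoded = FALSE,
    stringsAsFactors = FALSE
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write variant records back to the GWAS TSV layout
#'
#' Inverse of [read_gwas()] for valid records: positions go out 1-based.
#'
#' @param snps Variant `data.frame` as returned by [read_gwas()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gwas <- function(snps, path) {
  out <- data.frame(
    rsid = snps$rsid,
    chrom = snps$contig,
    pos = snps$pos0 + 1L,
    allele_other = snps$allele_nonrisk,
    allele_effect = snps$allele_risk,
    beta = snps$beta,
    pvalue = snps$pvalue
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct and validate a cell-by-feature count matrix
#'
#' @param counts Sparse non-negative integer matrix, cells x features.
#' @param cell_ids,feature_ids Character vectors naming the two axes.
#' @param cell_type,donor Per-cell annotation vectors.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, cell_ids, feature_ids, cell_type, donor) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (nrow(counts) != length(cell_ids) || ncol(counts) != length(feature_ids)) {
    stop("count matrix dimensions do not match id vectors")
  }
  if (length(cell_type) != length(cell_ids) || length(donor) != length(cell_ids)) {
    stop("annotation vectors must have one entry per cell")
  }
  if (anyDuplicated(feature_ids)) stop("feature_ids must be unique")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (any(counts@x < 0)) stop("negative count in matrix")
  if (any(counts@x != round(counts@x))) stop("non-integer count in matrix")
  dimnames(counts) <- list(cell_ids, feature_ids)
  structure(
    list(
      counts = counts,
      cell_ids = as.character(cell_ids),
      feature_ids = as.character(feature_ids),
      cell_type = as.character(cell_type),
      donor = as.character(donor)
    ),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(
    "count_matrix:", length(x$cell_ids), "cells x", length(x$feature_ids),
    "features;", length(unique(x$cell_type)), "cell types,",
    length(unique(x$donor)), "donors\n"
  )
  invisible(x)
}

#' Read a MatrixMarket count matrix with sidecar annotations
#'
#' @param mtx_path MatrixMarket coordinate file (cells x features).
#' @param cells_path One cell id per line.
#' @param features_path One feature id per line.
#' @param annot_path TSV with header `cell_id`, `cell_type`, `donor`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(mtx_path, cells_path, features_path, annot_path) {
  m <- Matrix::readMM(mtx_path)
  if (any(m@x < 0)) stop("negative count in ", mtx_path)
  if (any(m@x != round(m@x))) stop("non-integer entry in ", mtx_path)
  cell_ids <- readLines(cells_path)
  feature_ids <- readLines(features_path)
  if (nrow(m) != length(cell_ids) || ncol(m) != length(feature_ids)) {
    stop(
      "dimension mismatch: matrix is ", nrow(m), " x ", ncol(m),
      " but sidecars list ", length(cell_ids), " cells and ",
      length(feature_ids), " features"
    )
  }
  annot <- utils::read.delim(annot_path, stringsAsFactors = FALSE)
  need <- c("cell_id", "cell_type", "donor")
  if (!all(need %in% names(annot))) {
    stop("annotation TSV missing column(s): ", paste(setdiff(need, names(annot)), collapse = ", "))
  }
  idx <- match(cell_ids, annot$cell_id)
  if (anyNA(idx)) {
    miss <- cell_ids[is.na(idx)]
    stop(
      "cells missing annotation: ",
      paste(utils::head(miss, 5L), collapse = ", "),
      if (length(miss) > 5L) sprintf(" (and %d more)", length(miss) - 5L) else ""
    )
  }
  count_matrix(m, cell_ids, feature_ids, annot$cell_type[idx], annot$donor[idx])
}

#' Write a count matrix as MatrixMarket plus sidecar TSVs
#'
#' @param x A [count_matrix()].
#' @param mtx_path,cells_path,features_path,annot_path Output paths.
#' @return `mtx_path`, invisibly.
#' @export
write_count_matrix <- function(x, mtx_path, cells_path, features_path, annot_path) {
  stopifnot(inherits(x, "count_matrix"))
  Matrix::writeMM(x$counts, mtx_path)
  writeLines(x$cell_ids, cells_path)
  writeLines(x$feature_ids, features_path)
  utils::write.table(
    data.frame(cell_id = x$cell_ids, cell_type = x$cell_type, donor = x$donor),
    annot_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(mtx_path)
}

#' Read a genotype dosage table
#'
#' Rows are SNPs (first column `rsid`), remaining columns are donors; values
#' are risk-allele dosages 0/1/2 or NA.
#'
#' @param path Path to the dosage TSV.
#' @return Numeric matrix, SNPs x donors, with rsid rownames.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[[1L]] != "rsid") stop("genotype table must start with an rsid column")
  g <- as.matrix(df[, -1L, drop = FALSE])
  mode(g) <- "numeric"
  rownames(g) <- df$rsid
  bad <- !(g %in% c(0, 1, 2)) & !is.na(g)
  if (any(bad)) stop("genotype dosages must be 0, 1, 2 or NA")
  g
}

#' Write a genotype dosage table
#'
#' @param g SNPs x donors dosage matrix with rsid rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  df <- data.frame(rsid = rownames(g), g, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
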