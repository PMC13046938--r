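# Position weight matrix construction, exact score p-values by dynamic
# programming over a discretized score lattice, and two-strand scanning.
#
# Scores are log2 odds against a 0-order background. P-values are upper
# tails of the exact distribution of the window score of an i.i.d.
# background sequence, computed by per-column convolution on an integer
# score grid shared between scoring and lookup, so a scanned window's
# p-value is exactly the table entry for its discretized score.

BASES <- c("A", "C", "G", "T")

#' Build a log-odds position weight matrix
#'
#' `pwm[b, j] = log2((pfm[b, j] + pseudocount * background[b]) /
#' (colsum_j + pseudocount) / background[b])`. The pseudocount is
#' distributed across bases proportionally to the background.
#'
#' @param pfm 4 x w non-negative matrix of base counts (rows A, C, G, T).
#' @param background Base probabilities, length 4, strictly positive,
#'   summing to 1. Default uniform.
#' @param pseudocount Positive smoothing mass added per column. Default 0.1.
#' @param motif_id,tf_name Identifiers carried through to hits.
#' @return A `motif_model` list with `pfm`, `pwm`, `background`,
#'   `pseudocount`, `width`; the p-value table is attached by
#'   [score_pvalue_table()].
#' @export
build_pwm <- function(pfm, background = rep(0.25, 4), pseudocount = 0.1,
                      motif_id = "motif", tf_name = motif_id) {
  pfm <- as.matrix(pfm)
  if (nrow(pfm) != 4L) stop("pfm must have 4 rows (A, C, G, T)")
  if (ncol(pfm) < 1L) stop("pfm must have at least one column")
  if (any(pfm < 0)) stop("pfm entries must be non-negative")
  colsums <- colSums(pfm)
  if (any(colsums <= 0)) stop("pfm column with zero sum at position ", which(colsums <= 0)[[1L]])
  if (length(background) != 4L || any(background <= 0)) {
    stop("background must be 4 strictly positive probabilities")
  }
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  prob <- sweep(pfm + pseudocount * background, 2L, colsums + pseudocount, "/")
  pwm <- log2(prob / background)
  rownames(pwm) <- rownames(prob) <- BASES
  structure(
    list(
      motif_id = motif_id, tf_name = tf_name, width = ncol(pfm),
      pfm = pfm, pwm = pwm, background = as.numeric(background),
      pseudocount = pseudocount, pvalue_table = NULL
    ),
    class = "motif_model"
  )
}

#' @export
print.motif_model <- function(x, ...) {
  cat(
    "motif_model", x$motif_id, "(", x$tf_name, "), width", x$width,
    if (is.null(x$pvalue_table)) "- no p-value table" else
      sprintf("- p-value table (granularity %d)", x$pvalue_table$granularity),
    "\n"
  )
  invisible(x)
}

#' Attach the exact score p-value table to a motif model
#'
#' Discretizes each PWM column onto an integer grid (`granularity` bins per
#' column for the widest column) and convolves the per-column score
#' distributions under the background model. The resulting table gives
#' `p(s) = P(Score >= s)` for every achievable discretized score;
#' `p` is non-increasing in the score and equals 1 at the minimum
#' achievable score.
#'
#' @param model A `motif_model` from [build_pwm()].
#' @param granularity Number of discretization bins per column (>= 10).
#'   Default 1000.
#' @return The model with `$pvalue_table` set (fields `eps` bin width,
#'   `K` integer score matrix, `min_int`, `max_int`, `pvals`).
#' @export
score_pvalue_table <- function(model, granularity = 1000L) {
  stopifnot(inherits(model, "motif_model"))
  if (granularity < 10L) stop("granularity must be at least 10")
  pwm <- model$pwm
  w <- model$width
  col_range <- apply(pwm, 2L, function(x) max(x) - min(x))
  eps <- max(col_range) / granularity
  if (eps <= 0) eps <- .Machine$double.eps
  K <- matrix(as.integer(round(pwm / eps)), nrow = 4L)
  min_int <- sum(apply(K, 2L, min))
  max_int <- sum(apply(K, 2L, max))
  # distribution over integer total scores, indexed from min achievable
  dist <- 1
  lo <- 0L
  bg <- model$background
  for (j in seq_len(w)) {
    kj <- K[, j]
    klo <- min(kj)
    width_new <- length(dist) + max(kj) - klo
    nd <- numeric(width_new)
    for (b in 1:4) {
      sh <- kj[b] - klo
      idx <- seq_along(dist) + sh
      nd[idx] <- nd[idx] + dist * bg[b]
    }
    dist <- nd
    lo <- lo + klo
  }
  pvals <- rev(cumsum(rev(dist)))
  pvals <- pmin(pvals, 1)
  model$pvalue_table <- list(
    granularity = as.integer(granularity), eps = eps, K = K,
    min_int = min_int, max_int = max_int, pvals = pvals
  )
  model
}

#' Look up p-values for discretized window scores
#'
#' @param model Motif model with a p-value table.
#' @param s_int Integer score(s) on the model's grid.
#' @return Upper-tail p-value(s) in (0, 1].
#' @keywords internal
lookup_pvalue <- function(model, s_int) {
  tb <- model$pvalue_table
  if (is.null(tb)) stop("motif model has no p-value table; call score_pvalue_table()")
  idx <- pmin(pmax(s_int - tb$min_int + 1L, 1L), length(tb$pvals))
  tb$pvals[idx]
}

#' Estimate a 0-order background from sequences
#'
#' Pools base frequencies over the given sequences and their reverse
#' complements (so the background is strand-symmetric); `N` bases are
#' ignored.
#'
#' @param seqs Character vector of DNA sequences.
#' @return Length-4 probability vector (A, C, G, T).
#' @export
estimate_background <- function(seqs) {
  counts <- colSums(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(seqs), BASES
  ))
  counts <- counts + rev(counts)  # pool both strands: A<->T, C<->G
  if (sum(counts) == 0) stop("no ACGT bases in sequences")
  counts <- pmax(counts, 1e-9)
  as.numeric(counts / sum(counts))
}

encode_dna <- function(sequence) {
  ch <- strsplit(toupper(sequence), "")[[1L]]
  codes <- match(ch, BASES)  # N and anything else -> NA
  codes
}

#' Scan a sequence with a motif model on both strands
#'
#' Every window (both strands) whose match p-value is at or below
#' `p_threshold` is reported. Windows containing `N` are skipped. The
#' reverse-strand score is the score of the reverse complement of the
#' window; offsets always refer to the forward-strand window start.
#' Hits are ordered by offset, `+` strand before `-`.
#'
#' @param model Motif model with a p-value table.
#' @param sequence DNA string over ACGTN.
#' @param p_threshold Report hits with p-value <= this. Default 0.99.
#' @param region_id Identifier copied into the hit table.
#' @return A `data.frame` with columns `region_id`, `motif_id`, `offset`
#'   (0-based), `strand`, `score`, `pvalue`. Sequences shorter than the
#'   motif give zero rows.
#' @export
scan_region <- function(model, sequence, p_threshold = 0.99, region_id = "region") {
  stopifnot(inherits(model, "motif_model"))
  if (is.null(model$pvalue_table)) stop("call score_pvalue_table() before scanning")
  if (p_threshold <= 0 || p_threshold > 1) stop("p_threshold must be in (0, 1]")
  w <- model$width
  codes <- encode_dna(sequence)
  L <- length(codes)
  empty <- data.frame(
    region_id = character(), motif_id = character(), offset = integer(),
    strand = character(), score = numeric(), pvalue = numeric(),
    stringsAsFactors = FALSE
  )
  if (L < w) return(empty)
  n_off <- L - w + 1L
  K <- model$pvalue_table$K
  pwm <- model$pwm
  # reverse-complement scan = forward scan with base-complemented,
  # column-reversed matrices
  Krc <- K[4:1, w:1, drop = FALSE]
  pwmrc <- pwm[4:1, w:1, drop = FALSE]
  s_f <- s_r <- integer(n_off)
  sc_f <- sc_r <- numeric(n_off)
  valid <- !is.na(codes)
  win_ok <- rep(TRUE, n_off)
  codes0 <- ifelse(valid, codes, 1L)
  off <- seq_len(n_off)
  for (j in seq_len(w)) {
    cj <- codes0[off + j - 1L]
    win_ok <- win_ok & valid[off + j - 1L]
    s_f <- s_f + K[cbind(cj, j)]
    s_r <- s_r + Krc[cbind(cj, j)]
    sc_f <- sc_f + pwm[cbind(cj, j)]
    sc_r <- sc_r + pwmrc[cbind(cj, j)]
  }
  p_f <- lookup_pvalue(model, s_f)
  p_r <- lookup_pvalue(model, s_r)
  keep_f <- win_ok & p_f <= p_threshold
  keep_r <- win_ok & p_r <= p_threshold
  strand_hits <- function(keep, strand, sc, p) {
    n <- sum(keep)
    data.frame(
      region_id = rep(region_id, n), motif_id = rep(model$motif_id, n),
      offset = off[keep] - 1L, strand = rep(strand, n),
      score = sc[keep], pvalue = p[keep],
      stringsAsFactors = FALSE
    )
  }
  hits <- rbind(
    strand_hits(keep_f, "+", sc_f, p_f),
    strand_hits(keep_r, "-", sc_r, p_r)
  )
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Consensus sequence of a motif model
#'
#' @param model A `motif_model`.
#' @return Character string of per-column maximum-count bases.
#' @export
motif_consensus <- function(model) {
  paste0(BASES[apply(model$pfm, 2L, which.max)], collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param sequence DNA string over ACGTN.
#' @return The reverse complement.
#' @export
revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' Write motif hits as TSV
#'
#' @param hits Hit `data.frame` from [scan_region()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
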