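# Shared fixtures and independent oracles used across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# high-information PFM with a near-deterministic anchor column, built by
# hand so tests do not depend on the generator's internals
toy_pfm <- function(consensus, anchor_col = ceiling(nchar(consensus) / 2)) {
  bases <- c("A", "C", "G", "T")
  cons <- match(strsplit(consensus, "")[[1L]], bases)
  w <- length(cons)
  pfm <- matrix(150, nrow = 4, ncol = w, dimnames = list(bases, NULL))
  for (j in seq_len(w)) pfm[cons[j], j] <- 550
  pfm[, anchor_col] <- 1
  pfm[cons[anchor_col], anchor_col] <- 997
  pfm
}

# Enumeration oracle for exact motif p-values: scores and weights of all
# 4^w windows under the background, with tie groups formed at a 1e-9
# tolerance (summation-order floating point noise otherwise splits exact
# ties). Returns per-window enumeration p-values, the DP p-values at the
# same windows, and the background mass of the discretization band around
# each window score (the theoretical bound on any DP/enumeration gap).
enum_vs_dp <- function(model) {
  pwm <- model$pwm
  w <- model$width
  bg <- model$background
  K <- model$pvalue_table$K
  eps <- model$pvalue_table$eps
  sc <- 0; wt <- 1; si <- 0
  for (j in seq_len(w)) {
    sc <- as.vector(outer(sc, pwm[, j], "+"))
    wt <- as.vector(outer(wt, bg, "*"))
    si <- as.vector(outer(si, K[, j], "+"))
  }
  ord <- order(sc, decreasing = TRUE)
  s_sorted <- sc[ord]
  cs <- cumsum(wt[ord])
  grp <- cumsum(c(TRUE, diff(s_sorted) < -1e-9))
  grp_p <- tapply(seq_along(grp), grp, function(ix) cs[max(ix)])
  p_enum <- numeric(length(sc))
  p_enum[ord] <- as.numeric(grp_p[grp])
  p_dp <- deltabind:::lookup_pvalue(model, si)
  band <- (w + 1) * eps
  band_mass <- vapply(sc, function(s) sum(wt[abs(sc - s) <= band]), numeric(1))
  list(p_enum = p_enum, p_dp = p_dp, band_mass = band_mass,
       max_diff = max(abs(p_dp - p_enum)))
}

# closed-form upper-tail hypergeometric, independent of phyper
hyper_oracle <- function(N, K, n, k) {
  xs <- k:min(K, n)
  xs <- xs[n - xs <= N - K & xs >= 0]
  if (length(xs) == 0L) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# delta binding score computed only from windows overlapping a SNP
# position (locality oracle)
local_delta <- function(pair, model, p_threshold = 0.99) {
  w <- model$width
  L <- nchar(pair$seq_nonrisk)
  offs <- unique(unlist(lapply(pair$snp_offsets, function(s) {
    max(0L, s - w + 1L):min(L - w, s)
  })))
  part <- function(seq) {
    h <- scan_region(model, seq, p_threshold, pair$region_id)
    h <- h[h$offset %in% offs, , drop = FALSE]
    if (nrow(h) == 0L) 0 else sum(-log10(h$pvalue))
  }
  part(pair$seq_risk) - part(pair$seq_nonrisk)
}

# small ready-made motif model shared by several files
tiny_model <- function(consensus = "ACGTACGT", granularity = 1000) {
  score_pvalue_table(
    build_pwm(toy_pfm(consensus), motif_id = paste0("toy_", consensus)),
    granularity
  )
}
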