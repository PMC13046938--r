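test_that("scCREs are the union of peak calls and the accessibility criterion", {
  set.seed(2)
  # 100 cells of the target type; peak accessibility planted per column
  frac <- c(0.01, 0.06, 0.04, 0.30)
  counts <- sapply(frac, function(f) {
    v <- numeric(120)
    v[seq_len(round(f * 100))] <- 1  # first 100 cells are the target type
    v
  })
  atac <- count_matrix(Matrix::Matrix(counts, sparse = TRUE),
                       sprintf("c%03d", 1:120),
                       c("called_low", "uncalled_high", "uncalled_4pct", "both"),
                       rep(c("T", "other"), c(100, 20)),
                       rep("D1", 120))
  calls <- list(T = c("called_low", "both"))
  sc <- define_sccres(atac, calls, "T")
  expect_setequal(sc$region_id, c("called_low", "uncalled_high", "both"))
  expect_identical(sc$source[sc$region_id == "called_low"], "called-in-celltype")
  expect_identical(sc$source[sc$region_id == "uncalled_high"], "accessible-fraction")
  expect_identical(sc$source[sc$region_id == "both"], "both")
  expect_false("uncalled_4pct" %in% sc$region_id)  # below 5%, not called
})

test_that("binding score is the sum of -log10 p over hits, 0 when empty", {
  empty <- data.frame(region_id = character(), motif_id = character(),
                      offset = integer(), strand = character(),
                      score = numeric(), pvalue = numeric())
  expect_identical(peak_binding_score(empty), 0)
  hits <- data.frame(pvalue = c(0.1, 0.01))
  expect_equal(peak_binding_score(hits), 3)
  expect_equal(peak_binding_score(hits[2:1, , drop = FALSE]), 3)
  expect_error(peak_binding_score(data.frame(pvalue = c(0.1, 0))),
               "non-positive")
})

test_that("delta classification edges are strict at the threshold", {
  expect_identical(classify_delta(3.0), "unchanged")
  expect_identical(classify_delta(-3.0), "unchanged")
  expect_identical(classify_delta(3.0000001), "gained")
  expect_identical(classify_delta(-3.0000001), "lost")
  expect_identical(classify_delta(0), "unchanged")
})

make_pair <- function(seq_nonrisk, seq_risk, offsets, rsids = NULL,
                      region_id = "r") {
  list(region_id = region_id, seq_nonrisk = seq_nonrisk, seq_risk = seq_risk,
       snps_applied = rsids %||% sprintf("s%d", seq_along(offsets)),
       snp_offsets = offsets, n_dropped = 0L)
}

# plant `site` into `seq` at 0-based offset
with_site <- function(seq, site, at) {
  paste0(substr(seq, 1, at), site, substr(seq, at + nchar(site) + 1, nchar(seq)))
}

test_that("identical allele sequences give delta 0 and unchanged", {
  m <- tiny_model("GATTACAGAT")
  s <- random_dna(120)
  res <- delta_score(make_pair(s, s, integer(0)), m)
  expect_identical(res$delta, 0)
  expect_identical(res$call, "unchanged")
  expect_error(
    delta_score(make_pair(s, substr(s, 1, 100), integer(0)), m),
    "length"
  )
})

test_that("ablation of a planted anchor loses binding; creation gains it", {
  set.seed(21)
  cons <- "GATTACAGAT"
  anchor <- 5L
  m <- tiny_model(cons)
  n_neg <- n_pos <- 0L
  reps <- 100
  for (r in 1:reps) {
    bg_seq <- random_dna(200)
    at <- sample(0:(200 - 10), 1)
    intact <- with_site(bg_seq, cons, at)
    broken_site <- cons
    substr(broken_site, anchor, anchor) <- setdiff(
      c("A", "C", "G", "T"), substr(cons, anchor, anchor)
    )[sample.int(3, 1)]
    broken <- with_site(bg_seq, broken_site, at)
    snp_off <- at + anchor - 1L
    lost <- delta_score(make_pair(intact, broken, snp_off), m)
    gained <- delta_score(make_pair(broken, intact, snp_off), m)
    n_neg <- n_neg + (lost$delta < 0)
    n_pos <- n_pos + (gained$delta > 0)
  }
  expect_gte(n_neg, 95)
  expect_gte(n_pos, 95)
})

test_that("delta is local to windows overlapping the SNPs", {
  set.seed(31)
  m <- tiny_model("TTGACAGCTA")
  for (r in 1:30) {
    seq <- random_dna(150)
    pos <- sort(sample(0:149, sample(1:3, 1)))
    risk <- seq
    for (p in pos) {
      substr(risk, p + 1, p + 1) <- sample(c("A", "C", "G", "T"), 1)
    }
    pair <- make_pair(seq, risk, pos)
    full <- delta_score(pair, m)$delta
    expect_equal(full, local_delta(pair, m), tolerance = 1e-9)
  }
})

test_that("swapping allele roles negates deltas and swaps verdicts", {
  set.seed(41)
  m <- tiny_model("GATTACAGAT")
  rows <- lapply(1:25, function(r) {
    seq <- random_dna(150)
    pos <- sample(0:140, 1)
    risk <- seq
    substr(risk, pos + 1, pos + 1) <- sample(c("A", "C", "G", "T"), 1)
    fwd <- delta_score(make_pair(seq, risk, pos), m)
    swp <- delta_score(make_pair(risk, seq, pos), m)
    expect_equal(swp$delta, -fwd$delta, tolerance = 1e-9)
    fwd
  })
  results <- do.call(rbind, rows)
  results$cell_type <- "ct"
  cons <- motif_consistency(results)
  expect_identical(cons$n_gained + cons$n_lost + cons$n_unchanged, nrow(results))
  # the ref-minus-alt flag mirrors the default orientation
  seq <- random_dna(120)
  risk <- seq
  substr(risk, 50, 50) <- "A"
  pair <- make_pair(seq, risk, 49L)
  expect_equal(delta_score(pair, m, sign = "ref-minus-alt")$delta,
               -delta_score(pair, m)$delta)
})

test_that("consistency verdict applies the >= 5 difference rule", {
  fake <- function(n_gained, n_lost, n_unchanged = 0) {
    data.frame(
      cell_type = "ct", motif_id = "m",
      call = rep(c("gained", "lost", "unchanged"),
                 c(n_gained, n_lost, n_unchanged)),
      stringsAsFactors = FALSE
    )
  }
  expect_identical(motif_consistency(fake(10, 2))$verdict, "enhanced")
  expect_identical(motif_consistency(fake(4, 0))$verdict, "none")
  expect_identical(motif_consistency(fake(0, 5))$verdict, "disrupted")  # inclusive
  expect_identical(motif_consistency(fake(5, 0))$verdict, "enhanced")
})

test_that("delta_binding_analysis aggregates results and conserves counts", {
  set.seed(51)
  m1 <- tiny_model("GATTACAGAT")
  m2 <- tiny_model("TTGACAGCTA")
  pairs <- lapply(1:6, function(i) {
    seq <- random_dna(100)
    risk <- seq
    substr(risk, 40, 40) <- "C"
    make_pair(seq, risk, 39L, region_id = paste0("r", i))
  })
  names(pairs) <- sprintf("r%d", 1:6)
  out <- delta_binding_analysis(pairs, list(gat = m1, ttg = m2), "ct")
  expect_identical(nrow(out$results), 12L)
  expect_identical(nrow(out$summary), 2L)
  with(out$summary, expect_true(all(n_gained + n_lost + n_unchanged == 6L)))
})
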