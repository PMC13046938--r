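# builds a cells x peaks matrix with planted markers for one cell type
make_marker_atac <- function(n_donors = 10, cells_per = 10, n_peaks = 500,
                             n_markers = 50, fold = 8, base_rate = 0.2,
                             seed = 42) {
  set.seed(seed)
  n_cells <- 2 * n_donors * cells_per
  cell_type <- rep(c("target", "other"), each = n_donors * cells_per)
  donor <- rep(rep(sprintf("D%02d", 1:n_donors), each = cells_per), 2)
  rate <- matrix(base_rate, n_cells, n_peaks)
  rate[cell_type == "target", seq_len(n_markers)] <- base_rate * fold
  counts <- matrix(rpois(n_cells * n_peaks, rate), n_cells)
  count_matrix(Matrix::Matrix(counts, sparse = TRUE),
               sprintf("c%04d", seq_len(n_cells)),
               sprintf("pk%03d", seq_len(n_peaks)),
               cell_type, donor)
}

test_that("planted marker peaks are recovered at the stated thresholds", {
  atac <- make_marker_atac()
  res <- call_marker_peaks(atac, "target")
  planted <- sprintf("pk%03d", 1:50)
  recovered <- res$region_id[res$marker]
  expect_gte(sum(planted %in% recovered), 45)
  # few false markers among the 450 null peaks
  expect_lte(sum(!recovered %in% planted), 5)
  expect_error(call_marker_peaks(atac, "absent"), "absent")
})

test_that("identical in/out accessibility gives null p-values, no markers", {
  set.seed(1)
  n_cells <- 80
  counts <- matrix(rpois(n_cells * 20, 1), n_cells)
  atac <- count_matrix(Matrix::Matrix(counts, sparse = TRUE),
                       sprintf("c%03d", 1:n_cells), sprintf("p%02d", 1:20),
                       rep(c("a", "b"), each = 40),
                       rep(rep(sprintf("D%d", 1:4), each = 10), 2))
  res <- call_marker_peaks(atac, "a")
  expect_false(any(res$marker))
  expect_true(all(res$fdr >= res$pvalue))  # BH never lowers a p-value
})

test_that("hypergeometric enrichment matches the closed-form value", {
  presence <- matrix(FALSE, 10, 1, dimnames = list(NULL, "m"))
  presence[1:4, 1] <- TRUE            # motif in 4 peaks, all markers
  marker <- c(rep(TRUE, 5), rep(FALSE, 5))
  enr <- enrich_motifs(presence, marker, "ct")
  expect_equal(enr$pvalue_hypergeom, 5 / 210)  # == C(4,4) C(6,1) / C(10,5)
  expect_identical(enr$n_motif_marker, 4L)

  # motif absent from markers: upper tail includes X = 0, p = 1
  presence0 <- matrix(FALSE, 10, 1, dimnames = list(NULL, "m"))
  presence0[6:7, 1] <- TRUE
  presence0 <- presence0 & !marker
  enr0 <- enrich_motifs(presence0, marker, "ct")
  expect_equal(enr0$pvalue_hypergeom, 1)

  expect_error(enrich_motifs(presence, rep(FALSE, 10)), "no marker peaks")
})

test_that("enrichment agrees with the combinatorial oracle on random configs", {
  set.seed(8)
  for (rep in 1:25) {
    N <- sample(4:20, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    presence <- matrix(FALSE, N, 1, dimnames = list(NULL, "m"))
    if (K > 0) presence[sample.int(N, K), 1] <- TRUE
    marker <- rep(FALSE, N)
    marker[sample.int(N, n)] <- TRUE
    k <- sum(presence[, 1] & marker)
    enr <- enrich_motifs(presence, marker, "ct")
    expect_equal(enr$pvalue_hypergeom, hyper_oracle(N, K, n, k),
                 tolerance = 1e-12)
  }
})

make_deviation_atac <- function(n_cells = 300, n_peaks = 200, seed = 1,
                                hot_peaks = NULL, hot_fold = 3,
                                other_hot_peaks = NULL) {
  set.seed(seed)
  cell_type <- rep(c("target", "other"), each = n_cells / 2)
  rate <- matrix(0.5, n_cells, n_peaks)
  if (!is.null(hot_peaks)) {
    rate[cell_type == "target", hot_peaks] <- 0.5 * hot_fold
  }
  if (!is.null(other_hot_peaks)) {
    rate[cell_type == "other", other_hot_peaks] <- 0.5 * hot_fold
  }
  counts <- matrix(rpois(n_cells * n_peaks, rate), n_cells)
  count_matrix(Matrix::Matrix(counts, sparse = TRUE),
               sprintf("c%04d", seq_len(n_cells)),
               sprintf("p%03d", seq_len(n_peaks)),
               cell_type,
               rep(sprintf("D%02d", 1:10), length.out = n_cells))
}

test_that("deviation is near zero for random motif peak sets", {
  zs <- vapply(1:20, function(s) {
    atac <- make_deviation_atac(seed = 100 + s)
    presence <- matrix(FALSE, 200, 1, dimnames = list(NULL, "m"))
    set.seed(200 + s)
    presence[sample.int(200, 30), 1] <- TRUE
    gc <- runif(200, 0.3, 0.7)
    motif_deviation(atac, presence, gc, "target", seed = s)$deviation_z
  }, numeric(1))
  expect_true(all(abs(zs) < 0.5))
  expect_lt(abs(mean(zs)), 0.2)
})

test_that("deviation is positive for peaks planted more accessible", {
  # a second cell type contributes peaks with the same global accessibility
  # (hot in their own type), giving the matcher bias-comparable background
  hot <- 1:30
  atac <- make_deviation_atac(seed = 7, hot_peaks = hot, hot_fold = 3,
                              other_hot_peaks = 31:90)
  presence <- matrix(FALSE, 200, 1, dimnames = list(NULL, "m"))
  presence[hot, 1] <- TRUE
  gc <- runif(200, 0.3, 0.7)
  z <- motif_deviation(atac, presence, gc, "target", seed = 1)$deviation_z
  expect_gt(z, 1)
  expect_error(motif_deviation(atac, presence, gc, "target", n_background = 1),
               "insufficient background")
  empty <- matrix(FALSE, 200, 1, dimnames = list(NULL, "m"))
  expect_error(motif_deviation(atac, empty, gc, "target"), "0 peaks")
})

make_rna <- function(fracs, n_cells = 100) {
  # fracs: named per-gene fraction of target cells with nonzero counts
  counts <- sapply(fracs, function(f) {
    v <- numeric(n_cells)
    if (f > 0) v[seq_len(round(f * n_cells))] <- 1
    v
  })
  count_matrix(Matrix::Matrix(counts, sparse = TRUE),
               sprintf("c%03d", seq_len(n_cells)), names(fracs),
               rep("target", n_cells), rep("D1", n_cells))
}

test_that("expression filter is inclusive at 5% and requires all dimer parts", {
  rna <- make_rna(c(FOSL2 = 0.10, JUN = 0.03, LOW = 0.04, EDGE = 0.05))
  expect_true(expression_filter(rna, "target", "EDGE")$pass)    # 5% inclusive
  expect_false(expression_filter(rna, "target", "LOW")$pass)    # 4% fails
  dimer <- expression_filter(rna, "target", "FOSL2::JUN")
  expect_false(dimer$pass)                                      # all parts needed
  expect_equal(unname(dimer$fractions), c(0.10, 0.03))
  expect_message(absent <- expression_filter(rna, "target", "GHOST"),
                 "absent")
  expect_false(absent$pass)
})

test_that("motif selection intersects the three filters monotonically", {
  enr <- data.frame(
    cell_type = "ct", motif_id = c("m1", "m2", "m3", "m4"),
    n_universe = 100, n_marker = 10, n_motif_universe = 20,
    n_motif_marker = 9,
    pvalue_hypergeom = c(1e-12, 1e-12, 1e-12, 1e-10),
    enriched = NA, stringsAsFactors = FALSE
  )
  dev <- data.frame(cell_type = "ct", motif_id = c("m1", "m2", "m3", "m4"),
                    deviation_z = c(2, 0.5, 3, 5), stringsAsFactors = FALSE)
  expr <- list(
    m1 = list(pass = TRUE, fractions = c(g = 0.5)),
    m2 = list(pass = TRUE, fractions = c(g = 0.5)),
    m3 = list(pass = FALSE, fractions = c(g = 0.01)),
    m4 = list(pass = TRUE, fractions = c(g = 0.5))
  )
  sel <- select_motifs("ct", enr, dev, expr)
  expect_identical(sel$motifs, "m1")          # m2 fails z, m3 expression,
                                              # m4 enrichment (p = 1e-10 strict)
  expect_true(all(sel$motifs %in% sel$provenance$motif_id))
  # lowering z_min never shrinks the set
  for (z in c(2, 1, 0.4, 0)) {
    bigger <- select_motifs("ct", enr, dev, expr, z_min = z)$motifs
    expect_true(all(sel$motifs %in% bigger))
    sel_prev <- bigger
  }
})
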