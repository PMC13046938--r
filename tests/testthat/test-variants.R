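make_snps <- function(rsid, contig = "chr1", pos0 = 100L,
                      nonrisk = "A", risk = "G", beta = 0.1, pvalue = 1e-9) {
  data.frame(
    rsid = rsid, contig = contig, pos0 = pos0,
    allele_nonrisk = nonrisk, allele_risk = risk,
    beta = beta, pvalue = pvalue, recoded = FALSE,
    stringsAsFactors = FALSE
  )
}

test_that("genome-wide filter is inclusive at the threshold", {
  snps <- make_snps(c("a", "b", "c"), pvalue = c(5e-8, 5.1e-8, 1e-12))
  kept <- filter_genomewide(snps)
  expect_setequal(kept$rsid, c("a", "c"))
  expect_identical(nrow(filter_genomewide(snps[0, ])), 0L)
  expect_identical(nrow(filter_genomewide(snps, 1.0)), 3L)
})

test_that("risk recoding flips negative effects and is idempotent", {
  snps <- make_snps(c("neg", "pos", "zero"),
                    nonrisk = "A", risk = "G", beta = c(-0.1, 0.1, 0))
  out <- recode_risk(snps)
  expect_identical(out$allele_nonrisk, c("G", "A", "A"))
  expect_identical(out$allele_risk, c("A", "G", "G"))
  expect_equal(out$beta, c(0.1, 0.1, 0))
  expect_identical(out$recoded, c(TRUE, FALSE, FALSE))
  expect_identical(recode_risk(out), out)
  expect_error(recode_risk(make_snps("x", beta = NA_real_)), "finite")
})

test_that("SNP-to-region assignment respects half-open bounds", {
  regions <- data.frame(
    contig = c("chr1", "chr1"), start = c(100L, 150L), end = c(200L, 260L),
    region_id = c("r1", "r2"), stringsAsFactors = FALSE
  )
  snps <- make_snps(c("at_start", "at_end", "in_both", "outside"),
                    pos0 = c(100L, 200L, 160L, 5000L))
  m <- assign_snps_to_regions(snps, regions)
  expect_setequal(m$r1$rsid, c("at_start", "in_both"))      # start inclusive
  expect_setequal(m$r2$rsid, c("at_end", "in_both"))        # end exclusive in r1
  expect_false("at_end" %in% m$r1$rsid)
  expect_false("outside" %in% unlist(lapply(m, `[[`, "rsid")))
})

test_that("assignment agrees with a brute-force interval oracle", {
  set.seed(5)
  starts <- sample.int(1000, 20)
  regions <- data.frame(
    contig = sample(c("c1", "c2"), 20, replace = TRUE),
    start = starts, end = starts + sample.int(200, 20),
    region_id = sprintf("r%02d", 1:20), stringsAsFactors = FALSE
  )
  snps <- make_snps(sprintf("s%02d", 1:50),
                    contig = sample(c("c1", "c2"), 50, replace = TRUE),
                    pos0 = sample.int(1300, 50))
  got <- assign_snps_to_regions(snps, regions)
  for (i in seq_len(nrow(regions))) {
    expected <- snps$rsid[
      snps$contig == regions$contig[i] &
        snps$pos0 >= regions$start[i] & snps$pos0 < regions$end[i]
    ]
    found <- got[[regions$region_id[i]]]$rsid %||% character()
    expect_setequal(found, expected)
  }
})

test_that("allele pairs substitute all SNPs simultaneously", {
  genome <- c(ctg = "ACGTACGT")
  region <- data.frame(contig = "ctg", start = 0L, end = 8L, region_id = "r",
                       stringsAsFactors = FALSE)
  snp <- make_snps("s1", contig = "ctg", pos0 = 2L, nonrisk = "G", risk = "T")
  pair <- build_allele_pair(region, genome, snp)
  expect_identical(pair$seq_nonrisk, "ACGTACGT")
  expect_identical(pair$seq_risk, "ACTTACGT")

  two <- rbind(snp, make_snps("s2", contig = "ctg", pos0 = 6L,
                              nonrisk = "G", risk = "A"))
  pair2 <- build_allele_pair(region, genome, two)
  expect_identical(pair2$seq_risk, "ACTTACAT")
  expect_identical(pair2$seq_nonrisk, "ACGTACGT")
  expect_identical(pair2$snps_applied, c("s1", "s2"))

  outside <- make_snps("s3", contig = "ctg", pos0 = 20L)
  expect_error(build_allele_pair(region, genome, outside), "outside region")
})

test_that("genome base matching neither allele drops the SNP with a warning", {
  genome <- c(ctg = "ACGTACGT")
  region <- data.frame(contig = "ctg", start = 0L, end = 8L, region_id = "r",
                       stringsAsFactors = FALSE)
  snps <- rbind(
    make_snps("bad", contig = "ctg", pos0 = 0L, nonrisk = "C", risk = "T"),
    make_snps("ok", contig = "ctg", pos0 = 1L, nonrisk = "C", risk = "G")
  )
  expect_warning(pair <- build_allele_pair(region, genome, snps), "bad")
  expect_identical(pair$snps_applied, "ok")
  expect_identical(pair$n_dropped, 1L)
  # genome base equal to the risk allele is fine: records define the pair
  risky <- make_snps("r", contig = "ctg", pos0 = 3L, nonrisk = "C", risk = "T")
  pair2 <- build_allele_pair(region, genome, risky)
  expect_identical(substr(pair2$seq_nonrisk, 4, 4), "C")
  expect_identical(substr(pair2$seq_risk, 4, 4), "T")
})

test_that("Hamming distance between allele sequences equals applied SNPs", {
  set.seed(9)
  genome <- c(ctg = random_dna(300))
  region <- data.frame(contig = "ctg", start = 10L, end = 260L,
                       region_id = "r", stringsAsFactors = FALSE)
  pos <- sort(sample(10:259, 12))
  ref <- substring(genome, pos + 1, pos + 1)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1))
  snps <- make_snps(sprintf("s%02d", 1:12), contig = "ctg", pos0 = pos,
                    nonrisk = ref, risk = alt)
  pair <- build_allele_pair(region, genome, snps)
  hamming <- sum(strsplit(pair$seq_risk, "")[[1]] !=
                   strsplit(pair$seq_nonrisk, "")[[1]])
  expect_identical(hamming, 12L)
})

test_that("MHC exclusion removes only the stated interval", {
  snps <- make_snps(c("in", "below", "above", "other"),
                    contig = c("chr6", "chr6", "chr6", "chr2"),
                    pos0 = c(30000000L, 25999998L, 34000000L, 30000000L))
  out <- exclude_mhc(snps)
  expect_setequal(out$rsid, c("below", "above", "other"))
})

test_that("gwas_filter_summary counts significant, risk and protective variants", {
  f <- withr::local_tempfile(fileext = ".tsv")
  rows <- c(
    "rsid\tchrom\tpos\tallele_other\tallele_effect\tbeta\tpvalue",
    "rs1\tchr1\t100\tA\tG\t0.2\t1e-9",
    "rs2\tchr1\t200\tA\tG\t-0.2\t5e-8",
    "rs3\tchr1\t300\tA\tG\t0.2\t6e-8",
    "rs4\tchr1\t400\tC\tT\t-0.1\t1e-20"
  )
  writeLines(rows, f)
  s <- gwas_filter_summary(f)
  expect_identical(s$n_significant, 3L)
  expect_identical(s$n_risk, 1L)
  expect_identical(s$n_protective, 2L)
})
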