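# Seeded generator of a complete synthetic input bundle with known ground
# truth: toy genome (one contig per peak), peak set, motif models, GWAS
# table, donor genotypes, accessibility and expression count matrices, and
# donor covariates. Every planted signal (marker peaks, motif occurrences,
# binding-altering SNPs, dosage-dependent expression) is recorded so each
# downstream stage can be checked against truth.

#' Simulation configuration
#'
#' Defaults define the reference synthetic study: 3 cell types, 30 donors,
#' 500 peaks of 200 bp, 50 marker peaks per cell type at 8-fold
#' accessibility, two selected motifs per cell type with 8 planted lost and
#' 8 planted gained scCREs, and carrier-dependent target-gene expression at
#' one log2 unit.
#'
#' @param seed Master seed (mandatory); one stream per output artifact is
#'   split from it.
#' @param n_cell_types,n_donors,cells_per_donor_per_type Cohort shape.
#' @param n_peaks,peak_length_bp Peak set shape.
#' @param n_marker_peaks_per_type,marker_fold_change Planted marker-peak
#'   signal.
#' @param base_accessibility Per-cell per-peak Poisson rate outside
#'   markers.
#' @param motif_width Width of the generated consensus motifs.
#' @param n_motif_peaks Marker peaks per motif carrying a planted
#'   consensus occurrence.
#' @param n_planted_per_direction Planted lost (and gained) scCREs per
#'   affected motif.
#' @param n_neutral_snps,n_decoy_snps Significant SNPs outside motifs and
#'   sub-threshold decoys.
#' @param frac_beta_flipped Fraction of GWAS rows emitted in protective
#'   orientation (negative beta) to exercise recoding.
#' @param maf Risk-allele frequency for Hardy-Weinberg dosages.
#' @param geno_na_rate Missing-dosage rate.
#' @param expression_effect_log2fc Planted carrier effect on target genes.
#' @param nb_dispersion Cell-level negative-binomial dispersion for
#'   expression counts.
#' @param tf_expr_rate,silent_tf_rate,target_gene_rate Per-cell mean
#'   expression of TF genes, of the deliberately unexpressed TF gene, and
#'   of target/filler genes.
#' @param n_filler_genes Null target genes carried through the DE family.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_cell_types = 3,
                       n_donors = 30,
                       cells_per_donor_per_type = 20,
                       n_peaks = 500,
                       peak_length_bp = 200,
                       n_marker_peaks_per_type = 50,
                       marker_fold_change = 8,
                       base_accessibility = 0.2,
                       motif_width = 10,
                       n_motif_peaks = 40,
                       n_planted_per_direction = 8,
                       n_neutral_snps = 20,
                       n_decoy_snps = 20,
                       frac_beta_flipped = 0.3,
                       maf = 0.3,
                       geno_na_rate = 0.02,
                       expression_effect_log2fc = 1,
                       nb_dispersion = 0.2,
                       tf_expr_rate = 0.3,
                       silent_tf_rate = 5e-4,
                       target_gene_rate = 1,
                       n_filler_genes = 10) {
  cfg <- as.list(environment())
  if (cfg$n_cell_types * cfg$n_marker_peaks_per_type > cfg$n_peaks) {
    stop("infeasible config: more marker peaks than peaks")
  }
  if (cfg$n_motif_peaks + cfg$n_planted_per_direction + 2 >
      cfg$n_marker_peaks_per_type) {
    stop("infeasible config: marker peaks cannot host motif and SNP plantings")
  }
  structure(cfg, class = "sim_config")
}

# high-information PFM around a consensus: one near-deterministic anchor
# column (planting/ablating its base moves the binding score well past the
# gain/loss threshold) among moderately informative columns
planted_pfm <- function(consensus, anchor_col) {
  w <- nchar(consensus)
  cons <- match(strsplit(consensus, "")[[1L]], BASES)
  pfm <- matrix(150, nrow = 4L, ncol = w, dimnames = list(BASES, NULL))
  for (j in seq_len(w)) pfm[cons[j], j] <- 550
  pfm[, anchor_col] <- 1
  pfm[cons[anchor_col], anchor_col] <- 997
  pfm
}

#' Generate the toy motif set
#'
#' Two planted ("selected") motifs per cell type, one motif destined to
#' fail the expression filter, and one unplanted motif that should not
#' reach enrichment. Each motif has a random consensus with a
#' near-deterministic anchor column in the middle.
#'
#' @param config A [sim_config()].
#' @return List of raw motifs (`motif_id`, `tf_name`, `pfm`) with
#'   attributes `anchor_col` and `roles` (`data.frame`).
#' @export
toy_motifs <- function(config) {
  k <- config$n_cell_types
  anchor_col <- ceiling(config$motif_width / 2)
  roles <- data.frame(
    motif_id = c(
      paste0("M_DIS_", seq_len(k)), paste0("M_ENH_", seq_len(k)),
      "M_NOEXPR", "M_NOENRICH"
    ),
    role = c(rep("disrupted", k), rep("enhanced", k), "noexpr", "noenrich"),
    cell_type = c(paste0("CT", seq_len(k)), paste0("CT", seq_len(k)), "CT1", "CT1"),
    stringsAsFactors = FALSE
  )
  motifs <- lapply(seq_len(nrow(roles)), function(i) {
    consensus <- paste0(sample(BASES, config$motif_width, replace = TRUE),
                        collapse = "")
    list(
      motif_id = roles$motif_id[i],
      tf_name = paste0("TF_", roles$motif_id[i]),
      pfm = planted_pfm(consensus, anchor_col)
    )
  })
  attr(motifs, "anchor_col") <- anchor_col
  attr(motifs, "roles") <- roles
  motifs
}

#' Generate the full synthetic bundle
#'
#' Emits, in memory, every input the pipeline consumes plus the ground
#' truth of all planted signals. Deterministic given `config$seed`; each
#' artifact draws from its own stream split from the master seed, so one
#' artifact's size never perturbs another's content.
#'
#' @param config A [sim_config()].
#' @return List with `genome`, `regions`, `motifs`, `gwas`, `genotypes`,
#'   `atac`, `rna`, `covariates`, `celltype_peak_calls`, `genes`,
#'   `interaction_pairs`, `ground_truth`, `config`.
#' @export
simulate_bundle <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  streams <- sample.int(.Machine$integer.max - 1L, 10L)
  k <- config$n_cell_types
  cell_types <- paste0("CT", seq_len(k))
  donors <- sprintf("D%02d", seq_len(config$n_donors))
  peak_ids <- sprintf("peak_%04d", seq_len(config$n_peaks))
  L <- config$peak_length_bp
  w <- config$motif_width

  # --- motifs ------------------------------------------------------------
  set.seed(streams[1])
  motifs <- toy_motifs(config)
  roles <- attr(motifs, "roles")
  anchor_col <- attr(motifs, "anchor_col")
  consensi <- vapply(motifs, function(m) {
    paste0(BASES[apply(m$pfm, 2L, which.max)], collapse = "")
  }, character(1))
  names(consensi) <- roles$motif_id
  # fixed non-overlapping site slot per motif within the peak
  slot_offset <- 20L + (seq_len(nrow(roles)) - 1L) * (w + 14L)
  names(slot_offset) <- roles$motif_id
  stopifnot(max(slot_offset) + w <= L)

  # --- genome with planted sites ----------------------------------------
  set.seed(streams[2])
  genome <- vapply(peak_ids, function(p) {
    paste0(sample(BASES, L, replace = TRUE), collapse = "")
  }, character(1))
  marker_sets <- split(
    peak_ids[seq_len(k * config$n_marker_peaks_per_type)],
    rep(cell_types, each = config$n_marker_peaks_per_type)
  )
  plantings <- list()
  plant <- function(region, motif_id, site, kind) {
    off <- slot_offset[[motif_id]]
    substr(genome[[region]], off + 1L, off + w) <<- site
    plantings[[length(plantings) + 1L]] <<- data.frame(
      motif_id = motif_id, region_id = region, offset = off, kind = kind,
      stringsAsFactors = FALSE
    )
  }
  mismatch_base <- function(cons_base) sample(setdiff(BASES, cons_base), 1L)
  planted_info <- list()
  for (i in seq_len(nrow(roles))) {
    mid <- roles$motif_id[i]
    role <- roles$role[i]
    if (role == "noenrich") next
    ct <- roles$cell_type[i]
    markers <- marker_sets[[ct]]
    host <- markers[seq_len(config$n_motif_peaks)]
    for (r in host) plant(r, mid, consensi[[mid]], "consensus")
    if (role == "disrupted") {
      planted_info[[mid]] <- list(
        direction = "lost", cell_type = ct,
        snp_regions = host[seq_len(config$n_planted_per_direction)]
      )
    } else if (role == "enhanced") {
      mm_host <- markers[config$n_motif_peaks +
                           seq_len(config$n_planted_per_direction)]
      cons_chars <- strsplit(consensi[[mid]], "")[[1L]]
      mm_info <- vapply(mm_host, function(r) {
        mb <- mismatch_base(cons_chars[anchor_col])
        site <- cons_chars
        site[anchor_col] <- mb
        plant(r, mid, paste0(site, collapse = ""), "anchor-mismatch")
        mb
      }, character(1))
      planted_info[[mid]] <- list(
        direction = "gained", cell_type = ct,
        snp_regions = mm_host, mismatch_bases = mm_info
      )
    }
  }
  plantings <- do.call(rbind, plantings)

  # --- GWAS SNPs ---------------------------------------------------------
  set.seed(streams[3])
  snp_rows <- list()
  truth_snps <- list()
  add_snp <- function(rsid, region, pos_in_peak, nonrisk, risk, class,
                      motif_id = NA, cell_type = NA, pvalue) {
    flip <- stats::runif(1) < config$frac_beta_flipped
    beta <- abs(stats::rnorm(1, 0.05, 0.02))
    snp_rows[[length(snp_rows) + 1L]] <<- data.frame(
      rsid = rsid, chrom = region, pos = pos_in_peak + 1L,
      allele_other = if (flip) risk else nonrisk,
      allele_effect = if (flip) nonrisk else risk,
      beta = if (flip) -beta else beta,
      pvalue = pvalue, stringsAsFactors = FALSE
    )
    truth_snps[[length(truth_snps) + 1L]] <<- data.frame(
      rsid = rsid, class = class, motif_id = motif_id, cell_type = cell_type,
      region_id = region, pos0 = pos_in_peak,
      allele_nonrisk = nonrisk, allele_risk = risk,
      stringsAsFactors = FALSE
    )
  }
  rs_counter <- 0L
  next_rsid <- function() {
    rs_counter <<- rs_counter + 1L
    sprintf("rs%04d", rs_counter)
  }
  sig_p <- function() 10^-stats::runif(1, 9, 30)
  for (mid in names(planted_info)) {
    info <- planted_info[[mid]]
    cons_chars <- strsplit(consensi[[mid]], "")[[1L]]
    anchor_pos <- slot_offset[[mid]] + anchor_col - 1L
    for (j in seq_along(info$snp_regions)) {
      region <- info$snp_regions[j]
      if (info$direction == "lost") {
        nonrisk <- cons_chars[anchor_col]
        risk <- mismatch_base(nonrisk)
      } else {
        nonrisk <- info$mismatch_bases[j]
        risk <- cons_chars[anchor_col]
      }
      add_snp(next_rsid(), region, anchor_pos, nonrisk, risk,
              info$direction, mid, info$cell_type, sig_p())
    }
  }
  free_peaks <- setdiff(peak_ids, unlist(marker_sets))
  neutral_hosts <- sample(free_peaks, config$n_neutral_snps)
  for (region in neutral_hosts) {
    pos <- sample.int(L, 1L) - 1L
    ref <- substr(genome[[region]], pos + 1L, pos + 1L)
    add_snp(next_rsid(), region, pos, ref, mismatch_base(ref),
            "neutral", pvalue = sig_p())
  }
  decoy_hosts <- sample(free_peaks, config$n_decoy_snps)
  for (region in decoy_hosts) {
    pos <- sample.int(L, 1L) - 1L
    ref <- substr(genome[[region]], pos + 1L, pos + 1L)
    add_snp(next_rsid(), region, pos, ref, mismatch_base(ref),
            "decoy", pvalue = 10^-stats::runif(1, 3, 6))
  }
  gwas <- do.call(rbind, snp_rows)
  truth_snps <- do.call(rbind, truth_snps)

  # --- genotypes ---------------------------------------------------------
  set.seed(streams[4])
  sig_rsids <- truth_snps$rsid[truth_snps$class != "decoy"]
  genotypes <- matrix(
    stats::rbinom(length(sig_rsids) * config$n_donors, 2L, config$maf),
    nrow = length(sig_rsids), dimnames = list(sig_rsids, donors)
  )
  genotypes[stats::runif(length(genotypes)) < config$geno_na_rate] <- NA
  mode(genotypes) <- "numeric"

  # --- ATAC counts -------------------------------------------------------
  set.seed(streams[5])
  n_cells <- k * config$n_donors * config$cells_per_donor_per_type
  cell_type_vec <- rep(cell_types, each = config$n_donors * config$cells_per_donor_per_type)
  donor_vec <- rep(rep(donors, each = config$cells_per_donor_per_type), times = k)
  cell_ids <- sprintf("cell_%05d", seq_len(n_cells))
  rate <- matrix(config$base_accessibility, nrow = n_cells, ncol = config$n_peaks)
  for (ct in cell_types) {
    rows <- cell_type_vec == ct
    cols <- match(marker_sets[[ct]], peak_ids)
    rate[rows, cols] <- config$base_accessibility * config$marker_fold_change
  }
  atac_counts <- matrix(stats::rpois(length(rate), rate), nrow = n_cells)
  atac <- count_matrix(
    Matrix::Matrix(atac_counts, sparse = TRUE),
    cell_ids, peak_ids, cell_type_vec, donor_vec
  )
  celltype_peak_calls <- lapply(cell_types, function(ct) {
    sort(unique(c(marker_sets[[ct]], sample(peak_ids, 100L))))
  })
  names(celltype_peak_calls) <- cell_types

  # --- genes and expression ---------------------------------------------
  set.seed(streams[6])
  selected <- roles[roles$role %in% c("disrupted", "enhanced"), , drop = FALSE]
  effect_rows <- lapply(selected$motif_id, function(mid) {
    hit <- truth_snps$motif_id %in% mid
    if (!any(hit)) return(NULL)
    first_snp <- truth_snps[hit, ][1L, ]
    data.frame(
      rsid = first_snp$rsid,
      gene_id = paste0("TARGET_", mid),
      cell_type = first_snp$cell_type,
      region_id = first_snp$region_id,
      log2_fc = config$expression_effect_log2fc,
      stringsAsFactors = FALSE
    )
  })
  effects <- do.call(rbind, effect_rows)
  if (is.null(effects)) {
    effects <- data.frame(
      rsid = character(), gene_id = character(), cell_type = character(),
      region_id = character(), log2_fc = numeric(), stringsAsFactors = FALSE
    )
  }
  other_snps <- truth_snps[
    truth_snps$class %in% c("lost", "gained") & !truth_snps$rsid %in% effects$rsid, ]
  filler_idx <- seq_len(min(config$n_filler_genes, nrow(other_snps)))
  filler <- data.frame(
    gene_id = sprintf("FILLER_%02d", filler_idx),
    region_id = other_snps$region_id[filler_idx],
    stringsAsFactors = FALSE
  )
  tf_genes <- vapply(motifs, `[[`, character(1), "tf_name")
  gene_ids <- c(effects$gene_id, filler$gene_id)
  genes <- data.frame(
    gene_id = gene_ids,
    symbol = gene_ids,
    contig = c(effects$region_id, filler$region_id),
    tss_pos0 = rep(100L, length(gene_ids)),
    strand = rep("+", length(gene_ids)),
    stringsAsFactors = FALSE
  )
  all_genes <- c(tf_genes, effects$gene_id, filler$gene_id)
  base_rate <- c(
    ifelse(roles$role == "noexpr", config$silent_tf_rate, config$tf_expr_rate),
    rep(config$target_gene_rate, nrow(effects)),
    rep(config$target_gene_rate, nrow(filler))
  )
  mu <- matrix(rep(base_rate, each = n_cells), nrow = n_cells)
  colnames(mu) <- all_genes
  for (i in seq_len(nrow(effects))) {
    dose <- genotypes[effects$rsid[i], ]
    carrier_donors <- names(dose)[!is.na(dose) & dose >= 1]
    rows <- cell_type_vec == effects$cell_type[i] & donor_vec %in% carrier_donors
    mu[rows, effects$gene_id[i]] <-
      mu[rows, effects$gene_id[i]] * 2^effects$log2_fc[i]
  }
  rna_counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
    nrow = n_cells
  )
  rna <- count_matrix(
    Matrix::Matrix(rna_counts, sparse = TRUE),
    cell_ids, all_genes, cell_type_vec, donor_vec
  )

  # --- covariates --------------------------------------------------------
  set.seed(streams[7])
  covariates <- data.frame(
    donor = donors,
    diagnosis = sample(c("case", "control"), config$n_donors, replace = TRUE),
    sex = sample(c("F", "M"), config$n_donors, replace = TRUE, prob = c(0.34, 0.66)),
    age = stats::rnorm(config$n_donors, 55.31, 13.12),
    pH = stats::rnorm(config$n_donors, 6.60, 0.22),
    RIN = stats::rnorm(config$n_donors, 7.24, 1.17),
    PMI = stats::rnorm(config$n_donors, 32.77, 14.07),
    stringsAsFactors = FALSE
  )

  # --- interaction pairs (one long-range link for the mapper) ------------
  set.seed(streams[8])
  hic_peak <- sample(setdiff(free_peaks, c(neutral_hosts, decoy_hosts)), 1L)
  interaction_pairs <- data.frame(
    contig1 = truth_snps$region_id[1L], start1 = 0L, end1 = L,
    contig2 = hic_peak, start2 = 0L, end2 = L,
    stringsAsFactors = FALSE
  )

  regions <- data.frame(
    contig = peak_ids, start = 0L, end = as.integer(L), region_id = peak_ids,
    stringsAsFactors = FALSE
  )
  ground_truth <- list(
    markers = do.call(rbind, lapply(cell_types, function(ct) {
      data.frame(cell_type = ct, region_id = marker_sets[[ct]],
                 stringsAsFactors = FALSE)
    })),
    motif_sets = data.frame(
      cell_type = selected$cell_type,
      motif_id = selected$motif_id,
      direction = ifelse(selected$role == "disrupted", "disrupted", "enhanced"),
      stringsAsFactors = FALSE
    ),
    plantings = plantings,
    snps = truth_snps,
    effects = effects[, c("rsid", "gene_id", "cell_type", "log2_fc")],
    anchor_col = anchor_col,
    slot_offset = slot_offset
  )
  list(
    genome = genome, regions = regions, motifs = motifs, gwas = gwas,
    genotypes = genotypes, atac = atac, rna = rna, covariates = covariates,
    celltype_peak_calls = celltype_peak_calls, genes = genes,
    interaction_pairs = interaction_pairs, ground_truth = ground_truth,
    config = config
  )
}

#' Write a synthetic bundle to disk
#'
#' Emits every artifact in the pipeline's external formats: FASTA, BED4,
#' JASPAR motifs, GWAS TSV, genotype TSV, MatrixMarket matrices with
#' sidecars, covariate and gene TSVs.
#'
#' @param bundle Output of [simulate_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_fasta(bundle$genome, fp("genome.fa"))
  write_bed(bundle$regions, fp("peaks.bed"))
  write_motifs_jaspar(bundle$motifs, fp("motifs.jaspar"))
  utils::write.table(bundle$gwas, fp("gwas.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_genotypes(bundle$genotypes, fp("genotypes.tsv"))
  write_count_matrix(bundle$atac, fp("atac.mtx"), fp("atac_cells.tsv"),
                     fp("atac_peaks.tsv"), fp("atac_annot.tsv"))
  write_count_matrix(bundle$rna, fp("rna.mtx"), fp("rna_cells.tsv"),
                     fp("rna_genes.tsv"), fp("rna_annot.tsv"))
  utils::write.table(bundle$covariates, fp("covariates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  calls <- do.call(rbind, lapply(names(bundle$celltype_peak_calls), function(ct) {
    data.frame(cell_type = ct, region_id = bundle$celltype_peak_calls[[ct]],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(calls, fp("peak_calls.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bundle$genes, fp("genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bundle$interaction_pairs, fp("interaction_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write ground-truth tables
#'
#' @param gt `ground_truth` element of a bundle.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(gt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("markers", "motif_sets", "plantings", "snps", "effects")) {
    utils::write.table(gt[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read ground-truth tables back
#'
#' @param dir Directory written by [write_ground_truth()].
#' @return List of the five truth `data.frame`s.
#' @export
read_ground_truth <- function(dir) {
  out <- lapply(c("markers", "motif_sets", "plantings", "snps", "effects"),
                function(nm) {
                  utils::read.delim(file.path(dir, paste0(nm, ".tsv")),
                                    stringsAsFactors = FALSE)
                })
  names(out) <- c("markers", "motif_sets", "plantings", "snps", "effects")
  out
}

#' Simulate donor-level pseudobulk counts for one gene
#'
#' Donor-level negative-binomial counts with a library-size offset, a
#' carrier effect of `log2_fc`, and covariates drawn from the cohort
#' distributions. Used for DE parameter-recovery and null-calibration
#' studies.
#'
#' @param n_donors Number of donors.
#' @param mean_count Baseline expected count for the gene per donor.
#' @param log2_fc Planted carrier effect (0 for null genes).
#' @param dispersion Donor-level NB dispersion.
#' @param maf Risk-allele frequency for the carrier split.
#' @param seed Seed.
#' @return List with `pb` (donors x 2 matrix: the gene plus a bulk
#'   remainder), `carriers`, `noncarriers`, `covariates`.
#' @export
simulate_pseudobulk_gene <- function(n_donors = 30, mean_count = 100,
                                     log2_fc = 0, dispersion = 0.2,
                                     maf = 0.3, seed = 1) {
  set.seed(seed)
  donors <- sprintf("D%02d", seq_len(n_donors))
  dose <- stats::rbinom(n_donors, 2L, maf)
  carriers <- donors[dose >= 1]
  noncarriers <- donors[dose == 0]
  rest <- stats::rnbinom(n_donors, mu = 1e5, size = 50)
  libfac <- (rest + mean_count) / (1e5 + mean_count)
  mu <- mean_count * libfac * 2^(log2_fc * (dose >= 1))
  y <- stats::rnbinom(n_donors, mu = mu, size = 1 / dispersion)
  pb <- cbind(gene = y, rest = rest)
  rownames(pb) <- donors
  covariates <- data.frame(
    donor = donors,
    diagnosis = sample(c("case", "control"), n_donors, replace = TRUE),
    sex = sample(c("F", "M"), n_donors, replace = TRUE, prob = c(0.34, 0.66)),
    age = stats::rnorm(n_donors, 55.31, 13.12),
    pH = stats::rnorm(n_donors, 6.60, 0.22),
    RIN = stats::rnorm(n_donors, 7.24, 1.17),
    PMI = stats::rnorm(n_donors, 32.77, 14.07),
    stringsAsFactors = FALSE
  )
  list(pb = pb, carriers = carriers, noncarriers = noncarriers,
       covariates = covariates)
}
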