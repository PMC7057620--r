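#' Render array-like LRR/BAF signals from haplotypes and planted CNVs
#'
#' The Log R Ratio (LRR) of a SNP is the log of observed over expected
#' probe hybridization intensity; it shifts down in deletions and up in
#' duplications. The B allele frequency (BAF) is the proportion of B
#' alleles measured at the SNP; with diploid copy number `cn` and `b` B
#' alleles among the copies it clusters at `b/cn`. This renderer draws,
#' for every animal and SNP,
#' `LRR = state_lrr_means[cn] + gc_wave_coef * (gc - mean(gc)) + noise`
#' with state-specific Gaussian noise, and
#' `BAF ~ Normal(b/cn, baf_sd)` truncated to `[0, 1]` (uniform on
#' `[0, 1]` when `cn = 0`, where no allele signal exists). A duplicated
#' haplotype contributes two copies of its own SNP allele (a tandem
#' duplication), a deleted haplotype none.
#'
#' Called genotypes (the imputation substrate) are the underlying
#' diploid SNP genotypes (`AA`/`AB`/`BB` coded 0/1/2): the SNPs of an
#' edited panel have already survived genotype QC, so genotype-call
#' defects enter only through [inject_defects()] while the CNV signal
#' is carried by LRR/BAF.
#'
#' @param haps `hap_set`.
#' @param cnvs result of [plant_cnv_loci()], or `NULL` for a CNV-free
#'   population.
#' @param map SNP map aligned to `haps`.
#' @param state_lrr_means expected LRR per copy number 0..4.
#' @param state_lrr_sds LRR noise SD per copy number 0..4.
#' @param baf_sd BAF cluster SD.
#' @param gc_wave_coef slope of the GC wave added to the LRR.
#' @param seed integer seed.
#' @return object of class `signal_set`: list with matrices `lrr`,
#'   `baf`, `geno` (animals x SNPs; `geno` integer 0/1/2 with `NA` for
#'   missing), `cn` (true copy number used to render each cell),
#'   `animal_ids` and `snp_ids`.
#' @export
render_signals <- function(haps, cnvs, map,
                           state_lrr_means = c(-3.5, -0.66, 0, 0.4, 0.68),
                           state_lrr_sds = c(1.3, 0.28, 0.21, 0.21, 0.26),
                           baf_sd = 0.05, gc_wave_coef = 0.4, seed = 1) {
  stopifnot(length(state_lrr_means) == 5, length(state_lrr_sds) == 5,
            all(state_lrr_sds > 0))
  set.seed(seed)
  n_hap <- nrow(haps$alleles)
  n_animal <- n_hap / 2
  n_snp <- ncol(haps$alleles)
  stopifnot(n_snp == nrow(map))

  # per-haplotype copy contribution along the genome (default 1)
  copies <- matrix(1L, n_hap, n_snp)
  if (!is.null(cnvs)) {
    for (li in seq_len(nrow(cnvs$loci))) {
      cols <- cnvs$loci$start_snp[li]:cnvs$loci$end_snp[li]
      al <- cnvs$hap_alleles[, li]
      copies[al == "D", cols] <- 0L
      copies[al == "P", cols] <- 2L
    }
  }
  odd <- seq(1, n_hap, 2); even <- seq(2, n_hap, 2)
  cn <- copies[odd, , drop = FALSE] + copies[even, , drop = FALSE]
  bcnt <- copies[odd, , drop = FALSE] * haps$alleles[odd, , drop = FALSE] +
    copies[even, , drop = FALSE] * haps$alleles[even, , drop = FALSE]

  gc_dev <- rep(map$gc_frac - mean(map$gc_frac), each = n_animal)
  lrr <- matrix(state_lrr_means[cn + 1L] + gc_wave_coef * gc_dev +
                  stats::rnorm(n_animal * n_snp, sd = state_lrr_sds[cn + 1L]),
                n_animal, n_snp)

  baf_mean <- ifelse(cn > 0, bcnt / pmax(cn, 1L), 0)
  baf <- matrix(stats::rnorm(n_animal * n_snp, mean = baf_mean, sd = baf_sd),
                n_animal, n_snp)
  zero <- cn == 0L
  baf[zero] <- stats::runif(sum(zero))
  baf <- pmin(pmax(baf, 0), 1)

  # genotype calls carry the underlying diploid SNP alleles: the SNPs
  # of an edited panel have already survived genotype QC, so only the
  # injected defects perturb the calls, while the CNV signal lives in
  # the LRR/BAF channel
  geno <- haps$alleles[odd, , drop = FALSE] +
    haps$alleles[even, , drop = FALSE]
  storage.mode(geno) <- "integer"

  structure(list(lrr = lrr, baf = baf, geno = geno, cn = cn,
                 animal_ids = haps$animal_ids, snp_ids = map$snp_id),
            class = "signal_set")
}

#' Subset a signal set to a set of SNP columns
#' @param signals `signal_set`.
#' @param cols integer column indices to keep (in order).
#' @return the subsetted `signal_set`.
#' @export
subset_signal_snps <- function(signals, cols) {
  structure(list(
    lrr = signals$lrr[, cols, drop = FALSE],
    baf = signals$baf[, cols, drop = FALSE],
    geno = signals$geno[, cols, drop = FALSE],
    cn = if (!is.null(signals$cn)) signals$cn[, cols, drop = FALSE],
    animal_ids = signals$animal_ids,
    snp_ids = signals$snp_ids[cols]
  ), class = "signal_set")
}

#' Inject genotype-call defects for QC exercise
#'
#' Sets a random fraction of genotype calls to missing, and makes a
#' designated fraction of SNPs Mendelian-inconsistent in a designated
#' fraction of parent-progeny pairs (by forcing opposing homozygotes on
#' the pair). Rates of zero return the input unchanged.
#'
#' @param signals `signal_set`.
#' @param ped pedigree (needed only when `mendel_error_rate > 0`).
#' @param missing_rate fraction of genotype calls set to `NA`.
#' @param mendel_error_rate fraction of parent-progeny pairs violated
#'   at each affected SNP.
#' @param mendel_snp_frac fraction of SNPs affected by the Mendelian
#'   defect.
#' @param seed integer seed.
#' @return the modified `signal_set`.
#' @export
inject_defects <- function(signals, ped, missing_rate = 0,
                           mendel_error_rate = 0, mendel_snp_frac = 0.01,
                           seed = 1) {
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            mendel_error_rate >= 0, mendel_error_rate <= 1)
  if (missing_rate == 0 && mendel_error_rate == 0) return(signals)
  set.seed(seed)
  geno <- signals$geno
  if (mendel_error_rate > 0) {
    pairs <- parent_progeny_pairs(ped)
    if (nrow(pairs) == 0) stop("no parent-progeny pairs to violate")
    row_of <- stats::setNames(seq_along(signals$animal_ids),
                              signals$animal_ids)
    n_bad_snps <- max(1L, round(mendel_snp_frac * ncol(geno)))
    bad_snps <- sample.int(ncol(geno), n_bad_snps)
    n_bad_pairs <- max(1L, round(mendel_error_rate * nrow(pairs)))
    for (j in bad_snps) {
      sel <- sample.int(nrow(pairs), n_bad_pairs)
      pr <- row_of[pairs$parent_id[sel]]
      cr <- row_of[pairs$child_id[sel]]
      geno[cbind(pr, j)] <- 0L
      geno[cbind(cr, j)] <- 2L
    }
  }
  if (missing_rate > 0) {
    drop <- which(stats::runif(length(geno)) < missing_rate)
    geno[drop] <- NA_integer_
  }
  signals$geno <- geno
  signals
}

#' SNP quality control: call rate and Mendelian consistency
#'
#' Removes SNPs with a genotype call rate below `min_call_rate` and
#' SNPs whose genotypes are inconsistent with Mendelian inheritance
#' (opposing homozygotes) in more than `max_mendel_pair_frac` of the
#' parent-progeny pairs in which both members are genotyped. A SNP with
#' call rate exactly at the threshold, or a Mendelian-inconsistency
#' fraction exactly at the threshold, is retained. SNP ordering is
#' preserved. When the pedigree contains no parent-progeny pair the
#' Mendelian filter is skipped with a warning.
#'
#' @param signals `signal_set`.
#' @param map SNP map aligned to `signals`.
#' @param ped pedigree.
#' @param min_call_rate minimum per-SNP genotype call rate.
#' @param max_mendel_pair_frac maximum tolerated fraction of
#'   inconsistent parent-progeny pairs.
#' @return `list(map =, signals =, removed =)` with failing SNPs
#'   dropped from both map and signals.
#' @export
filter_snps <- function(signals, map, ped, min_call_rate = 0.95,
                        max_mendel_pair_frac = 0.02) {
  stopifnot(nrow(map) == ncol(signals$geno))
  call_rate <- colMeans(!is.na(signals$geno))
  fail_cr <- call_rate < min_call_rate

  pairs <- parent_progeny_pairs(ped)
  if (nrow(pairs) == 0) {
    warning("no parent-progeny pairs in pedigree; Mendelian filter skipped")
    fail_mendel <- rep(FALSE, nrow(map))
  } else {
    row_of <- stats::setNames(seq_along(signals$animal_ids),
                              signals$animal_ids)
    gp <- signals$geno[row_of[pairs$parent_id], , drop = FALSE]
    gc_ <- signals$geno[row_of[pairs$child_id], , drop = FALSE]
    opposing <- (gp == 0L & gc_ == 2L) | (gp == 2L & gc_ == 0L)
    both <- !is.na(gp) & !is.na(gc_)
    n_eval <- colSums(both)
    n_bad <- colSums(opposing & both, na.rm = TRUE)
    frac <- ifelse(n_eval > 0, n_bad / n_eval, 0)
    fail_mendel <- frac > max_mendel_pair_frac
  }

  keep <- !(fail_cr | fail_mendel)
  if (!any(keep)) stop("all SNPs removed by QC filters")
  removed <- data.frame(snp_id = map$snp_id[!keep],
                        call_rate = call_rate[!keep],
                        fail_call_rate = fail_cr[!keep],
                        fail_mendel = fail_mendel[!keep],
                        stringsAsFactors = FALSE)
  map2 <- map[keep, , drop = FALSE]
  rownames(map2) <- NULL
  list(map = map2, signals = subset_signal_snps(signals, which(keep)),
       removed = removed)
}
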