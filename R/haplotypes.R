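#' Simulate phased haplotypes over a SNP map
#'
#' Founder haplotypes are drawn from per-SNP B-allele frequencies with a
#' latent Gaussian AR(1) chain along each chromosome, which gives
#' tunable local linkage disequilibrium (LD) -- the quantity the
#' flanking-haplotype imputation study manipulates. Non-founder
#' haplotypes are recombinant mosaics of their parents' haplotypes,
#' with Poisson crossovers at `recomb_rate_per_mb` per megabase.
#'
#' Besides the 0/1 allele matrix (1 = B allele) the function tracks, for
#' every haplotype and SNP, the founder haplotype the segment descends
#' from. That identity-by-descent record is what lets the CNV planter
#' put a CNV allele on a single founder lineage (perfect LD with the
#' surrounding haplotype) without any genealogy bookkeeping downstream.
#'
#' @param ped pedigree from [simulate_pedigree()]; processed in birth
#'   order so parents are always simulated before offspring.
#' @param map SNP map.
#' @param recomb_rate_per_mb expected crossovers per megabase per
#'   meiosis (cattle-like default 0.01, i.e. ~1 cM/Mb).
#' @param maf_spectrum either `list(type = "uniform", min =, max =)` for
#'   minor-allele frequencies drawn uniformly, or
#'   `list(type = "point", value =)` for a fixed frequency.
#' @param ld_rho AR(1) coefficient of the founder latent chain; 0 gives
#'   linkage equilibrium among founders, values near 1 strong local LD.
#' @param seed integer seed.
#' @return an object of class `hap_set`: list with `alleles` (integer
#'   matrix, 2 rows per animal, SNPs in map order), `origin` (integer
#'   matrix of founder-haplotype ids), `freq_b` (realized population B
#'   allele frequency per SNP), `animal_ids`, and `hap_animal` (animal
#'   id of each haplotype row).
#' @export
simulate_haplotypes <- function(ped, map, recomb_rate_per_mb = 0.01,
                                maf_spectrum = list(type = "uniform",
                                                    min = 0.05, max = 0.5),
                                ld_rho = 0.95, seed = 1) {
  stopifnot(nrow(map) >= 1)
  if (recomb_rate_per_mb < 0) stop("recomb_rate_per_mb must be >= 0")
  stopifnot(ld_rho >= 0, ld_rho < 1)
  set.seed(seed)
  n_snp <- nrow(map)
  ped <- ped[order(ped$birth_order), , drop = FALSE]
  n_animal <- nrow(ped)
  is_founder <- is.na(ped$sire_id) & is.na(ped$dam_id)
  n_f <- sum(is_founder)
  if (any(is.na(ped$sire_id) != is.na(ped$dam_id))) {
    stop("animals must have both parents known or both unknown")
  }

  # per-SNP B allele frequency from the MAF spectrum
  maf <- switch(maf_spectrum$type,
    uniform = stats::runif(n_snp, maf_spectrum$min, maf_spectrum$max),
    point = rep(maf_spectrum$value, n_snp),
    stop("unknown maf_spectrum type: ", maf_spectrum$type)
  )
  b_is_minor <- stats::runif(n_snp) < 0.5
  p_b <- ifelse(b_is_minor, maf, 1 - maf)
  thresh <- stats::qnorm(p_b)

  chrom <- map$chrom
  chrom_ids <- unique(chrom)
  chrom_cols <- lapply(chrom_ids, function(cc) which(chrom == cc))

  n_fh <- 2L * n_f
  alleles <- matrix(0L, nrow = 2L * n_animal, ncol = n_snp)
  origin <- matrix(0L, nrow = 2L * n_animal, ncol = n_snp)
  hap_rows <- function(a_idx) c(2L * a_idx - 1L, 2L * a_idx)

  # founder haplotypes: latent AR(1) chain restarted at each chromosome
  f_idx <- which(is_founder)
  z <- matrix(0, nrow = n_fh, ncol = n_snp)
  for (cols in chrom_cols) {
    z[, cols[1]] <- stats::rnorm(n_fh)
    if (length(cols) > 1) {
      sd_in <- sqrt(1 - ld_rho^2)
      for (j in 2:length(cols)) {
        z[, cols[j]] <- ld_rho * z[, cols[j - 1]] +
          stats::rnorm(n_fh, sd = sd_in)
      }
    }
  }
  fa <- matrix(0L, nrow = n_fh, ncol = n_snp)
  for (j in seq_len(n_snp)) fa[, j] <- as.integer(z[, j] < thresh[j])
  for (k in seq_along(f_idx)) {
    rows <- hap_rows(f_idx[k])
    alleles[rows, ] <- fa[c(2L * k - 1L, 2L * k), ]
    origin[rows[1], ] <- 2L * k - 1L
    origin[rows[2], ] <- 2L * k
  }

  # meiosis: one gamete per parent per chromosome
  animal_row <- stats::setNames(seq_len(n_animal), ped$animal_id)
  chrom_len_mb <- vapply(chrom_cols, function(cols) {
    diff(range(map$pos_bp[cols])) / 1e6
  }, numeric(1))
  gamete <- function(parent_idx) {
    prows <- hap_rows(parent_idx)
    g_allele <- integer(n_snp)
    g_origin <- integer(n_snp)
    for (ci in seq_along(chrom_cols)) {
      cols <- chrom_cols[[ci]]
      pos <- map$pos_bp[cols]
      n_x <- stats::rpois(1, recomb_rate_per_mb * chrom_len_mb[ci])
      start_hap <- sample.int(2, 1)
      if (n_x == 0) {
        src <- rep(start_hap, length(cols))
      } else {
        xpos <- sort(stats::runif(n_x, min(pos), max(pos)))
        seg <- findInterval(pos, xpos)  # 0..n_x segments
        src <- 1L + (start_hap - 1L + seg) %% 2L
      }
      take <- prows[src]
      idx <- cbind(take, cols)
      g_allele[cols] <- alleles[idx]
      g_origin[cols] <- origin[idx]
    }
    list(allele = g_allele, origin = g_origin)
  }
  for (a in which(!is_founder)) {
    rows <- hap_rows(a)
    gs <- gamete(animal_row[[ped$sire_id[a]]])
    gd <- gamete(animal_row[[ped$dam_id[a]]])
    alleles[rows[1], ] <- gs$allele; origin[rows[1], ] <- gs$origin
    alleles[rows[2], ] <- gd$allele; origin[rows[2], ] <- gd$origin
  }

  structure(list(
    alleles = alleles,
    origin = origin,
    freq_b = colMeans(alleles),
    animal_ids = ped$animal_id,
    hap_animal = rep(ped$animal_id, each = 2)
  ), class = "hap_set")
}
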