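#' Plant CNV loci on simulated haplotypes
#'
#' Places `n_loci` non-overlapping CNV loci on the HD map and assigns a
#' CNV allele to individual haplotypes. Alleles follow the tri-allelic
#' convention used throughout: `N` (normal, 1 copy per haplotype), `D`
#' (deletion, 0 copies), `P` (duplication, 2 copies); an animal's true
#' diploid copy number is the sum of its two haplotype contributions,
#' so it lies in 0..4 and equals 2 only for `(N,N)` genotypes.
#'
#' `ld_mode` controls how strongly carrier status is tied to the
#' flanking SNP haplotype:
#' \describe{
#'   \item{`"perfect"`}{the CNV allele rides exactly one founder
#'     haplotype lineage (chosen so the realized carrier frequency falls
#'     in `freq_range`); absent recombination inside the flanking
#'     window, the window haplotype identifies carrier status exactly.}
#'   \item{`list(mode="tagged_r2", r2=)`}{starts from the perfect
#'     assignment and degrades it so the squared correlation between
#'     carrier status and the founder lineage is about `r2`.}
#'   \item{`"independent"`}{carrier haplotypes drawn independently of
#'     the SNP alleles -- the no-information extreme.}
#' }
#'
#' @param map HD SNP map.
#' @param haps `hap_set` from [simulate_haplotypes()].
#' @param n_loci number of loci to plant.
#' @param len_snps_range integer range (min, max) of HD SNPs spanned;
#'   minimum 3 enforced.
#' @param freq_range range of the population carrier frequency
#'   (fraction of animals with true copy number != 2).
#' @param allele_set `"del"` (alleles {N,D}), `"dup"` ({N,P}) or
#'   `"mixed"` (each locus randomly del or dup). Mixed D+P genotypes
#'   within one locus are never produced.
#' @param ld_mode `"perfect"`, `"independent"`, or
#'   `list(mode = "tagged_r2", r2 = )`.
#' @param min_gap_snps minimum HD SNPs between consecutive loci.
#' @param chroms optional chromosome subset to place loci on.
#' @param seed integer seed.
#' @param max_tries attempts per locus before giving up.
#' @return list with `loci` (data.frame: `locus_id`, `chrom`,
#'   `start_bp`, `end_bp`, `start_snp`, `end_snp`, `n_snps`,
#'   `cnv_allele`, `ld_mode`, `n_carriers`), `truth` (data.frame:
#'   `animal_id`, `locus_id`, `true_cn`) and `hap_alleles` (character
#'   matrix, haplotypes x loci, entries in {"N","D","P"}).
#' @export
plant_cnv_loci <- function(map, haps, n_loci,
                           len_snps_range = c(10, 30),
                           freq_range = c(0.08, 0.30),
                           allele_set = "del",
                           ld_mode = "perfect",
                           min_gap_snps = 50, chroms = NULL,
                           seed = 1, max_tries = 500) {
  stopifnot(n_loci >= 1, len_snps_range[1] >= 3)
  set.seed(seed)
  n_hap <- nrow(haps$alleles)
  n_animal <- n_hap / 2
  mode_name <- if (is.list(ld_mode)) ld_mode$mode else ld_mode
  stopifnot(mode_name %in% c("perfect", "tagged_r2", "independent"))
  count_range <- sort(round(freq_range * n_animal))

  carriers_for <- function(mid_col) {
    org <- haps$origin[, mid_col]
    if (mode_name == "independent") {
      # haplotype carrier prob q so that P(animal carries) hits mid-range
      target <- mean(freq_range)
      q <- 1 - sqrt(1 - target)
      return(stats::runif(n_hap) < q)
    }
    tab <- table(org)
    # animal carrier count if lineage f is the carrier lineage
    cnt_animals <- vapply(names(tab), function(f) {
      ch <- org == as.integer(f)
      sum(ch[seq(1, n_hap, 2)] | ch[seq(2, n_hap, 2)])
    }, numeric(1))
    ok <- which(cnt_animals >= count_range[1] & cnt_animals <= count_range[2])
    if (length(ok) == 0) return(NULL)
    pick <- if (length(ok) == 1) ok else sample(ok, 1)
    f <- as.integer(names(tab)[pick])
    carrier <- org == f
    if (mode_name == "tagged_r2") {
      keep <- stats::runif(n_hap) < sqrt(ld_mode$r2)
      rand <- stats::runif(n_hap) < mean(carrier)
      carrier <- ifelse(keep, carrier, rand)
    }
    carrier
  }

  loci <- list()
  hap_alleles <- matrix("N", nrow = n_hap, ncol = n_loci)
  truth <- list()
  used <- list()  # per chrom, occupied snp index ranges
  if (is.null(chroms)) chroms <- unique(map$chrom)
  stopifnot(all(chroms %in% map$chrom))
  snp_idx_by_chrom <- lapply(chroms, function(cc) which(map$chrom == cc))
  names(snp_idx_by_chrom) <- as.character(chroms)

  for (li in seq_len(n_loci)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cc <- if (length(chroms) == 1) chroms else sample(chroms, 1)
      cols <- snp_idx_by_chrom[[as.character(cc)]]
      len_choices <- seq(len_snps_range[1], len_snps_range[2])
      n_snps <- if (length(len_choices) == 1) len_choices else
        sample(len_choices, 1)
      if (length(cols) < n_snps + 2 * min_gap_snps) next
      s <- sample.int(length(cols) - n_snps + 1, 1)
      rng <- c(s, s + n_snps - 1)
      clash <- any(vapply(used[[as.character(cc)]] %||% list(), function(u) {
        rng[1] <= u[2] + min_gap_snps && u[1] <= rng[2] + min_gap_snps
      }, logical(1)))
      if (clash) next
      mid_col <- cols[s] + (n_snps %/% 2)
      carrier <- carriers_for(mid_col)
      if (is.null(carrier)) next
      n_car_animals <- sum(carrier[seq(1, n_hap, 2)] | carrier[seq(2, n_hap, 2)])
      if (mode_name == "perfect" &&
          (n_car_animals < count_range[1] || n_car_animals > count_range[2])) next
      al <- switch(allele_set,
                   del = "D", dup = "P",
                   mixed = sample(c("D", "P"), 1),
                   stop("unknown allele_set: ", allele_set))
      hap_alleles[carrier, li] <- al
      contrib <- ifelse(hap_alleles[, li] == "D", 0L,
                        ifelse(hap_alleles[, li] == "P", 2L, 1L))
      cn <- contrib[seq(1, n_hap, 2)] + contrib[seq(2, n_hap, 2)]
      locus_id <- sprintf("cnv%03d", li)
      loci[[li]] <- data.frame(
        locus_id = locus_id, chrom = cc,
        start_bp = map$pos_bp[cols[s]],
        end_bp = map$pos_bp[cols[s] + n_snps - 1],
        start_snp = cols[s], end_snp = cols[s] + n_snps - 1,
        n_snps = n_snps, cnv_allele = al, ld_mode = mode_name,
        n_carriers = sum(cn != 2L), stringsAsFactors = FALSE
      )
      truth[[li]] <- data.frame(
        animal_id = haps$animal_ids, locus_id = locus_id,
        true_cn = cn, stringsAsFactors = FALSE
      )
      used[[as.character(cc)]] <- c(used[[as.character(cc)]] %||% list(),
                                    list(rng))
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place locus ", li, " with carrier frequency in [",
           freq_range[1], ", ", freq_range[2], "] after ", max_tries,
           " tries; population too small or frequency range unattainable")
    }
  }
  list(loci = do.call(rbind, loci),
       truth = do.call(rbind, truth),
       hap_alleles = hap_alleles)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
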