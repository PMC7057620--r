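#' Run the CNV-imputation experiment for one breed
#'
#' Strings together the imputation design: consensus CNVs are grouped
#' into population loci and filtered to those carried by at least
#' `min_carriers` animals; each selected locus is recoded as a midpoint
#' marker; the oldest 80% of the breed (by birth order) form the
#' reference population with known marker genotypes and the youngest
#' 20% the validation population; for each flank size `k` the marker is
#' imputed onto the validation animals from the `k` SNPs on each side
#' of the midpoint.
#'
#' Validation animals without a consensus call at a locus have called
#' copy number 2 (normal) -- this is what makes the normal state
#' dominate the validation sets. Reference marker alleles are the
#' called copy numbers phased onto haplotypes; where the simulator
#' truth (`cnvs`) identifies the carrier haplotype of an animal the
#' called alleles are oriented onto it, otherwise the orientation is
#' deterministic.
#'
#' @param consensus consensus calls for the breed's animals.
#' @param ped pedigree (one breed, or filtered by `breed`).
#' @param map SNP map whose rows align with `map$hap_col` columns of
#'   the haplotype matrix (after QC, `hap_col` carries the original
#'   column index; without it, rows align directly).
#' @param haps `hap_set`.
#' @param cnvs optional [plant_cnv_loci()] result used to orient
#'   heterozygous reference markers onto the true carrier haplotype.
#' @param breed breed to analyse (default: all animals in `ped`).
#' @param flank_ks flank sizes (SNPs per side).
#' @param mode marker encoding, see [cn_to_allele_pair()].
#' @param method imputer preset, see [impute_marker()].
#' @param min_carriers locus-selection threshold.
#' @param frac_reference reference fraction of the age split.
#' @param bp_tol locus-grouping coordinate tolerance.
#' @param switch_rate,error_rate copying-model rates.
#' @return data.frame with one row per (locus, flank k, validation
#'   animal): `breed`, `locus_id`, `flank_k`, `method`, `mode`,
#'   `animal_id`, `called_cn`, `imputed_cn`, `correct`,
#'   `bayes_factor` (the animal's consensus-call Bayes factor, `NA`
#'   for uncalled animals), `population_frequency` (carrier animals at
#'   the locus) and `length_kb`.
#' @export
run_imputation_experiment <- function(consensus, ped, map, haps,
                                      cnvs = NULL, breed = NULL,
                                      flank_ks = c(10, 25, 50, 100, 250, 500),
                                      mode = "triallelic",
                                      method = c("hmm", "window"),
                                      min_carriers = 30,
                                      frac_reference = 0.8, bp_tol = 0,
                                      switch_rate = 0.01,
                                      error_rate = 0.002) {
  method <- match.arg(method)
  if (!is.null(breed)) {
    ped <- ped[ped$breed == breed, , drop = FALSE]
    consensus <- consensus[consensus$animal_id %in% ped$animal_id, ,
                           drop = FALSE]
  }
  breed_label <- if (!is.null(breed)) breed else
    paste(unique(ped$breed), collapse = "+")
  empty <- data.frame(breed = character(0), locus_id = character(0),
                      flank_k = integer(0), method = character(0),
                      mode = character(0), animal_id = character(0),
                      called_cn = integer(0), imputed_cn = integer(0),
                      correct = logical(0), bayes_factor = numeric(0),
                      population_frequency = integer(0),
                      length_kb = numeric(0), stringsAsFactors = FALSE)
  sel <- group_loci_and_select(consensus, min_carriers, bp_tol)
  if (nrow(sel$loci) == 0) return(empty)
  split_rv <- split_reference_validation(ped, frac_reference = frac_reference)
  hap_col <- map$hap_col %||% seq_len(nrow(map))
  hap_of <- split(seq_len(nrow(haps$alleles)), haps$hap_animal)

  out <- list()
  for (li in seq_len(nrow(sel$loci))) {
    locus <- sel$loci[li, ]
    asg <- sel$assignments[sel$assignments$locus_id == locus$locus_id, ]
    called <- stats::setNames(rep(2L, nrow(ped)), ped$animal_id)
    called[asg$animal_id] <- asg$copy_number
    bf <- stats::setNames(rep(NA_real_, nrow(ped)), ped$animal_id)
    bf[asg$animal_id] <- asg$bayes_factor

    # simulator truth for phasing: best-overlapping planted locus
    truth_hap <- NULL
    if (!is.null(cnvs)) {
      pl <- cnvs$loci
      ov <- ifelse(pl$chrom == locus$chrom,
                   pmin(pl$end_bp, locus$end_bp) -
                     pmax(pl$start_bp, locus$start_bp) + 1, 0)
      if (any(ov > 0)) truth_hap <- cnvs$hap_alleles[, which.max(ov)]
    }

    marker <- encode_marker(locus, called, mode = mode)
    # phased reference marker alleles, one per reference haplotype
    ref_rows <- unlist(hap_of[split_rv$reference], use.names = FALSE)
    ref_marker <- character(length(ref_rows))
    for (a in seq_along(split_rv$reference)) {
      an <- split_rv$reference[a]
      pair <- marker$genotypes[an, ]
      tp <- if (!is.null(truth_hap)) truth_hap[hap_of[[an]]] else NULL
      pair <- phase_pair(pair, tp)
      ref_marker[c(2 * a - 1, 2 * a)] <- pair
    }
    val_rows <- unlist(hap_of[split_rv$validation], use.names = FALSE)

    for (k in flank_ks) {
      fl <- extract_flanks(map, locus$chrom, marker$midpoint_bp, k)
      if (is.null(fl)) next
      cols <- hap_col[fl$idx]
      ref_flank <- haps$alleles[ref_rows, cols, drop = FALSE]
      val_flank <- haps$alleles[val_rows, cols, drop = FALSE]
      imp_allele <- impute_marker(ref_flank, ref_marker, val_flank,
                                  fl$n_left, method = method,
                                  switch_rate = switch_rate,
                                  error_rate = error_rate)
      n_val <- length(split_rv$validation)
      imputed <- vapply(seq_len(n_val), function(v) {
        allele_pair_to_cn(imp_allele[c(2 * v - 1, 2 * v)])
      }, integer(1))
      # called copy number on the same coding scale as the imputer
      called_coded <- vapply(split_rv$validation, function(an) {
        allele_pair_to_cn(marker$genotypes[an, ])
      }, integer(1))
      out[[length(out) + 1L]] <- data.frame(
        breed = breed_label, locus_id = locus$locus_id, flank_k = k,
        method = method, mode = mode,
        animal_id = split_rv$validation,
        called_cn = called_coded, imputed_cn = imputed,
        correct = called_coded == imputed,
        bayes_factor = unname(bf[split_rv$validation]),
        population_frequency = locus$n_carriers,
        length_kb = locus$length_kb, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
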