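#' Consensus CNVs called by both callers
#'
#' A CNV is considered called by both callers when it is called in the
#' same animal on the same chromosome by both, with the same copy
#' number, and its endpoint demarcation differs by at most
#' `snp_tolerance` SNPs at each end (default 1: a difference of one
#' SNP in the endpoint demarcation between the callers is allowed).
#' Matching is greedy in start order and each call is used at most
#' once; the consensus interval is the union of the two calls.
#'
#' @param penn_calls,quanti_calls call data.frames sharing one SNP
#'   index space (both called on the HD panel).
#' @param snp_tolerance maximum per-end SNP-index difference.
#' @return data.frame: `animal_id`, `chrom`, `start_bp`, `end_bp`,
#'   `start_snp_index`, `end_snp_index` (union interval),
#'   `copy_number`, `n_snps`, `bayes_factor` (from the quanti-like
#'   call).
#' @export
consensus_calls <- function(penn_calls, quanti_calls, snp_tolerance = 1) {
  if (nrow(penn_calls) == 0 || nrow(quanti_calls) == 0) {
    return(data.frame(animal_id = character(0), chrom = integer(0),
                      start_bp = integer(0), end_bp = integer(0),
                      start_snp_index = integer(0),
                      end_snp_index = integer(0), copy_number = integer(0),
                      n_snps = integer(0), bayes_factor = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- list()
  qkey <- paste(quanti_calls$animal_id, quanti_calls$chrom)
  q_by <- split(seq_len(nrow(quanti_calls)), qkey)
  used <- rep(FALSE, nrow(quanti_calls))
  ord <- order(penn_calls$animal_id, penn_calls$chrom, penn_calls$start_bp)
  for (i in ord) {
    cand <- q_by[[paste(penn_calls$animal_id[i], penn_calls$chrom[i])]]
    cand <- cand[!used[cand]]
    if (length(cand) == 0) next
    ds <- abs(quanti_calls$start_snp_index[cand] - penn_calls$start_snp_index[i])
    de <- abs(quanti_calls$end_snp_index[cand] - penn_calls$end_snp_index[i])
    ok <- which(ds <= snp_tolerance & de <= snp_tolerance &
                  quanti_calls$copy_number[cand] == penn_calls$copy_number[i])
    if (length(ok) == 0) next
    j <- cand[ok[order(ds[ok] + de[ok],
                       quanti_calls$start_bp[cand[ok]])][1]]
    used[j] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      animal_id = penn_calls$animal_id[i], chrom = penn_calls$chrom[i],
      start_bp = min(penn_calls$start_bp[i], quanti_calls$start_bp[j]),
      end_bp = max(penn_calls$end_bp[i], quanti_calls$end_bp[j]),
      start_snp_index = min(penn_calls$start_snp_index[i],
                            quanti_calls$start_snp_index[j]),
      end_snp_index = max(penn_calls$end_snp_index[i],
                          quanti_calls$end_snp_index[j]),
      copy_number = penn_calls$copy_number[i],
      n_snps = max(penn_calls$end_snp_index[i],
                   quanti_calls$end_snp_index[j]) -
        min(penn_calls$start_snp_index[i],
            quanti_calls$start_snp_index[j]) + 1L,
      bayes_factor = quanti_calls$bayes_factor[j],
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) return(consensus_calls(penn_calls[0, ], quanti_calls))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group consensus CNVs into population loci and select by frequency
#'
#' Groups per-animal consensus CNVs that share coordinates (within a
#' `bp_tol` jitter at each end; default 0 = exact) into population-level
#' loci and keeps loci carried by at least `min_carriers` animals --
#' the selection rule that avoids small-sample bias when scoring
#' imputation. Selection is intended to run within one breed.
#'
#' @param consensus data.frame from [consensus_calls()].
#' @param min_carriers minimum number of carrier animals.
#' @param bp_tol coordinate jitter tolerated when grouping.
#' @return list with `loci` (selected loci: `locus_id`, `chrom`,
#'   `start_bp`, `end_bp`, `midpoint_bp`, `length_kb`, `n_carriers`)
#'   and `assignments` (all consensus rows with their `locus_id`).
#' @export
group_loci_and_select <- function(consensus, min_carriers = 30, bp_tol = 0) {
  if (nrow(consensus) == 0) {
    warning("no consensus CNVs; no locus qualifies for imputation")
    return(list(loci = data.frame(), assignments = consensus))
  }
  ord <- order(consensus$chrom, consensus$start_bp, consensus$end_bp)
  cs <- consensus[ord, , drop = FALSE]
  locus_id <- character(nrow(cs))
  reps <- list()  # group representatives
  for (i in seq_len(nrow(cs))) {
    assigned <- FALSE
    for (g in seq_along(reps)) {
      r <- reps[[g]]
      if (cs$chrom[i] == r$chrom &&
          abs(cs$start_bp[i] - r$start_bp) <= bp_tol &&
          abs(cs$end_bp[i] - r$end_bp) <= bp_tol) {
        locus_id[i] <- r$id; assigned <- TRUE; break
      }
    }
    if (!assigned) {
      id <- sprintf("L%s_%d_%d", cs$chrom[i], cs$start_bp[i], cs$end_bp[i])
      reps[[length(reps) + 1L]] <- list(chrom = cs$chrom[i],
                                        start_bp = cs$start_bp[i],
                                        end_bp = cs$end_bp[i], id = id)
      locus_id[i] <- id
    }
  }
  cs$locus_id <- locus_id
  carriers <- tapply(cs$animal_id, cs$locus_id,
                     function(a) length(unique(a)))
  sel <- names(carriers)[carriers >= min_carriers]
  if (length(sel) == 0) {
    warning("no locus reaches ", min_carriers, " carriers")
    return(list(loci = data.frame(), assignments = cs))
  }
  loci <- do.call(rbind, lapply(sel, function(id) {
    r <- reps[[which(vapply(reps, function(x) x$id, "") == id)]]
    data.frame(locus_id = id, chrom = r$chrom, start_bp = r$start_bp,
               end_bp = r$end_bp,
               midpoint_bp = floor((r$start_bp + r$end_bp) / 2),
               length_kb = (r$end_bp - r$start_bp + 1) / 1000,
               n_carriers = as.integer(carriers[[id]]),
               stringsAsFactors = FALSE)
  }))
  rownames(loci) <- NULL
  list(loci = loci[order(loci$chrom, loci$start_bp), , drop = FALSE],
       assignments = cs)
}

#' Copy number to CNV-marker allele pair, and back
#'
#' The tri-allelic midpoint encoding: alleles `N` (normal), `D`
#' (deletion), `P` (duplication). Copy number maps to genotype as
#' 0 = (D,D), 1 = (N,D), 2 = (N,N), 3 = (N,P), 4 = (P,P). The
#' bi-allelic split codings collapse the invisible class to normal:
#' `biallelic_del` keeps {N,D} (3 and 4 become (N,N)), `biallelic_dup`
#' keeps {N,P} (0 and 1 become (N,N)).
#'
#' @param cn integer copy number in 0..4.
#' @param mode `"triallelic"`, `"biallelic_del"` or `"biallelic_dup"`.
#' @return `cn_to_allele_pair`: character vector of length 2;
#'   `allele_pair_to_cn`: integer copy number.
#' @export
cn_to_allele_pair <- function(cn, mode = "triallelic") {
  if (!cn %in% 0:4) stop("copy number must be in 0..4, got ", cn)
  pair <- switch(as.character(cn),
                 "0" = c("D", "D"), "1" = c("N", "D"), "2" = c("N", "N"),
                 "3" = c("N", "P"), "4" = c("P", "P"))
  if (mode == "biallelic_del" && cn >= 2) pair <- c("N", "N")
  if (mode == "biallelic_dup" && cn <= 2) pair <- c("N", "N")
  pair
}

#' @rdname cn_to_allele_pair
#' @param pair character vector of two alleles in {"N","D","P"}.
#' @export
allele_pair_to_cn <- function(pair) {
  stopifnot(length(pair) == 2, all(pair %in% c("N", "D", "P")))
  contrib <- c(N = 1L, D = 0L, P = 2L)
  sum(contrib[pair])
}

#' Encode a selected CNV locus as a midpoint marker
#'
#' @param locus one row of the `loci` table from
#'   [group_loci_and_select()].
#' @param copy_numbers named integer vector (animal id -> called copy
#'   number; animals without a call at the locus are copy number 2).
#' @param mode encoding mode, see [cn_to_allele_pair()].
#' @return list of class `cnv_marker`: `locus_id`, `chrom`,
#'   `midpoint_bp`, `mode`, and `genotypes` (2-column character matrix
#'   of allele pairs, rownames = animal ids).
#' @export
encode_marker <- function(locus, copy_numbers, mode = "triallelic") {
  g <- t(vapply(copy_numbers, cn_to_allele_pair, character(2), mode = mode))
  rownames(g) <- names(copy_numbers)
  structure(list(locus_id = locus$locus_id, chrom = locus$chrom,
                 midpoint_bp = floor((locus$start_bp + locus$end_bp) / 2),
                 mode = mode, genotypes = g), class = "cnv_marker")
}

#' Indices of the k SNPs flanking each side of a midpoint
#'
#' The k nearest SNPs strictly left of the midpoint and the k nearest
#' strictly right, by position, on the marker's chromosome. SNPs inside
#' the CNV interval are eligible by design (the flanks are taken around
#' the midpoint, not around the CNV boundaries). A chromosome end may
#' truncate a side; if a side is completely empty the task should be
#' skipped.
#'
#' @param map SNP map (sorted).
#' @param chrom,midpoint_bp marker location.
#' @param k SNPs requested per side.
#' @return list with `idx` (sorted row indices into `map`), `n_left`,
#'   `n_right`; or `NULL` when one side has no SNP at all.
#' @export
extract_flanks <- function(map, chrom, midpoint_bp, k) {
  cols <- which(map$chrom == chrom)
  pos <- map$pos_bp[cols]
  left <- cols[pos < midpoint_bp]
  right <- cols[pos > midpoint_bp]
  if (length(left) == 0 || length(right) == 0) {
    warning("midpoint at ", chrom, ":", midpoint_bp,
            " has an empty flank side; task skipped")
    return(NULL)
  }
  lsel <- utils::tail(left, k)
  rsel <- utils::head(right, k)
  list(idx = c(lsel, rsel), n_left = length(lsel), n_right = length(rsel))
}

#' Oldest-80% reference / youngest-20% validation split
#'
#' Within a breed, the oldest `frac_reference` of animals (by birth
#' order, smaller = older) form the reference population whose marker
#' genotypes are known; the remaining animals form the validation
#' population whose marker is hidden and imputed. The reference takes
#' `ceiling(frac * n)` animals, so the oldest animal is always in it.
#'
#' @param ped pedigree.
#' @param breed optional breed to restrict to.
#' @param frac_reference reference fraction.
#' @return list with character vectors `reference` and `validation`.
#' @export
split_reference_validation <- function(ped, breed = NULL,
                                       frac_reference = 0.8) {
  if (!is.null(breed)) ped <- ped[ped$breed == breed, , drop = FALSE]
  n <- nrow(ped)
  if (n < 5) stop("need at least 5 animals to split, got ", n)
  ord <- ped$animal_id[order(ped$birth_order)]
  n_ref <- ceiling(frac_reference * n)
  list(reference = ord[seq_len(n_ref)],
       validation = ord[seq.int(n_ref + 1L, n)])
}

# integer codes for marker alleles, kept clear of the 0/1 SNP codes
.marker_code <- c(N = 0L, D = 1L, P = 2L)

#' Impute a CNV marker allele onto validation haplotypes
#'
#' Given reference haplotypes carrying both the flanking SNP alleles
#' and the marker allele, and validation haplotypes carrying the flank
#' alleles only, imputes the marker allele of each validation
#' haplotype. Two presets:
#' \describe{
#'   \item{`"hmm"`}{a haploid Li-Stephens haplotype-copying model:
#'     each validation haplotype is a mosaic of reference haplotypes
#'     with per-SNP template-switch probability `switch_rate` and
#'     allele-mismatch probability `error_rate`; the imputed allele is
#'     the posterior-mode marker allele at the marker column.}
#'   \item{`"window"`}{a sliding-window haplotype match: the reference
#'     haplotype with the longest exact allele match spanning the
#'     midpoint donates its marker allele (ties: majority allele among
#'     the tied templates, then N > D > P).}
#' }
#' Both are deterministic given their inputs.
#'
#' @param ref_flank integer matrix (reference haplotypes x flank SNPs,
#'   0/1 alleles, columns in genome order).
#' @param ref_marker character vector of reference marker alleles
#'   ("N"/"D"/"P"), one per reference haplotype.
#' @param val_flank integer matrix (validation haplotypes x flank
#'   SNPs).
#' @param n_left number of flank columns left of the midpoint.
#' @param method `"hmm"` or `"window"`.
#' @param switch_rate,error_rate copying-model rates (hmm preset).
#' @return character vector of imputed marker alleles, one per
#'   validation haplotype.
#' @export
impute_marker <- function(ref_flank, ref_marker, val_flank, n_left,
                          method = c("hmm", "window"),
                          switch_rate = 0.01, error_rate = 0.002) {
  method <- match.arg(method)
  H <- nrow(ref_flank)
  if (is.null(H) || H == 0) stop("empty reference haplotype panel")
  P <- ncol(ref_flank)
  stopifnot(length(ref_marker) == H, ncol(val_flank) == P,
            n_left >= 1, n_left < P)
  alleles <- c("N", "D", "P")
  if (length(unique(ref_marker)) == 1) {
    message("marker monomorphic in reference; imputing the single allele")
    return(rep(ref_marker[1], nrow(val_flank)))
  }
  if (method == "hmm") {
    ref_full <- cbind(ref_flank[, seq_len(n_left), drop = FALSE],
                      .marker_code[ref_marker],
                      ref_flank[, seq.int(n_left + 1, P), drop = FALSE])
    storage.mode(ref_full) <- "integer"
    marker_col <- n_left + 1L
    out <- character(nrow(val_flank))
    for (v in seq_len(nrow(val_flank))) {
      obs <- c(val_flank[v, seq_len(n_left)], NA_integer_,
               val_flank[v, seq.int(n_left + 1, P)])
      post <- ls_posterior_cpp(ref_full, as.integer(obs), marker_col,
                               switch_rate, error_rate)
      ap <- vapply(alleles, function(a) sum(post[ref_marker == a]),
                   numeric(1))
      out[v] <- alleles[which.max(ap)]
    }
    return(out)
  }
  # window preset
  out <- character(nrow(val_flank))
  for (v in seq_len(nrow(val_flank))) {
    eq <- ref_flank == matrix(val_flank[v, ], H, P, byrow = TRUE)
    runL <- integer(H); alive <- rep(TRUE, H)
    for (j in n_left:1) {
      alive <- alive & eq[, j]
      runL <- runL + alive
      if (!any(alive)) break
    }
    runR <- integer(H); alive <- rep(TRUE, H)
    for (j in seq.int(n_left + 1, P)) {
      alive <- alive & eq[, j]
      runR <- runR + alive
      if (!any(alive)) break
    }
    score <- runL + runR
    cand <- which(score == max(score))
    tab <- table(factor(ref_marker[cand], levels = alleles))
    out[v] <- alleles[which.max(tab)]
  }
  out
}

# orient a called allele pair onto an animal's two haplotypes, using
# the simulator's true carrier haplotypes where they are consistent
phase_pair <- function(pair, truth_pair = NULL) {
  if (is.null(truth_pair) || pair[1] == pair[2]) return(pair)
  if (all(sort(pair) == sort(truth_pair))) return(truth_pair)
  nonN <- which(truth_pair != "N")
  if (length(nonN) == 1) {
    out <- c("N", "N")
    out[nonN] <- pair[pair != "N"][1]
    return(out)
  }
  pair
}
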