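#' Parameters of the five-state copy-number HMM
#'
#' States are indexed by diploid copy number 0..4, state 2 being the
#' normal diploid state. Emissions combine a Gaussian on the LRR with a
#' BAF mixture over the `b/cn` cluster means of the state (uniform for
#' copy number 0, where there is no allele signal), plus a small
#' uniform outlier component; transitions are distance-dependent with
#' `expected_cnv_length_bp` setting the length prior (see
#' [viterbi_segment()]).
#'
#' Two presets are provided: `"penn_like"` (short length prior, no
#' Bayes factor) and `"quanti_like"` (longer length prior; segments get
#' a log10 Bayes factor attached). State means/SDs default to the
#' conventional values used for Illumina-style arrays.
#'
#' @param state_lrr_means expected LRR per state.
#' @param state_lrr_sds LRR SD per state.
#' @param baf_sd BAF cluster SD.
#' @param baf_outlier_weight weight of the uniform BAF outlier
#'   component.
#' @param expected_cnv_length_bp transition distance scale.
#' @param state_entry_prob entry probability of each state; must sum
#'   to 1 and put almost all mass on state 2.
#' @param preset `"penn_like"` or `"quanti_like"`.
#' @return list of class `hmm_params`.
#' @export
hmm_params <- function(state_lrr_means = c(-3.5, -0.66, 0, 0.4, 0.68),
                       state_lrr_sds = c(1.3, 0.28, 0.21, 0.21, 0.26),
                       baf_sd = 0.06, baf_outlier_weight = 0.01,
                       expected_cnv_length_bp = NULL,
                       state_entry_prob = NULL,
                       preset = c("penn_like", "quanti_like")) {
  preset <- match.arg(preset)
  if (is.null(expected_cnv_length_bp)) {
    expected_cnv_length_bp <- if (preset == "penn_like") 1e5 else 2e6
  }
  if (is.null(state_entry_prob)) {
    state_entry_prob <- c(1e-4, 9e-4, 1 - 2e-3, 9e-4, 1e-4)
  }
  stopifnot(length(state_lrr_means) == 5, length(state_lrr_sds) == 5,
            all(state_lrr_sds > 0), baf_sd > 0,
            baf_outlier_weight >= 0, baf_outlier_weight <= 1,
            expected_cnv_length_bp > 0, length(state_entry_prob) == 5,
            abs(sum(state_entry_prob) - 1) < 1e-8,
            all(state_entry_prob > 0))
  structure(list(state_lrr_means = state_lrr_means,
                 state_lrr_sds = state_lrr_sds,
                 baf_sd = baf_sd,
                 baf_outlier_weight = baf_outlier_weight,
                 expected_cnv_length_bp = expected_cnv_length_bp,
                 state_entry_prob = state_entry_prob,
                 preset = preset), class = "hmm_params")
}

# truncated-normal density on [0,1]; boundary clusters keep a proper
# density this way instead of degenerating to point masses
dtnorm01 <- function(x, mean, sd) {
  z <- stats::pnorm(1, mean, sd) - stats::pnorm(0, mean, sd)
  stats::dnorm(x, mean, sd) / z
}

#' Per-SNP emission log-likelihood of one HMM state
#'
#' Gaussian LRR term plus the BAF mixture of the state. For state
#' `cn >= 1` the BAF clusters sit at `b/cn`, `b = 0..cn`, weighted by
#' the binomial genotype probabilities given the population B allele
#' frequency `pfb`; cluster densities are normals truncated to
#' `[0, 1]`. State 0 emits a uniform BAF. A `baf_outlier_weight`
#' uniform component keeps the density finite and robust everywhere.
#'
#' @param lrr,baf numeric vectors (one value per SNP).
#' @param pfb population B allele frequency per SNP (scalar recycled).
#' @param state copy-number state 0..4.
#' @param params `hmm_params`.
#' @return numeric vector of log densities.
#' @export
emission_loglik <- function(lrr, baf, pfb = 0.5, state, params) {
  stopifnot(state %in% 0:4, all(baf >= 0 & baf <= 1))
  n <- length(lrr)
  pfb <- rep_len(pfb, n)
  ll_lrr <- stats::dnorm(lrr, params$state_lrr_means[state + 1],
                         params$state_lrr_sds[state + 1], log = TRUE)
  w <- params$baf_outlier_weight
  if (state == 0) {
    dens <- rep(1, n)  # uniform on [0,1]
  } else {
    dens <- numeric(n)
    for (b in 0:state) {
      dens <- dens + stats::dbinom(b, state, pfb) *
        dtnorm01(baf, b / state, params$baf_sd)
    }
  }
  ll_baf <- log((1 - w) * dens + w)
  ll_lrr + ll_baf
}

# emission log-likelihood matrix (n x 5) for vectors of signals
emission_matrix <- function(lrr, baf, pfb, params) {
  vapply(0:4, function(s) emission_loglik(lrr, baf, pfb, s, params),
         numeric(length(lrr)))
}

#' Remove the GC wave from LRR by per-sample regression
#'
#' The median intensity of a genomic region correlates with its GC
#' content ("genomic waves"); this adjustment regresses each animal's
#' LRR on the local GC fraction of the SNP (GC content of the sequence
#' flanking the SNP) and keeps the residuals, preserving each animal's
#' mean LRR. After adjustment the sample correlation between LRR and GC
#' is zero up to numerical tolerance. A constant GC track makes the
#' regression undefined; the signals are then returned unchanged with a
#' warning.
#'
#' @param signals `signal_set`.
#' @param map SNP map aligned to `signals` (provides `gc_frac`).
#' @return the `signal_set` with adjusted `lrr`.
#' @export
gc_adjust_lrr <- function(signals, map) {
  gc <- map$gc_frac
  stopifnot(length(gc) == ncol(signals$lrr))
  xc <- gc - mean(gc)
  ss <- sum(xc^2)
  if (ss < .Machine$double.eps * length(gc)) {
    warning("GC track is constant; LRR left unadjusted")
    return(signals)
  }
  beta <- as.vector(signals$lrr %*% xc) / ss
  signals$lrr <- signals$lrr - outer(beta, xc)
  signals
}

#' Viterbi segmentation of one animal's signals on one chromosome
#'
#' Decodes the maximum-probability copy-number state path and turns
#' maximal runs of a constant non-normal state into CNV segments. Runs
#' shorter than `min_snps` are discarded, not merged: a CNV must span
#' at least `min_snps` consecutive SNPs (default 3) to be called, and
#' no upper length limit is applied.
#'
#' @param lrr,baf,pos aligned numeric vectors for one chromosome,
#'   positions strictly increasing.
#' @param params `hmm_params`.
#' @param min_snps minimum SNPs per emitted segment.
#' @param pfb population B allele frequency per SNP.
#' @return data.frame with one row per segment: `start_idx`, `end_idx`
#'   (1-based indices into the input vectors), `copy_number`, `n_snps`.
#' @export
viterbi_segment <- function(lrr, baf, pos, params, min_snps = 3, pfb = 0.5) {
  n <- length(lrr)
  if (n < 1) {
    return(data.frame(start_idx = integer(0), end_idx = integer(0),
                      copy_number = integer(0), n_snps = integer(0)))
  }
  E <- emission_matrix(lrr, baf, pfb, params)
  segments_from_emissions(E, pos, params, min_snps)
}

# shared run-extraction over a precomputed emission matrix
segments_from_emissions <- function(E, pos, params, min_snps = 3) {
  path <- viterbi_path_cpp(E, diff(pos), params$expected_cnv_length_bp,
                           params$state_entry_prob)
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 2L & r$lengths >= min_snps
  data.frame(start_idx = starts[keep], end_idx = ends[keep],
             copy_number = r$values[keep], n_snps = r$lengths[keep])
}

#' Log10 Bayes factor of a called segment
#'
#' Measures whether the data support the segment being a true CNV:
#' the log10 likelihood ratio of the segment's SNPs under the called
#' state versus under the normal state, summed over the segment's
#' SNPs (per-SNP terms are independent given the state).
#'
#' @param lrr,baf,pfb signal vectors covering exactly the segment SNPs.
#' @param copy_number the called state.
#' @param params `hmm_params`.
#' @return scalar log10 Bayes factor.
#' @export
bayes_factor <- function(lrr, baf, pfb = 0.5, copy_number, params) {
  ll_cnv <- emission_loglik(lrr, baf, pfb, copy_number, params)
  ll_norm <- emission_loglik(lrr, baf, pfb, 2, params)
  sum(ll_cnv - ll_norm) / log(10)
}

#' Call CNVs genome-wide for all animals
#'
#' Applies the GC-wave adjustment, restricts to the requested panel,
#' and runs Viterbi segmentation per animal and chromosome. The
#' `"quanti_like"` caller is the same decoder with its own length prior
#' and attaches a log10 Bayes factor to every call; `"penn_like"` calls
#' carry `NA` there.
#'
#' @param signals `signal_set` (HD signals).
#' @param map HD SNP map aligned to `signals`.
#' @param panel `"HD"` or `"MD"`; `"MD"` restricts to `on_md_panel`
#'   SNPs before decoding.
#' @param caller `"penn_like"` or `"quanti_like"`.
#' @param params optional `hmm_params`; defaults to the caller preset.
#' @param min_snps minimum SNPs per call.
#' @param gc_adjust apply [gc_adjust_lrr()] first.
#' @param pfb optional per-SNP population B allele frequency (aligned
#'   to the HD map); default 0.5 everywhere.
#' @return data.frame of calls: `animal_id`, `chrom`, `start_bp`,
#'   `end_bp` (1-based closed, at SNP positions), `start_snp_index`,
#'   `end_snp_index` (row indices into the panel-restricted map),
#'   `copy_number`, `n_snps`, `caller`, `bayes_factor`.
#' @export
call_cnvs <- function(signals, map, panel = c("HD", "MD"),
                      caller = c("penn_like", "quanti_like"),
                      params = NULL, min_snps = 3, gc_adjust = TRUE,
                      pfb = NULL) {
  panel <- match.arg(panel)
  caller <- match.arg(caller)
  if (is.null(params)) params <- hmm_params(preset = caller)
  stopifnot(inherits(params, "hmm_params"))
  if (is.null(pfb)) pfb <- rep(0.5, nrow(map))
  if (panel == "MD") {
    keep <- which(map$on_md_panel)
    map <- map[keep, , drop = FALSE]
    rownames(map) <- NULL
    signals <- subset_signal_snps(signals, keep)
    pfb <- pfb[keep]
  }
  if (gc_adjust) signals <- gc_adjust_lrr(signals, map)

  n_animal <- length(signals$animal_ids)
  out <- vector("list", 0)
  for (cc in unique(map$chrom)) {
    cols <- which(map$chrom == cc)
    pos <- map$pos_bp[cols]
    lrr_c <- signals$lrr[, cols, drop = FALSE]
    baf_c <- signals$baf[, cols, drop = FALSE]
    pfb_c <- pfb[cols]
    # one vectorized emission evaluation for all animals on this chrom
    E_all <- emission_matrix(as.vector(lrr_c), as.vector(baf_c),
                             rep(pfb_c, each = n_animal), params)
    for (a in seq_len(n_animal)) {
      idx <- a + (seq_along(cols) - 1L) * n_animal
      segs <- segments_from_emissions(E_all[idx, , drop = FALSE], pos,
                                      params, min_snps)
      if (nrow(segs) == 0) next
      bf <- NA_real_
      if (caller == "quanti_like") {
        bf <- vapply(seq_len(nrow(segs)), function(i) {
          sub <- segs$start_idx[i]:segs$end_idx[i]
          bayes_factor(lrr_c[a, sub], baf_c[a, sub], pfb_c[sub],
                       segs$copy_number[i], params)
        }, numeric(1))
      }
      out[[length(out) + 1L]] <- data.frame(
        animal_id = signals$animal_ids[a], chrom = cc,
        start_bp = pos[segs$start_idx], end_bp = pos[segs$end_idx],
        start_snp_index = cols[segs$start_idx],
        end_snp_index = cols[segs$end_idx],
        copy_number = segs$copy_number, n_snps = segs$n_snps,
        caller = caller, bayes_factor = bf, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(animal_id = character(0), chrom = integer(0),
                      start_bp = integer(0), end_bp = integer(0),
                      start_snp_index = integer(0),
                      end_snp_index = integer(0),
                      copy_number = integer(0), n_snps = integer(0),
                      caller = character(0), bayes_factor = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
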