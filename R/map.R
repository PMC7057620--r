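#' Simulate an autosomal SNP map with a local GC track
#'
#' Builds the coordinate backbone used by every other stage: ordered SNP
#' positions on one or more autosomes, a smooth local GC-content track
#' (the GC fraction of a window around each SNP, which later induces the
#' "genomic wave" artifact in the Log R Ratio), and a panel-membership
#' flag initialised to the full high-density (HD) set.
#'
#' The GC track is a latent AR(1) series squashed into a realistic
#' autosomal range (about 0.3--0.6); only its smoothness and its
#' correlation with the rendered LRR matter downstream, not its
#' base-level realism.
#'
#' @param n_chrom number of autosomes.
#' @param snps_per_chrom SNPs per autosome.
#' @param chrom_length_bp autosome length in base pairs.
#' @param gc_smoothness AR(1) coefficient of the latent GC series
#'   (closer to 1 = smoother waves).
#' @param seed integer seed.
#' @return a `data.frame` with columns `snp_id`, `chrom`, `pos_bp`
#'   (1-based), `on_md_panel` (all `TRUE` initially) and `gc_frac`,
#'   ordered by chromosome then position, positions strictly increasing
#'   within chromosome.
#' @export
simulate_snp_map <- function(n_chrom = 3, snps_per_chrom = 5000,
                             chrom_length_bp = 5e7,
                             gc_smoothness = 0.995, seed = 1) {
  stopifnot(n_chrom >= 1, snps_per_chrom >= 2, chrom_length_bp > snps_per_chrom)
  set.seed(seed)
  pieces <- lapply(seq_len(n_chrom), function(chr) {
    pos <- sort(sample.int(chrom_length_bp, snps_per_chrom))
    # strictly increasing is guaranteed by sampling without replacement
    z <- numeric(snps_per_chrom)
    z[1] <- stats::rnorm(1)
    innov <- stats::rnorm(snps_per_chrom - 1, sd = sqrt(1 - gc_smoothness^2))
    for (i in 2:snps_per_chrom) z[i] <- gc_smoothness * z[i - 1] + innov[i - 1]
    gc <- 0.3 + 0.3 * stats::plogis(z)
    data.frame(
      snp_id = sprintf("snp%d_%07d", chr, seq_len(snps_per_chrom)),
      chrom = chr,
      pos_bp = pos,
      on_md_panel = TRUE,
      gc_frac = gc,
      stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, pieces)
  rownames(map) <- NULL
  map
}

#' Flag a nested medium-density subset of the HD map
#'
#' Emulates the construction of a medium-density (MD) panel as the SNPs
#' shared between the edited HD panel and a commercial ~50k beadchip:
#' either an explicit SNP-id list, or a seeded thinning to an exact
#' target fraction (`floor(fraction * n)` SNPs, sampled without
#' replacement). The default fraction mirrors the ~6.4% size ratio of a
#' 45,677-SNP panel nested in a 713,162-SNP panel.
#'
#' @param map SNP map as from [simulate_snp_map()].
#' @param md either a numeric fraction in (0, 1] or a character vector
#'   of SNP ids that must all exist in `map`.
#' @param seed integer seed used only for fractional thinning.
#' @return the map with `on_md_panel` set for the selected SNPs only.
#' @export
make_md_subset <- function(map, md = 45677 / 713162, seed = 1) {
  stopifnot(is.data.frame(map), nrow(map) >= 1)
  if (is.character(md)) {
    missing_ids <- setdiff(md, map$snp_id)
    if (length(missing_ids) > 0) {
      stop("SNP id(s) absent from the HD map: ",
           paste(utils::head(missing_ids, 5), collapse = ", "))
    }
    map$on_md_panel <- map$snp_id %in% md
    return(map)
  }
  stopifnot(is.numeric(md), length(md) == 1, md > 0, md <= 1)
  n_keep <- floor(md * nrow(map))
  set.seed(seed)
  keep <- sort(sample.int(nrow(map), n_keep))
  map$on_md_panel <- FALSE
  map$on_md_panel[keep] <- TRUE
  map
}

#' Restrict a map (and optionally a signal set) to one panel
#'
#' @param map SNP map.
#' @param signals optional signal set aligned to `map`.
#' @param panel `"HD"` (all SNPs) or `"MD"` (SNPs with `on_md_panel`).
#' @return the map alone, or `list(map=, signals=)` when signals given.
#' @export
restrict_panel <- function(map, signals = NULL, panel = c("HD", "MD")) {
  panel <- match.arg(panel)
  keep <- if (panel == "HD") rep(TRUE, nrow(map)) else map$on_md_panel
  map2 <- map[keep, , drop = FALSE]
  rownames(map2) <- NULL
  if (is.null(signals)) return(map2)
  list(map = map2, signals = subset_signal_snps(signals, which(keep)))
}
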