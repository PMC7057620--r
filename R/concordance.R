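#' Classify HD calls by overlap with MD calls
#'
#' For every CNV called from the high-density (HD) panel, looks for
#' calls from the medium-density (MD) panel in the same animal on the
#' same chromosome whose genomic position overlaps. Coordinates are
#' 1-based closed intervals, so the overlap of `[100,200]` and
#' `[150,400]` is 51 bp. Categories:
#' \describe{
#'   \item{direct}{identical `start_bp` and `end_bp` (strict reading of
#'     "the genomic position of both CNVs were the same").}
#'   \item{partial}{intervals intersect but are not identical.}
#'   \item{none}{no intersecting MD call.}
#' }
#' Copy-number state is deliberately not required to match: only
#' genomic position is compared. If several MD calls intersect one HD
#' call, the one with the largest overlap wins (ties to the leftmost
#' start) and the multiplicity is recorded.
#'
#' @param hd_calls,md_calls call data.frames from [call_cnvs()].
#' @param md_map the MD SNP map (rows = MD SNPs), used to count MD
#'   SNPs inside each HD call region.
#' @return data.frame with one row per HD call: the HD call columns
#'   prefixed `hd_`, the matched MD interval (or `NA`), `category`,
#'   `overlap_bp`, `n_md_matches` and `md_snps_in_region`.
#' @export
classify_overlaps <- function(hd_calls, md_calls, md_map = NULL) {
  n <- nrow(hd_calls)
  category <- character(n)
  overlap_bp <- integer(n)
  md_start <- md_end <- rep(NA_integer_, n)
  n_md <- integer(n)
  md_key <- paste(md_calls$animal_id, md_calls$chrom)
  md_by <- split(seq_len(nrow(md_calls)), md_key)
  for (i in seq_len(n)) {
    key <- paste(hd_calls$animal_id[i], hd_calls$chrom[i])
    cand <- md_by[[key]]
    if (is.null(cand)) { category[i] <- "none"; next }
    s <- md_calls$start_bp[cand]; e <- md_calls$end_bp[cand]
    ov <- pmin(hd_calls$end_bp[i], e) - pmax(hd_calls$start_bp[i], s) + 1L
    hit <- which(ov > 0)
    if (length(hit) == 0) { category[i] <- "none"; next }
    n_md[i] <- length(hit)
    best <- hit[order(-ov[hit], s[hit])][1]
    overlap_bp[i] <- ov[best]
    md_start[i] <- s[best]; md_end[i] <- e[best]
    direct <- s[best] == hd_calls$start_bp[i] && e[best] == hd_calls$end_bp[i]
    category[i] <- if (direct) "direct" else "partial"
  }
  out <- data.frame(
    animal_id = hd_calls$animal_id, chrom = hd_calls$chrom,
    hd_start_bp = hd_calls$start_bp, hd_end_bp = hd_calls$end_bp,
    hd_copy_number = hd_calls$copy_number, hd_n_snps = hd_calls$n_snps,
    md_start_bp = md_start, md_end_bp = md_end,
    category = category, overlap_bp = overlap_bp, n_md_matches = n_md,
    stringsAsFactors = FALSE
  )
  if (!is.null(md_map)) {
    out$md_snps_in_region <- vapply(seq_len(n), function(i) {
      md_snp_density(hd_calls$chrom[i], hd_calls$start_bp[i],
                     hd_calls$end_bp[i], md_map)
    }, integer(1))
  }
  out
}

#' Count MD SNPs inside a genomic region
#'
#' Binary-search count of MD SNPs with position in `[start_bp, end_bp]`
#' (closed interval) on the given chromosome. Regions with fewer than 3
#' MD SNPs can never yield an MD call, because a CNV must span at least
#' 3 SNPs.
#'
#' @param chrom,start_bp,end_bp the region.
#' @param md_map MD SNP map, sorted by chromosome and position.
#' @return integer count.
#' @export
md_snp_density <- function(chrom, start_bp, end_bp, md_map) {
  pos <- md_map$pos_bp[md_map$chrom == chrom]
  if (length(pos) == 0) return(0L)
  # findInterval on a sorted vector is a binary search
  hi <- findInterval(end_bp, pos)
  lo <- findInterval(start_bp - 1L, pos)
  as.integer(hi - lo)
}

#' Summarize cross-panel concordance (Table-1-style)
#'
#' Per overlap category: count, and first quartile / median / third
#' quartile of CNV length (kb, computed as `(end - start + 1)/1000`)
#' and of the number of HD SNPs per call. Quartiles use the
#' linear-interpolation convention (R quantile type 7). Also reports
#' the fraction of HD calls with no MD counterpart and the fraction
#' whose region holds fewer than 3 MD SNPs, and compares mean length
#' and mean population call frequency across categories by one-way
#' ANOVA (skipped when fewer than two categories have two or more
#' records).
#'
#' @param records output of [classify_overlaps()].
#' @param call_freq optional per-record population frequency of the HD
#'   call (number of animals sharing the call).
#' @return list with `by_category` (data.frame), `fraction_none`,
#'   `fraction_lt3_md_snps`, `anova_length_p`, `anova_freq_p`.
#' @export
summarize_concordance <- function(records, call_freq = NULL) {
  stopifnot(nrow(records) >= 1)
  records$length_kb <- (records$hd_end_bp - records$hd_start_bp + 1) / 1000
  cats <- c("direct", "partial", "none")
  q3 <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), type = 7,
                                    names = FALSE)
  rows <- lapply(cats, function(cg) {
    r <- records[records$category == cg, , drop = FALSE]
    if (nrow(r) == 0) {
      return(data.frame(category = cg, count = 0L,
                        q1_length_kb = NA, median_length_kb = NA,
                        q3_length_kb = NA, q1_n_snps = NA,
                        median_n_snps = NA, q3_n_snps = NA,
                        mean_freq = NA))
    }
    ql <- q3(r$length_kb); qs <- q3(r$hd_n_snps)
    mf <- if (is.null(call_freq)) NA_real_ else
      mean(call_freq[records$category == cg])
    data.frame(category = cg, count = nrow(r),
               q1_length_kb = ql[1], median_length_kb = ql[2],
               q3_length_kb = ql[3], q1_n_snps = qs[1],
               median_n_snps = qs[2], q3_n_snps = qs[3],
               mean_freq = mf)
  })
  by_cat <- do.call(rbind, rows)
  ok_cats <- by_cat$category[by_cat$count >= 2]
  test_p <- function(value) {
    sub <- records[records$category %in% ok_cats, , drop = FALSE]
    if (length(unique(sub$category)) < 2) return(NA_real_)
    stats::anova(stats::aov(value[records$category %in% ok_cats] ~
                              factor(sub$category)))[["Pr(>F)"]][1]
  }
  anova_length_p <- test_p(records$length_kb)
  anova_freq_p <- if (is.null(call_freq)) NA_real_ else test_p(call_freq)
  frac_lt3 <- if ("md_snps_in_region" %in% names(records)) {
    mean(records$md_snps_in_region < 3)
  } else NA_real_
  list(by_category = by_cat,
       fraction_none = mean(records$category == "none"),
       fraction_lt3_md_snps = frac_lt3,
       anova_length_p = anova_length_p,
       anova_freq_p = anova_freq_p)
}
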