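# Small in-code fixtures and independent oracles shared across tests.

# deterministic evenly spaced map (no randomness needed in most tests)
grid_map <- function(n = 60, chrom = 1, spacing = 10000, gc = NULL) {
  n_tot <- n * length(chrom)
  do.call(rbind, lapply(chrom, function(cc) {
    data.frame(
      snp_id = sprintf("s%d_%04d", cc, seq_len(n)),
      chrom = cc,
      pos_bp = seq(spacing, by = spacing, length.out = n),
      on_md_panel = TRUE,
      gc_frac = if (is.null(gc)) {
        0.45 + 0.1 * sin(seq_len(n) / 7)
      } else rep_len(gc, n),
      stringsAsFactors = FALSE
    )
  }))
}

# a small population with planted deletions, reused by several files
small_popsim <- function(seed = 42, n_loci = 2, allele_set = "del",
                         ld_mode = "perfect", n_chrom = 1, n_snp = 600) {
  map <- simulate_snp_map(n_chrom, n_snp, n_snp * 10000, seed = seed)
  ped <- simulate_pedigree(30, 3, 2, sire_pool = 3, seed = seed + 1)
  haps <- simulate_haplotypes(ped, map, seed = seed + 2)
  cnvs <- plant_cnv_loci(map, haps, n_loci = n_loci,
                         len_snps_range = c(10, 20),
                         freq_range = c(0.15, 0.35),
                         allele_set = allele_set, ld_mode = ld_mode,
                         seed = seed + 3)
  signals <- render_signals(haps, cnvs, map, seed = seed + 4)
  list(map = map, ped = ped, haps = haps, cnvs = cnvs, signals = signals)
}

# log-probability of one explicit state path under the HMM
path_logprob <- function(path, E, pos, params) {
  entry <- params$state_entry_prob
  L <- params$expected_cnv_length_bp
  lp <- log(entry[path[1] + 1]) + E[1, path[1] + 1]
  for (t in seq_along(path)[-1]) {
    rho <- 1 - exp(-(pos[t] - pos[t - 1]) / L)
    i <- path[t - 1]; j <- path[t]
    p <- if (i == j) 1 - rho * (1 - entry[i + 1]) else rho * entry[j + 1]
    lp <- lp + log(p) + E[t, j + 1]
  }
  lp
}

# brute-force best path log-probability by enumerating all 5^L paths
brute_force_best <- function(E, pos, params) {
  L <- nrow(E)
  paths <- as.matrix(expand.grid(rep(list(0:4), L)))
  entry <- params$state_entry_prob
  Lscale <- params$expected_cnv_length_bp
  lp <- log(entry[paths[, 1] + 1]) + E[cbind(1, paths[, 1] + 1)]
  for (t in 2:L) {
    rho <- 1 - exp(-(pos[t] - pos[t - 1]) / Lscale)
    i <- paths[, t - 1]; j <- paths[, t]
    ptrans <- ifelse(i == j, 1 - rho * (1 - entry[i + 1]),
                     rho * entry[j + 1])
    lp <- lp + log(ptrans) + E[cbind(t, j + 1)]
  }
  max(lp)
}

# exhaustive pair-counting adjusted Rand index (all C(n,2) pairs)
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  n11 <- sum(same_a & same_b); n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b); n01 <- sum(!same_a & same_b)
  npairs <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / npairs
  maxi <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxi == expected) return(0)
  (n11 - expected) / (maxi - expected)
}

# reciprocal-overlap recovery of planted loci by a call set
recovery_rate <- function(calls, cnvs, min_recip = 0.8, min_len_snps = 10) {
  loci <- cnvs$loci[cnvs$loci$n_snps >= min_len_snps, , drop = FALSE]
  hits <- integer(0)
  for (i in seq_len(nrow(loci))) {
    l <- loci[i, ]
    carriers <- cnvs$truth$animal_id[cnvs$truth$locus_id == l$locus_id &
                                       cnvs$truth$true_cn != 2]
    for (a in carriers) {
      cc <- calls[calls$animal_id == a & calls$chrom == l$chrom, ,
                  drop = FALSE]
      ok <- FALSE
      if (nrow(cc) > 0) {
        ov <- pmin(cc$end_bp, l$end_bp) - pmax(cc$start_bp, l$start_bp) + 1
        len_call <- cc$end_bp - cc$start_bp + 1
        len_locus <- l$end_bp - l$start_bp + 1
        ok <- any(ov / pmax(len_call, len_locus) >= min_recip)
      }
      hits <- c(hits, ok)
    }
  }
  mean(hits)
}

# merge several plant_cnv_loci results over disjoint chromosomes into
# one object (used to mix LD modes within one rendered signal set)
merge_cnvs <- function(...) {
  parts <- list(...)
  for (i in seq_along(parts)) {
    pref <- sprintf("m%d_", i)
    parts[[i]]$loci$locus_id <- paste0(pref, parts[[i]]$loci$locus_id)
    parts[[i]]$truth$locus_id <- paste0(pref, parts[[i]]$truth$locus_id)
  }
  list(loci = do.call(rbind, lapply(parts, `[[`, "loci")),
       truth = do.call(rbind, lapply(parts, `[[`, "truth")),
       hap_alleles = do.call(cbind, lapply(parts, `[[`, "hap_alleles")))
}
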