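test_that("pedigree structure: founders, ordering, determinism", {
  # founders only
  p0 <- simulate_pedigree(2, 0, seed = 1)
  expect_equal(nrow(p0), 2)
  expect_true(all(is.na(p0$sire_id)) && all(is.na(p0$dam_id)))

  # every non-founder has both parents with smaller birth order
  ped <- simulate_pedigree(10, 3, 2, sire_pool = 2, seed = 7)
  bo <- setNames(ped$birth_order, ped$animal_id)
  nf <- ped[!is.na(ped$sire_id), ]
  expect_true(all(bo[nf$sire_id] < nf$birth_order))
  expect_true(all(bo[nf$dam_id] < nf$birth_order))
  expect_equal(sort(ped$birth_order), seq_len(nrow(ped)))

  # same seed reproduces byte-identical pedigree
  expect_identical(ped, simulate_pedigree(10, 3, 2, sire_pool = 2, seed = 7))
  expect_error(simulate_pedigree(1, 1), "founders")
})

test_that("haplotypes: no-recombination limit, MAF target, determinism", {
  map <- grid_map(n = 200)
  ped <- simulate_pedigree(6, 1, 2, seed = 3)
  h0 <- simulate_haplotypes(ped, map, recomb_rate_per_mb = 0, seed = 5)
  # with no recombination every child haplotype equals one parental
  # haplotype over the whole chromosome
  kids <- which(!is.na(ped$sire_id))
  for (a in kids) {
    sire_rows <- 2 * match(ped$sire_id[a], ped$animal_id) - c(1, 0)
    kid_hap <- h0$alleles[2 * a - 1, ]
    expect_true(identical(kid_hap, h0$alleles[sire_rows[1], ]) ||
                  identical(kid_hap, h0$alleles[sire_rows[2], ]))
  }

  # a point-mass 0.5 spectrum gives mean realized founder MAF near 0.5
  map2 <- grid_map(n = 1500)
  ped2 <- simulate_pedigree(30, 0, seed = 2)
  h2 <- simulate_haplotypes(ped2, map2,
                            maf_spectrum = list(type = "point", value = 0.5),
                            ld_rho = 0, seed = 6)
  maf <- pmin(h2$freq_b, 1 - h2$freq_b)
  expect_lt(abs(mean(maf) - 0.5), 0.06)

  expect_identical(h0, simulate_haplotypes(ped, map, recomb_rate_per_mb = 0,
                                           seed = 5))
  expect_error(simulate_haplotypes(ped, map, recomb_rate_per_mb = -1),
               "recomb")
})

test_that("planted loci: copy-number arithmetic and LD modes", {
  sim <- small_popsim(seed = 11, n_loci = 3)
  # truth copy number always equals the sum of haplotype contributions
  contrib <- c(N = 1L, D = 0L, P = 2L)
  for (li in seq_len(nrow(sim$cnvs$loci))) {
    al <- sim$cnvs$hap_alleles[, li]
    n_hap <- length(al)
    cn <- contrib[al[seq(1, n_hap, 2)]] + contrib[al[seq(2, n_hap, 2)]]
    tr <- sim$cnvs$truth[sim$cnvs$truth$locus_id ==
                           sim$cnvs$loci$locus_id[li], ]
    expect_equal(unname(cn), tr$true_cn)
  }
  # every locus spans at least 3 HD SNPs and carriers are in range
  expect_true(all(sim$cnvs$loci$n_snps >= 3))
  n_animal <- nrow(sim$ped)
  expect_true(all(sim$cnvs$loci$n_carriers >= 0.15 * n_animal - 1))

  # homozygous duplication means copy number 4
  dup <- small_popsim(seed = 12, n_loci = 2, allele_set = "dup")
  al <- dup$cnvs$hap_alleles[, 1]
  both_p <- which(al[seq(1, length(al), 2)] == "P" &
                    al[seq(2, length(al), 2)] == "P")
  tr <- dup$cnvs$truth[dup$cnvs$truth$locus_id == dup$cnvs$loci$locus_id[1], ]
  if (length(both_p) > 0) expect_true(all(tr$true_cn[both_p] == 4))

  # perfect LD: carrier haplotypes are exactly one founder lineage
  l1 <- sim$cnvs$loci[1, ]
  mid <- l1$start_snp + (l1$n_snps %/% 2)
  org <- sim$haps$origin[, mid]
  carrier <- sim$cnvs$hap_alleles[, 1] != "N"
  expect_equal(length(unique(org[carrier])), 1)
  expect_false(unique(org[carrier]) %in% org[!carrier])
})

test_that("independent-LD carrier status is uncorrelated with flanking SNPs", {
  map <- grid_map(n = 300)
  ped <- simulate_pedigree(500, 0, seed = 21)  # 500 unrelated animals
  haps <- simulate_haplotypes(ped, map, ld_rho = 0.9, seed = 22)
  cnvs <- plant_cnv_loci(map, haps, n_loci = 1,
                         len_snps_range = c(10, 10),
                         freq_range = c(0.3, 0.5),
                         ld_mode = "independent", seed = 23)
  l <- cnvs$loci[1, ]
  tr <- cnvs$truth[cnvs$truth$locus_id == l$locus_id, ]
  carrier <- as.integer(tr$true_cn != 2)
  flank <- c(max(1, l$start_snp - 10):(l$start_snp - 1),
             (l$end_snp + 1):min(nrow(map), l$end_snp + 10))
  for (s in flank) {
    dosage <- haps$alleles[seq(1, nrow(haps$alleles), 2), s] +
      haps$alleles[seq(2, nrow(haps$alleles), 2), s]
    if (stats::sd(dosage) == 0) next
    expect_lt(abs(stats::cor(carrier, dosage)), 0.2)
  }
})

test_that("signal model: cluster means, GC wave, CLT bound, cn=0 BAF", {
  map <- grid_map(n = 400)
  ped <- simulate_pedigree(40, 0, seed = 31)
  haps <- simulate_haplotypes(ped, map, seed = 32)
  # near-noiseless signals hit the defining cluster positions
  sig0 <- render_signals(haps, NULL, map,
                         state_lrr_sds = rep(1e-9, 5), baf_sd = 1e-9,
                         gc_wave_coef = 0, seed = 33)
  het <- haps$alleles[seq(1, 80, 2), ] + haps$alleles[seq(2, 80, 2), ] == 1
  expect_true(all(abs(sig0$baf[het] - 0.5) < 1e-6))
  expect_true(all(abs(sig0$lrr) < 1e-6))  # state 2 reference intensity is 0

  # deletion segment mean LRR within the CLT bound
  cnvs <- plant_cnv_loci(map, haps, n_loci = 1, len_snps_range = c(10, 10),
                         freq_range = c(0.2, 0.6), ld_mode = "independent",
                         seed = 34)
  sig1 <- render_signals(haps, cnvs, map,
                         state_lrr_sds = rep(0.2, 5), baf_sd = 0.03,
                         gc_wave_coef = 0, seed = 35)
  l <- cnvs$loci[1, ]
  tr <- cnvs$truth[cnvs$truth$locus_id == l$locus_id, ]
  hemi <- which(tr$true_cn == 1)
  # pooled CLT bound over all hemizygous segment SNPs
  pooled <- as.vector(sig1$lrr[hemi, l$start_snp:l$end_snp])
  expect_lt(abs(mean(pooled) - (-0.66)), 3 * 0.2 / sqrt(length(pooled)))

  # homozygous-deletion BAF is uniform on [0,1]
  map0 <- grid_map(n = 600)
  ped0 <- simulate_pedigree(300, 0, seed = 38)
  haps0 <- simulate_haplotypes(ped0, map0, seed = 39)
  cnvs0 <- plant_cnv_loci(map0, haps0, n_loci = 4,
                          len_snps_range = c(40, 40),
                          freq_range = c(0.6, 0.9), ld_mode = "independent",
                          seed = 36)
  sig2 <- render_signals(haps0, cnvs0, map0, seed = 37)
  baf0 <- sig2$baf[sig2$cn == 0]
  expect_gt(length(baf0), 5000)
  expect_gt(stats::ks.test(baf0, "punif")$p.value, 0.01)
})

test_that("defect injection matches configured rates and is reproducible", {
  map <- grid_map(n = 1000)
  ped <- simulate_pedigree(50, 1, 2, seed = 41)
  haps <- simulate_haplotypes(ped, map, seed = 42)
  sig <- render_signals(haps, NULL, map, seed = 43)

  expect_identical(inject_defects(sig, ped, 0, 0), sig)

  sig_m <- inject_defects(sig, ped, missing_rate = 0.06, seed = 44)
  expect_lt(abs(mean(is.na(sig_m$geno)) - 0.06), 0.01)
  expect_identical(sig_m, inject_defects(sig, ped, missing_rate = 0.06,
                                         seed = 44))
})

test_that("SNP QC removes exactly the failing SNPs", {
  map <- grid_map(n = 4)
  ped <- simulate_pedigree(2, 1, offspring_per_mating = 50, sire_pool = 1,
                           seed = 51)
  n <- nrow(ped)  # 2 founders + 50 offspring
  geno <- matrix(1L, n, 4)
  # SNP 1: call rate 0.94 -> removed; SNP 2: exactly 0.95 -> kept
  geno[seq_len(ceiling(0.061 * n)), 1] <- NA_integer_
  geno[seq_len(floor(0.05 * n)), 2] <- NA_integer_
  # SNP 3: opposing homozygotes in 3% of the 100 parent-progeny pairs
  pairs <- parent_progeny_pairs(ped)
  sig <- structure(list(lrr = matrix(0, n, 4), baf = matrix(0.5, n, 4),
                        geno = geno, cn = NULL,
                        animal_ids = ped$animal_id,
                        snp_ids = map$snp_id), class = "signal_set")
  row_of <- setNames(seq_len(n), ped$animal_id)
  bad <- pairs[1:3, ]  # 3 of 100 pairs -> 3% > 2%
  sig$geno[row_of[bad$parent_id], 3] <- 0L
  sig$geno[row_of[bad$child_id], 3] <- 2L
  res <- filter_snps(sig, map, ped)
  expect_setequal(res$removed$snp_id, map$snp_id[c(1, 3)])
  expect_equal(res$map$snp_id, map$snp_id[c(2, 4)])
  expect_equal(ncol(res$signals$geno), 2)

  # zero injected defects -> zero SNPs removed
  clean <- structure(list(lrr = matrix(0, n, 4), baf = matrix(0.5, n, 4),
                          geno = matrix(1L, n, 4), cn = NULL,
                          animal_ids = ped$animal_id,
                          snp_ids = map$snp_id), class = "signal_set")
  expect_equal(nrow(filter_snps(clean, map, ped)$removed), 0)
})

test_that("MD subset selection: explicit list, exact thinning, identity", {
  map <- grid_map(n = 100)
  ids <- map$snp_id[c(3, 10, 55, 70, 99)]
  m1 <- make_md_subset(map, ids)
  expect_setequal(map$snp_id[m1$on_md_panel], ids)
  expect_error(make_md_subset(map, c(ids, "nope")), "nope")

  big <- grid_map(n = 10000)
  m2 <- make_md_subset(big, 0.064, seed = 9)
  expect_equal(sum(m2$on_md_panel), 640)

  m3 <- make_md_subset(map, 1.0)
  expect_true(all(m3$on_md_panel))
})
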