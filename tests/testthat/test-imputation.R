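mk_hd <- function(animal, s_idx, e_idx, cn = 1, caller = "penn_like",
                  bf = NA_real_) {
  data.frame(animal_id = animal, chrom = 1L,
             start_bp = s_idx * 1000L, end_bp = e_idx * 1000L,
             start_snp_index = s_idx, end_snp_index = e_idx,
             copy_number = cn, n_snps = e_idx - s_idx + 1L,
             caller = caller, bayes_factor = bf, stringsAsFactors = FALSE)
}

test_that("consensus matching honours the one-SNP endpoint tolerance", {
  penn <- mk_hd("a1", 10, 20)
  # identical calls match
  expect_equal(nrow(consensus_calls(penn, mk_hd("a1", 10, 20))), 1)
  # one-SNP end difference matches; the union interval is kept
  cons <- consensus_calls(penn, mk_hd("a1", 10, 21))
  expect_equal(nrow(cons), 1)
  expect_equal(cons$end_snp_index, 21)
  expect_equal(cons$start_snp_index, 10)
  # two-SNP difference does not match
  expect_equal(nrow(consensus_calls(penn, mk_hd("a1", 10, 22))), 0)
  # copy numbers must agree
  expect_equal(nrow(consensus_calls(penn, mk_hd("a1", 10, 20, cn = 3))), 0)
  # different animal never matches
  expect_equal(nrow(consensus_calls(penn, mk_hd("a2", 10, 20))), 0)

  # symmetric in its two inputs and each call used at most once
  p2 <- rbind(mk_hd("a1", 10, 20), mk_hd("a1", 30, 40))
  q2 <- rbind(mk_hd("a1", 30, 41), mk_hd("a1", 9, 20))
  c12 <- consensus_calls(p2, q2)
  c21 <- consensus_calls(q2, p2)
  expect_equal(nrow(c12), 2)
  expect_equal(c12[order(c12$start_snp_index),
                   c("start_snp_index", "end_snp_index")],
               c21[order(c21$start_snp_index),
                   c("start_snp_index", "end_snp_index")])
})

test_that("locus grouping counts carriers and applies the threshold", {
  cons <- do.call(rbind, lapply(1:40, function(i) mk_hd(paste0("a", i), 5, 9)))
  other <- do.call(rbind, lapply(1:29, function(i)
    mk_hd(paste0("b", i), 50, 60)))
  sel <- group_loci_and_select(rbind(cons, other), min_carriers = 30)
  expect_equal(nrow(sel$loci), 1)
  expect_equal(sel$loci$n_carriers, 40)
  # exactly at the threshold is selected
  sel30 <- group_loci_and_select(cons[1:30, ], min_carriers = 30)
  expect_equal(nrow(sel30$loci), 1)
  # one below is not
  expect_warning(sel29 <- group_loci_and_select(cons[1:29, ],
                                                min_carriers = 30),
                 "no locus")
  expect_equal(nrow(sel29$loci), 0)

  # coordinate jitter within bp_tol groups into one locus
  jit <- cons
  jit$start_bp[1:10] <- jit$start_bp[1:10] + 800
  selj <- group_loci_and_select(jit, min_carriers = 35, bp_tol = 1000)
  expect_equal(nrow(selj$loci), 1)
})

test_that("copy-number encoding round-trips and split modes collapse", {
  for (cn in 0:4) {
    expect_equal(allele_pair_to_cn(cn_to_allele_pair(cn)), cn)
  }
  expect_equal(cn_to_allele_pair(1), c("N", "D"))
  expect_equal(cn_to_allele_pair(4), c("P", "P"))
  expect_equal(cn_to_allele_pair(3, "biallelic_del"), c("N", "N"))
  expect_equal(cn_to_allele_pair(4, "biallelic_dup"), c("P", "P"))
  expect_equal(cn_to_allele_pair(0, "biallelic_dup"), c("N", "N"))
  expect_error(cn_to_allele_pair(5), "0..4")

  locus <- data.frame(locus_id = "L", chrom = 1, start_bp = 101,
                      end_bp = 200)
  m <- encode_marker(locus, c(a = 1L, b = 4L, c = 2L))
  expect_equal(m$midpoint_bp, 150)  # floor((101 + 200)/2)
  expect_equal(unname(m$genotypes["b", ]), c("P", "P"))
})

test_that("flank extraction: k per side, boundaries, linear-scan oracle", {
  map <- grid_map(n = 100, chrom = 1:2)
  mid <- 505000  # between SNPs 50 and 51
  fl <- extract_flanks(map, 1, mid, 10)
  expect_equal(fl$n_left, 10)
  expect_equal(fl$n_right, 10)
  expect_equal(length(fl$idx), 20)
  # oracle: the 2k nearest positions excluding the midpoint itself
  pos <- map$pos_bp[map$chrom == 1]
  left <- which(pos < mid); right <- which(pos > mid)
  expect_equal(fl$idx, c(utils::tail(left, 10), utils::head(right, 10)))

  # chromosome start truncates the left side
  fl2 <- extract_flanks(map, 1, 35000, 10)
  expect_equal(fl2$n_left, 3)
  expect_equal(fl2$n_right, 10)
  # midpoint before the first SNP: task must be skipped
  expect_warning(fl3 <- extract_flanks(map, 1, 500, 10), "skipped")
  expect_null(fl3)
})

test_that("age split: arithmetic, oldest in reference, determinism", {
  ped <- simulate_pedigree(10, 0, seed = 1)
  sp <- split_reference_validation(ped)
  expect_equal(length(sp$reference), 8)
  expect_equal(length(sp$validation), 2)
  oldest <- ped$animal_id[which.min(ped$birth_order)]
  expect_true(oldest %in% sp$reference)
  expect_identical(sp, split_reference_validation(ped))
  expect_error(split_reference_validation(simulate_pedigree(4, 0)), "at least 5")
})

test_that("single-template reference copies its marker allele everywhere", {
  ref_flank <- matrix(c(0L, 1L, 0L, 1L), 1, 4)
  val <- rbind(c(0L, 1L, 0L, 1L), c(1L, 0L, 1L, 0L))
  for (m in c("hmm", "window")) {
    expect_message(
      out <- impute_marker(ref_flank, "D", val, 2, method = m),
      "monomorphic")
    expect_equal(out, c("D", "D"))
  }
})

test_that("haplotype-copying imputer recovers a tagged allele and both
           presets agree on clean data", {
  set.seed(7)
  H <- 40; P <- 21; n_left <- 10
  base <- matrix(rbinom(H * P, 1, 0.5), H, P)
  carrier <- rep(c(TRUE, FALSE), length.out = H)
  # carriers share a distinctive local haplotype around the marker
  sig_cols <- (n_left - 3):(n_left + 4)
  base[carrier, sig_cols] <- rep(c(1L, 1L, 0L, 1L, 0L, 0L, 1L, 1L),
                                 each = sum(carrier))
  ref_marker <- ifelse(carrier, "D", "N")
  val <- base[c(3, 4, 7, 12), ]
  truth <- ref_marker[c(3, 4, 7, 12)]
  for (m in c("hmm", "window")) {
    expect_equal(impute_marker(base, ref_marker, val, n_left, method = m),
                 truth)
  }
})

test_that("end-to-end imputation: perfect LD recovers, split modes
           agree on deletion-only loci", {
  sim <- small_popsim(seed = 91, n_loci = 2, n_snp = 900)
  penn <- call_cnvs(sim$signals, sim$map, "HD", "penn_like")
  quanti <- call_cnvs(sim$signals, sim$map, "HD", "quanti_like")
  cons <- consensus_calls(penn, quanti)
  res <- run_imputation_experiment(cons, sim$ped, sim$map, sim$haps,
                                   sim$cnvs, flank_ks = c(10, 25),
                                   min_carriers = 15, bp_tol = 5e4)
  expect_gt(nrow(res), 0)
  # per-animal called state 2 dominates the validation sets
  expect_gt(mean(res$called_cn == 2), 0.5)
  acc <- imputation_accuracy(res)
  del <- acc[acc$called_state %in% c(0, 1), ]
  nrm <- acc[acc$called_state == 2, ]
  expect_gt(mean(del$accuracy), 0.9)
  expect_gt(mean(nrm$accuracy), 0.9)

  # deletion-only locus: the bi-allelic deletion run reproduces the
  # tri-allelic per-state accuracies, and the duplication run sees
  # nothing but normals
  res_del <- run_imputation_experiment(cons, sim$ped, sim$map, sim$haps,
                                       sim$cnvs, flank_ks = 10,
                                       mode = "biallelic_del",
                                       min_carriers = 15, bp_tol = 5e4)
  res_tri <- res[res$flank_k == 10, ]
  acc_del <- imputation_accuracy(res_del)
  acc_tri <- imputation_accuracy(res_tri)
  key <- function(d) paste(d$locus_id, d$called_state)
  shared <- intersect(key(acc_del), key(acc_tri))
  expect_gt(length(shared), 0)
  expect_equal(acc_del$accuracy[match(shared, key(acc_del))],
               acc_tri$accuracy[match(shared, key(acc_tri))])

  res_dup <- run_imputation_experiment(cons, sim$ped, sim$map, sim$haps,
                                       sim$cnvs, flank_ks = 10,
                                       mode = "biallelic_dup",
                                       min_carriers = 15, bp_tol = 5e4)
  expect_true(all(res_dup$called_cn == 2))
})

test_that("empty selections degrade gracefully", {
  sim <- small_popsim(seed = 95, n_loci = 1, n_snp = 400)
  penn <- call_cnvs(sim$signals, sim$map, "HD", "penn_like")
  quanti <- call_cnvs(sim$signals, sim$map, "HD", "quanti_like")
  cons <- consensus_calls(penn, quanti)
  expect_warning(
    res <- run_imputation_experiment(cons, sim$ped, sim$map, sim$haps,
                                     sim$cnvs, flank_ks = 10,
                                     min_carriers = 10000),
    "carriers")
  expect_equal(nrow(res), 0)
})
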