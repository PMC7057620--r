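#' Default configuration of the end-to-end demonstration run
#'
#' Desk-scale study conditions: one breed of ~300 animals (75
#' founders, three offspring generations under a 4-sire popular-sire
#' scheme), 3 autosomes of 5,000 HD SNPs
#' each, an MD subset at the ~6.4% nested-panel fraction, 12 planted
#' CNV loci of 10-30 SNPs at 12-30% carrier frequency in perfect LD
#' with their flanking haplotypes, and the full imputation design
#' (consensus calling, >= 30 carriers, midpoint tri-allelic encoding,
#' flank sizes 10..500, oldest-80% reference split).
#'
#' @param seed root seed; every stage derives its own stream from it.
#' @return nested configuration list.
#' @export
default_run_config <- function(seed = 1) {
  list(
    seed = seed,
    breeds = list(list(name = "breedA", n_founders = 75,
                       n_generations = 3, offspring_per_mating = 2,
                       sire_pool = 4)),
    map = list(n_chrom = 3, snps_per_chrom = 5000, chrom_length_bp = 5e7),
    md_fraction = 45677 / 713162,
    haplotypes = list(recomb_rate_per_mb = 0.01, ld_rho = 0.95,
                      maf_spectrum = list(type = "uniform",
                                          min = 0.05, max = 0.5)),
    loci = list(n_loci = 12, len_snps_range = c(10, 30),
                freq_range = c(0.12, 0.30), allele_set = "mixed",
                ld_mode = "perfect"),
    signals = list(state_lrr_means = c(-3.5, -0.66, 0, 0.4, 0.68),
                   state_lrr_sds = c(1.3, 0.28, 0.21, 0.21, 0.26),
                   baf_sd = 0.05, gc_wave_coef = 0.4),
    defects = list(missing_rate = 0.02, mendel_error_rate = 0.05,
                   mendel_snp_frac = 0.005),
    qc = list(min_call_rate = 0.95, max_mendel_pair_frac = 0.02),
    calling = list(min_snps = 3),
    consensus_tolerance = 1,
    min_carriers = 30,
    locus_bp_tol = 1e5,
    flank_ks = c(10, 25, 50, 100, 250, 500),
    imputer = list(method = "hmm", mode = "triallelic",
                   switch_rate = 0.01, error_rate = 0.002),
    frac_reference = 0.8
  )
}

# named-substream seed derivation: adding a stage never perturbs the
# randomness of earlier stages
stage_seed <- function(root_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(root_seed) * 10007 + h) %% 2147483647)
}

# re-anchor planted-locus SNP indices onto a (QC-filtered) map that
# carries hap_col, dropping loci reduced below 3 SNPs; hap_alleles
# columns and truth rows are kept aligned with the surviving loci
remap_loci <- function(cnvs, map) {
  keep <- logical(nrow(cnvs$loci))
  for (i in seq_len(nrow(cnvs$loci))) {
    l <- cnvs$loci[i, ]
    inside <- which(map$chrom == l$chrom & map$pos_bp >= l$start_bp &
                      map$pos_bp <= l$end_bp)
    if (length(inside) >= 3) {
      cnvs$loci$start_snp[i] <- inside[1]
      cnvs$loci$end_snp[i] <- inside[length(inside)]
      cnvs$loci$n_snps[i] <- length(inside)
      # the locus's observable extent is bounded by the surviving SNPs
      cnvs$loci$start_bp[i] <- map$pos_bp[inside[1]]
      cnvs$loci$end_bp[i] <- map$pos_bp[inside[length(inside)]]
      keep[i] <- TRUE
    }
  }
  cnvs$loci <- cnvs$loci[keep, , drop = FALSE]
  cnvs$hap_alleles <- cnvs$hap_alleles[, keep, drop = FALSE]
  cnvs$truth <- cnvs$truth[cnvs$truth$locus_id %in% cnvs$loci$locus_id, ,
                           drop = FALSE]
  cnvs
}

#' Run the full simulate - call - compare - impute - evaluate pipeline
#'
#' Executes every stage from one configuration with per-stage derived
#' seeds, optionally writes all stage tables plus a checksum manifest
#' to `out_dir`, and returns the in-memory results. Re-running with an
#' identical configuration reproduces identical outputs and manifest.
#'
#' @param config configuration list, see [default_run_config()].
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @return list with elements `ped`, `map` (post-QC, with `hap_col`),
#'   `haps`, `cnvs`, `signals` (post-QC), `calls_hd_penn`,
#'   `calls_hd_quanti`, `calls_md_penn`, `overlaps`, `concordance`,
#'   `consensus`, `imputation`, `accuracy`, `reports`, `ari`,
#'   `bf_comparison`, `correlations`, `config`, and `manifest` (when
#'   `out_dir` is given).
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  root <- config$seed

  ## simulate ---------------------------------------------------------
  map <- simulate_snp_map(config$map$n_chrom, config$map$snps_per_chrom,
                          config$map$chrom_length_bp,
                          seed = stage_seed(root, "map"))
  map <- make_md_subset(map, config$md_fraction,
                        seed = stage_seed(root, "md_subset"))
  map$hap_col <- seq_len(nrow(map))

  peds <- list(); hapss <- list(); cnvss <- list(); sigs <- list()
  for (bi in seq_along(config$breeds)) {
    b <- config$breeds[[bi]]
    ped <- simulate_pedigree(b$n_founders, b$n_generations,
                             b$offspring_per_mating,
                             sire_pool = b$sire_pool %||% 4,
                             breed = b$name,
                             seed = stage_seed(root, paste0("ped_", b$name)))
    haps <- simulate_haplotypes(
      ped, map, config$haplotypes$recomb_rate_per_mb,
      config$haplotypes$maf_spectrum, config$haplotypes$ld_rho,
      seed = stage_seed(root, paste0("haps_", b$name)))
    cnvs <- plant_cnv_loci(
      map, haps, config$loci$n_loci, config$loci$len_snps_range,
      config$loci$freq_range, config$loci$allele_set,
      config$loci$ld_mode,
      seed = stage_seed(root, paste0("loci_", b$name)))
    signals <- render_signals(
      haps, cnvs, map, config$signals$state_lrr_means,
      config$signals$state_lrr_sds, config$signals$baf_sd,
      gc_wave_coef = config$signals$gc_wave_coef,
      seed = stage_seed(root, paste0("signals_", b$name)))
    signals <- inject_defects(
      signals, ped, config$defects$missing_rate,
      config$defects$mendel_error_rate, config$defects$mendel_snp_frac,
      seed = stage_seed(root, paste0("defects_", b$name)))
    peds[[bi]] <- ped; hapss[[b$name]] <- haps
    cnvss[[b$name]] <- cnvs; sigs[[b$name]] <- signals
  }
  ped_all <- do.call(rbind, peds)

  ## QC (joint across breeds so every breed shares one edited map) ----
  geno_all <- do.call(rbind, lapply(sigs, function(s) s$geno))
  joint <- structure(list(lrr = NULL, baf = NULL, geno = geno_all,
                          cn = NULL,
                          animal_ids = unlist(lapply(sigs, function(s)
                            s$animal_ids), use.names = FALSE),
                          snp_ids = map$snp_id), class = "signal_set")
  call_rate <- colMeans(!is.na(geno_all))
  qc <- filter_snps(joint, map, ped_all, config$qc$min_call_rate,
                    config$qc$max_mendel_pair_frac)
  map_qc <- qc$map
  keep_cols <- match(map_qc$snp_id, map$snp_id)
  sigs <- lapply(sigs, subset_signal_snps, cols = keep_cols)
  cnvss <- lapply(cnvss, remap_loci, map = map_qc)

  ## call -------------------------------------------------------------
  breed_names <- vapply(config$breeds, `[[`, "", "name")
  res_breed <- list()
  for (bn in breed_names) {
    pfb <- hapss[[bn]]$freq_b[map_qc$hap_col]
    hd_penn <- call_cnvs(sigs[[bn]], map_qc, "HD", "penn_like",
                         min_snps = config$calling$min_snps, pfb = pfb)
    hd_quanti <- call_cnvs(sigs[[bn]], map_qc, "HD", "quanti_like",
                           min_snps = config$calling$min_snps, pfb = pfb)
    md_penn <- call_cnvs(sigs[[bn]], map_qc, "MD", "penn_like",
                         min_snps = config$calling$min_snps,
                         pfb = pfb[map_qc$on_md_panel])
    res_breed[[bn]] <- list(hd_penn = hd_penn, hd_quanti = hd_quanti,
                            md_penn = md_penn)
  }
  calls_hd_penn <- do.call(rbind, lapply(res_breed, `[[`, "hd_penn"))
  calls_hd_quanti <- do.call(rbind, lapply(res_breed, `[[`, "hd_quanti"))
  calls_md_penn <- do.call(rbind, lapply(res_breed, `[[`, "md_penn"))

  ## cross-panel concordance ------------------------------------------
  md_map <- restrict_panel(map_qc, panel = "MD")
  overlaps <- classify_overlaps(calls_hd_penn, calls_md_penn, md_map)
  hd_key <- paste(calls_hd_penn$chrom, calls_hd_penn$start_bp,
                  calls_hd_penn$end_bp)
  call_freq <- as.integer(ave(seq_along(hd_key), hd_key, FUN = length))
  concordance <- summarize_concordance(overlaps, call_freq)

  ## consensus + imputation -------------------------------------------
  consensus <- list(); imputation <- list()
  for (bn in breed_names) {
    cons <- consensus_calls(res_breed[[bn]]$hd_penn,
                            res_breed[[bn]]$hd_quanti,
                            config$consensus_tolerance)
    consensus[[bn]] <- cons
    ped_b <- ped_all[ped_all$breed == bn, , drop = FALSE]
    imputation[[bn]] <- run_imputation_experiment(
      cons, ped_b, map_qc, hapss[[bn]], cnvss[[bn]],
      flank_ks = config$flank_ks, mode = config$imputer$mode,
      method = config$imputer$method,
      min_carriers = config$min_carriers,
      frac_reference = config$frac_reference,
      bp_tol = config$locus_bp_tol %||% 0,
      switch_rate = config$imputer$switch_rate,
      error_rate = config$imputer$error_rate)
  }
  consensus_all <- do.call(rbind, consensus)
  imputation_all <- do.call(rbind, imputation)
  rownames(imputation_all) <- NULL

  ## evaluate ----------------------------------------------------------
  accuracy <- imputation_accuracy(imputation_all)
  ari <- data.frame(breed = character(0), ari = numeric(0))
  reports <- NULL; bf_cmp <- NULL; correlations <- NULL
  if (nrow(imputation_all) > 0) {
    ari <- do.call(rbind, lapply(unique(imputation_all$breed), function(b) {
      d <- imputation_all[imputation_all$breed == b, ]
      a <- tryCatch(adjusted_rand_index(d$called_cn, d$imputed_cn),
                    warning = function(w) 0)
      data.frame(breed = b, ari = a, stringsAsFactors = FALSE)
    }))
    reports <- render_reports(accuracy)
    bf_cmp <- compare_bayes_factors(imputation_all)
    correlations <- list(
      freq = tryCatch(pearson_fisher_ci(accuracy$population_frequency,
                                        accuracy$accuracy),
                      error = function(e) NULL),
      length = tryCatch(pearson_fisher_ci(accuracy$length_kb,
                                          accuracy$accuracy),
                        error = function(e) NULL))
  }

  out <- list(ped = ped_all, map = map_qc, haps = hapss, cnvs = cnvss,
              signals = sigs, calls_hd_penn = calls_hd_penn,
              calls_hd_quanti = calls_hd_quanti,
              calls_md_penn = calls_md_penn, overlaps = overlaps,
              concordance = concordance, consensus = consensus_all,
              imputation = imputation_all, accuracy = accuracy,
              reports = reports, ari = ari, bf_comparison = bf_cmp,
              correlations = correlations, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(ped_all, file.path(out_dir, "pedigree.tsv"))
    write_tsv(map_qc, file.path(out_dir, "map_qc.tsv"))
    for (bn in breed_names) {
      write_tsv(cnvss[[bn]]$loci,
                file.path(out_dir, paste0("planted_loci_", bn, ".tsv")))
      write_tsv(cnvss[[bn]]$truth,
                file.path(out_dir, paste0("truth_", bn, ".tsv")))
    }
    write_tsv(calls_hd_penn, file.path(out_dir, "calls_hd_penn.tsv"))
    write_tsv(calls_hd_quanti, file.path(out_dir, "calls_hd_quanti.tsv"))
    write_tsv(calls_md_penn, file.path(out_dir, "calls_md_penn.tsv"))
    write_tsv(calls_to_bed(calls_hd_penn),
              file.path(out_dir, "calls_hd_penn.bed"))
    write_tsv(overlaps, file.path(out_dir, "overlaps.tsv"))
    write_tsv(concordance$by_category,
              file.path(out_dir, "concordance_by_category.tsv"))
    write_tsv(consensus_all, file.path(out_dir, "consensus.tsv"))
    write_tsv(imputation_all, file.path(out_dir, "imputation.tsv"))
    write_tsv(accuracy, file.path(out_dir, "accuracy_records.tsv"))
    write_tsv(ari, file.path(out_dir, "ari.tsv"))
    if (!is.null(reports)) {
      write_tsv(reports$by_state_breed,
                file.path(out_dir, "accuracy_by_state_breed.tsv"))
      write_tsv(reports$high_accuracy,
                file.path(out_dir, "high_accuracy_loci.tsv"))
      write_tsv(reports$scatter_frequency,
                file.path(out_dir, "scatter_accuracy_vs_frequency.tsv"))
      write_tsv(reports$scatter_length,
                file.path(out_dir, "scatter_accuracy_vs_length.tsv"))
    }
    yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
    files <- sort(list.files(out_dir, full.names = FALSE))
    files <- setdiff(files, "manifest.json")
    sums <- tools::md5sum(file.path(out_dir, files))
    manifest <- list(config = config,
                     files = stats::setNames(as.list(unname(sums)), files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    out$manifest <- manifest
  }
  out
}
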