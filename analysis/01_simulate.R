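#!/usr/bin/env Rscript
# Stage 1: simulate the study population.
#
# One cattle-like breed of ~300 animals (75 founders, three offspring
# generations under a 4-sire popular-sire scheme), a 3-autosome HD map
# of 15,000 SNPs with a nested ~6.4% MD subset, haplotypes with strong
# local LD, 12 planted CNV loci (deletions and duplications, 10-30
# SNPs, 12-30% carrier frequency, in perfect LD with their flanking
# haplotypes), LRR/BAF signals with a GC wave, injected genotype
# defects, and the call-rate/Mendelian SNP QC.
#
# Writes the simulation tables under results/run/ and an .rds bundle
# under results/state/ for the later stages.

library(herdcnv)

seed <- 1
dir.create("results/state", recursive = TRUE, showWarnings = FALSE)

cfg <- default_run_config(seed = seed)
res <- run_pipeline(cfg, out_dir = "results/run")

cat("Simulated", nrow(res$ped), "animals over",
    length(unique(res$map$chrom)), "chromosomes;",
    nrow(res$map), "SNPs survive QC (",
    sum(res$map$on_md_panel), "on the MD panel).\n")
cat("Planted loci surviving QC:", nrow(res$cnvs[[1]]$loci), "of",
    cfg$loci$n_loci, "\n")
print(res$cnvs[[1]]$loci[, c("locus_id", "chrom", "start_bp", "end_bp",
                             "n_snps", "cnv_allele", "n_carriers")])

saveRDS(res, "results/state/pipeline_run.rds")
cat("Full pipeline state saved to results/state/pipeline_run.rds\n")
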