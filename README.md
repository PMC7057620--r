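# herdcnv

Copy number variants (CNVs) — deleted or duplicated stretches of DNA
— are called from SNP-array data using the Log R Ratio (LRR, log of
observed over expected probe intensity) and the B allele frequency
(BAF, measured proportion of B alleles). When genotype data are
exchanged without LRR/BAF, CNVs cannot be called directly, which
raises two practical questions for livestock genetics:

1. **Panel density**: how often is a CNV called from a high-density
   (HD, ~713k-SNP class) panel re-detected on a nested medium-density
   (MD, ~46k-SNP class) panel of the same animals?
2. **Imputability**: can the diploid copy number of a CNV be imputed
   from the haplotype structure of the SNPs flanking its midpoint,
   using an older reference population whose CNVs were called?

`herdcnv` implements both analyses end-to-end on a simulated
pedigreed cattle-like population with known ground truth, so every
stage is testable: a population/haplotype/CNV/signal simulator, a
five-state hidden Markov model caller (states = copy numbers 0–4,
distance-dependent transitions, GC-wave regression, ≥3-SNP rule,
Viterbi decoding with an optional per-call log10 Bayes factor),
cross-panel overlap classification, and the full imputation design:
consensus calls across two callers (endpoints within 1 SNP), loci
carried by ≥30 animals, midpoint tri-allelic encoding
((D,D)=0, (N,D)=1, (N,N)=2, (N,P)=3, (P,P)=4), flanks of
10–500 SNPs per side, an oldest-80% reference split, a Li–Stephens
haplotype-copying imputer, and the evaluation suite (per-state
accuracy, adjusted Rand index, ANOVA + Tukey, Pearson correlations
with Fisher r-to-z intervals, Bayes-factor comparisons).

## Worked example

The demonstration pipeline (one breed of ~300 animals, 3 autosomes ×
5,000 HD SNPs, 12 planted CNV loci in perfect LD with their flanking
haplotypes) runs in about a minute:

```r
library(herdcnv)
res <- run_pipeline(default_run_config(seed = 1), out_dir = "results/run")
```

The numbered drivers under `analysis/` narrate the same run stage by
stage (`Rscript analysis/01_simulate.R` … `05_evaluate.R`). With seed
1 they print, among other things:

```
Simulated 315 animals over 3 chromosomes; 14914 SNPs survive QC ( 958 on the MD panel).
        call_set n_calls median_per_animal
1   HD penn_like     596                 2
2 HD quanti_like     574                 2
3   MD penn_like       1                 0

HD calls with no MD counterpart: 99.8%
HD call regions with < 3 MD SNPs (uncallable on MD): 64.3%

  flank_k overall_accuracy
1      10        0.9325397
2      25        0.9854497
...
Adjusted Rand index (called vs imputed copy number):
   breed       ari
1 breedA 0.9166771
```

Reading these numbers: the nested ~6.4% MD panel almost never
re-detects an HD call — mostly because the region no longer holds the
3 SNPs a call requires — reproducing the panel-density mechanism of
the real comparison. Imputation accuracy is high here *because* the
planted loci are in perfect LD with their flanking haplotypes (one
founder lineage carries the allele); this is the regime that
upper-bounds any imputer, and the package's no-LD control shows
accuracy collapsing to the majority-state baseline. Accuracy is
essentially flat in the number of flanking SNPs, and the normal state
(copy number 2) is imputed almost perfectly simply because most
validation animals carry no CNV.

## Layout

```
R/                  package code: simulator, caller, concordance,
                    imputation, evaluation, pipeline
src/                C++ (Rcpp): Viterbi decoder, Li-Stephens
                    forward-backward
analysis/01..05_*.R narrated stage drivers writing results/
scripts/acceptance.R  headline-quantity recomputation (JSON)
tests/testthat/     unit, property and end-to-end suites
vignettes/          methods vignette: models, parameters, limitations
```
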