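---
title: "Cross-panel CNV concordance and haplotype-based CNV imputation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-panel CNV concordance and haplotype-based CNV imputation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`herdcnv` implements, as a fully synthetic and tested pipeline, two
linked analyses on SNP-array copy number variants (CNVs) in a
pedigreed livestock population:

1. **Cross-panel concordance** — how often a CNV called from a
   high-density (HD, ~713k-SNP class) genotyping panel is re-detected
   on a nested medium-density (MD, ~46k-SNP class) subset of the same
   animals, and why it usually is not;
2. **Haplotype-based imputation** — whether the diploid copy number of
   a CNV can be imputed into animals for which only SNP genotypes are
   available, from the haplotype structure of the SNPs flanking the
   CNV midpoint.

Real array data for this design is proprietary; everything here runs
on a simulator whose ground truth makes every stage checkable. This
vignette explains the models, the tunable parameters, the numerical
conventions, and what the synthetic results do and do not show about
real data.

## The signal model

For each animal and SNP the array reports two values. The **Log R
Ratio (LRR)** is the log of observed over expected probe
hybridization intensity; its expectation shifts with the diploid copy
number `cn`. The **B allele frequency (BAF)** is the measured
proportion of B alleles; with `b` B alleles among `cn` copies it
clusters at `b/cn`. The renderer draws

```
LRR = mu[cn] + w * (gc - mean(gc)) + N(0, sigma[cn])
BAF ~ N(b/cn, sigma_baf) truncated to [0, 1]   (uniform when cn = 0)
```

Defaults: `mu = (-3.5, -0.66, 0, 0.40, 0.68)` and
`sigma = (1.3, 0.28, 0.21, 0.21, 0.26)` for copy numbers 0..4 — the
conventional working values for Illumina-style arrays; `sigma_baf =
0.05`; GC-wave slope `w = 0.4` against a smooth simulated GC track in
[0.3, 0.6]. None of these is a measured reproduction of any
particular array; they were chosen once for realistic state
separation and are fully configurable. A duplicated haplotype
contributes two copies of its own allele (a tandem duplication);
mixed deletion+duplication genotypes at one locus are not generated.

Called genotypes carry the underlying diploid SNP alleles: the SNPs
of an edited commercial panel have already survived genotype QC, so
genotype-call defects enter only through the explicit defect
injector (random missingness; forced opposing homozygotes at
designated SNPs), which the call-rate (< 95%) and
Mendelian-inconsistency (> 2% of parent-progeny pairs) filters then
catch. Both thresholds are boundary-exact: a call rate of exactly
0.95 or an inconsistency rate of exactly 2% is retained.

## Population and linkage disequilibrium

The pedigree uses discrete generations with a small pool of popular
sires (default 4) serving all dams — the standard structure of
commercial cattle breeding. This matters: the imputation design
selects CNVs carried by **at least 30 animals**, and with ~300
animals a carrier frequency above ~10% is only reachable by a founder
lineage that popular-sire breeding has expanded.

Founder haplotypes are drawn from per-SNP B-allele frequencies
(minor-allele frequency uniform on [0.05, 0.5] by default) with a
latent Gaussian AR(1) chain along each chromosome (`ld_rho = 0.95`)
that creates tunable local LD; meiosis applies Poisson crossovers at
~1 cM/Mb. The simulator records, for every haplotype segment, the
founder haplotype it descends from. A planted CNV locus uses that
record in one of three LD modes:

* `perfect` — the CNV allele rides exactly one founder lineage, so
  (absent recombination inside the window) the flanking haplotype
  identifies carrier status deterministically. This is the regime in
  which imputation *can* work, and it upper-bounds any imputer.
* `tagged_r2(r2)` — the perfect assignment degraded to a target
  squared correlation with the lineage.
* `independent` — carrier status independent of the flanking SNPs;
  the regime in which no imputer can beat the majority-state guess.

Real CNVs are somewhere between these extremes, typically far from
`perfect` (low-frequency structural alleles on common SNP
haplotypes); the simulator makes the extremes explicit instead of
claiming realism in between. Passing the perfect-LD recovery tests
therefore shows the machinery is correct, not that real cattle CNVs
are imputable — on the real data they largely were not.

## The caller

Both callers are the same five-state hidden Markov model (states =
copy numbers 0..4), decoded by Viterbi per animal and chromosome.
Emissions: Gaussian in LRR per state; BAF mixture over the `b/cn`
cluster means with binomial weights from the population B-allele
frequency, truncated-normal boundary clusters at 0 and 1 (avoiding
degenerate point masses), a uniform BAF for copy number 0, and a
small uniform outlier component (weight 0.01) for robustness.
Transitions are distance-dependent,

```
rho(d) = 1 - exp(-d / L);  P(i->j) = rho * pi[j]  (j != i)
P(i->i) = 1 - rho * (1 - pi[i])
```

with entry distribution `pi` putting 99.8% on the normal state and
length prior `L` = 100 kb (`penn_like`) or 2 Mb (`quanti_like`).
Before decoding, each animal's LRR is regressed on the local GC
fraction and replaced by the residuals (mean retained) — the
"genomic wave" correction; a simple per-sample linear regression
suffices because only the LRR-GC correlation is modelled.

Decoding conventions: ties in the Viterbi argmax resolve toward the
normal state (conservative calling; exact decoder equality with
brute-force path enumeration is property-tested). Maximal runs of a
constant non-normal state become calls only when they span **at
least 3 consecutive SNPs**; shorter runs are discarded, never merged,
and no upper length limit exists. Coordinates are 1-based closed
intervals at SNP positions everywhere; BED export converts to
0-based half-open.

The `quanti_like` caller attaches to each call a log10 Bayes factor:
the summed per-SNP log10 likelihood ratio of the called state versus
the normal state — a measure of whether the data support the CNV
being real. Full objective-Bayes machinery of the original tool is
deliberately out of scope; the Bayes factor is used downstream only
as a per-call confidence covariate.

A single boundary SNP adjacent to a wide inter-SNP gap can be won or
lost by emission noise; since such a SNP can carry a large share of
the bp span, reciprocal-overlap recovery of short planted loci
saturates near (not at) 100%. This is inherent to single-SNP
resolution, not a decoder defect.

## Cross-panel concordance

The MD panel is a nested subset of the HD map (default fraction
45,677/713,162 ≈ 6.4%, seeded thinning of exactly `floor(f*n)` SNPs,
or an explicit SNP list emulating a commercial chip). CNVs are called
from HD with both callers and from MD with the `penn_like` caller
only. Each HD call is classified against the same animal's MD calls:
`direct` (identical bp coordinates — the strictest reading of
"same genomic position"), `partial` (intervals intersect), `none`.
Copy-number state is *not* required to match; only position is
compared. Multiple intersecting MD calls resolve to the largest
overlap, ties to the leftmost start. Summaries use type-7
(linear-interpolation) quantiles; lengths are `(end - start + 1)/1000`
kb under the closed-interval convention.

The mechanism behind the dominant `none` class is SNP support: a
region holding fewer than 3 MD SNPs can never produce an MD call.
The per-region MD SNP count (binary search, oracle-tested against a
linear scan) makes that mechanism an exact, testable rule.

## The imputation experiment

* **Consensus**: a CNV enters the experiment only if called in the
  same animal by both callers with the same copy number and endpoint
  SNP indices differing by at most 1; the consensus interval is the
  union. Matching is greedy in start order, each call used once.
* **Locus grouping**: per-animal consensus calls sharing coordinates
  are grouped into population loci. The default grouping is exact,
  with a configurable bp tolerance; the pipeline uses 100 kb because
  Viterbi boundary jitter of a few SNPs (~10 kb spacing) otherwise
  fragments one biological locus into several coordinate groups,
  splitting its carriers below the selection threshold.
* **Selection**: loci carried by **>= 30** animals within the breed
  (small-sample-bias guard).
* **Encoding**: each selected locus becomes a marker at
  `floor((start+end)/2)` with alleles N (normal), D (deletion), P
  (duplication); genotype-to-copy-number map (D,D)=0, (N,D)=1,
  (N,N)=2, (N,P)=3, (P,P)=4. Split bi-allelic modes (deletions-only,
  duplications-only) mirror imputers restricted to bi-allelic
  markers; the invisible class collapses to (N,N).
* **Flanks**: the k nearest SNPs strictly left and right of the
  midpoint, k in {10, 25, 50, 100, 250, 500}; SNPs inside the CNV are
  eligible by design. A chromosome end may truncate a side; an empty
  side skips the task.
* **Split**: within breed, the oldest `ceiling(0.8 n)` animals (by
  birth order) are the reference population with known marker
  genotypes; the youngest 20% are validation, marker hidden. The
  same split serves every imputer configuration.
* **Imputer**: a haploid Li–Stephens haplotype-copying model — each
  validation haplotype is a mosaic of reference haplotypes with
  per-SNP switch probability 0.01 and allele-error probability 0.002
  (standard small-panel values, configurable); the marker is one more
  column, and the imputed allele is the posterior mode at that
  column. A second preset (`window`) imputes by the longest exact
  haplotype match spanning the midpoint, emulating sliding-window
  imputers. Both are deterministic given their inputs. Validation
  flank haplotypes come phased from the simulator; statistical
  phasing is out of scope, and reference marker alleles are the
  *called* copy numbers oriented onto the true carrier haplotype
  where the simulator identifies it.

Validation animals without a consensus call at a locus count as
called copy number 2 — which is why the normal state dominates every
validation set and is imputed with near-perfect accuracy while rare
states carry the information.

## Evaluation statistics

* **Accuracy**: per locus and per called state, the fraction of
  validation animals whose imputed copy number equals the called copy
  number. The default denominator is the number of validation animals
  in which that state was called (the convention of the per-CNV
  accuracy listing); `all_validation` divides by the whole validation
  population instead, and the flag is exposed because the two
  conventions genuinely differ.
* **Adjusted Rand index** (Hubert–Arabie): chance-corrected
  pair-counting agreement between called and imputed labels, computed
  per breed over all validation (animal x locus) pairs, pooling
  states. Degenerate single-cluster labelings return 0 with a
  warning. The implementation is oracle-tested against exhaustive
  pair enumeration and cross-checked against an independent library
  implementation.
* **ANOVA + Tukey HSD** over flank size, called state, and breed;
  pairs declared different at adjusted p < 0.05; no cross-family
  multiplicity correction is applied (none is in the design being
  emulated). Zero-spread inputs short-circuit to F = 0, all p = 1.
* **Pearson correlations** of accuracy with population frequency and
  genomic length, with Fisher r-to-z 95% intervals
  `tanh(atanh(r) ± 1.96/sqrt(n-3))`; a correlation is "different from
  zero" only when the interval excludes zero.
* **Bayes-factor comparison**: two-level ANOVA of per-call Bayes
  factors between correctly and incorrectly imputed instances, per
  breed and pooled, with the direction of the mean difference.

## Problem sizes and reproducibility

The demonstration configuration is one breed of ~300 animals, 3
autosomes x 5,000 HD SNPs (50 Mb each, so ~10 kb spacing — a
desk-scale stand-in for the real ~3 kb), 12 planted loci at 12–30%
carrier frequency in perfect LD, and the full flank-size grid. These
sizes were chosen as the smallest population in which the >= 30
carrier rule, the 80/20 age split, and per-state accuracies are all
non-trivially exercised. Every stage derives its seed from the root
seed by a named-substream scheme, so adding a stage never perturbs
earlier stages; re-running a configuration reproduces byte-identical
outputs, which the manifest (MD5 per artifact) makes checkable.

## Known limitations

* The HMM is a convention-faithful re-creation, not a numerical clone
  of any published caller; parameter files of those tools are not
  reproduced.
* Simulated LD is a two-knob caricature (AR(1) founder chain +
  explicit LD modes); real haplotype mosaics are richer, and real
  CNV-SNP LD is usually much weaker than the `perfect` regime.
* One internal imputer stands in for the external imputation tools of
  the original design; its two presets emulate their mechanisms
  (HMM copying vs window matching), not their codebases.
* Breeds are independent simulated populations; cross-breed reference
  panels are out of scope, as are X/Y chromosomes, CNVR merging
  across animals, and raw intensity (IDAT) handling.
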