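---
title: "Population-scale lncRNA analysis of the wheat spike: methods and design"
author: "spikelnc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-scale lncRNA analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikelnc)
```

## Scope and model

`spikelnc` re-implements, as a tested and reusable pipeline, the analysis
chain used to characterise long non-coding RNAs (lncRNAs) in a population
transcriptome of the wheat spike: candidate calling from a reference-guided
assembly, cis/trans target pairing, population genetics over a structured
nine-group *Triticum*/*Aegilops* diversity panel, competing-endogenous-RNA
(ceRNA) triangle inference, trait association with QTL/introgression
co-localization, and cross-species conservation. Everything runs at desk
scale on synthetic inputs whose statistical structure mirrors the real
study design (186 spike RNA-seq samples from 93 genotypes; 261 genotyped
accessions in nine groups; a wheat 660K-style array on 93 accessions).

Upstream heavy lifting that the original analysis delegated to external
tools is consumed as tables, not re-implemented: read alignment and
transcript assembly, coding-potential prediction (CPC/LGC/Pfam-style
verdicts arrive as a `coding_calls` table), miRNA target prediction
(psRNATarget-style binding spans), pairing free energies (LncTar-style
normalised free energy), and genome alignment hits (BLAST/GMAP-style rows
with identity and coverage).

## Discovery: structural class codes plus three filters

Candidate lncRNAs are the intersection of four rules, applied in gffcompare
spirit:

1. **Structural class** in {i, j, o, u} against the reference annotation:
   `i` fully contained in a reference intron, `j` multi-exon sharing at
   least one exact splice junction, `o` other same-strand exonic overlap,
   `u` intergenic. Codes `=`, `c`, `e`, `x` mark reference-matching,
   contained, single-exon exon/intron-spanning and antisense transcripts
   respectively; all four are excluded from candidacy (antisense transcripts
   are genuine lncRNAs biologically, but the discovery rule used here keeps
   only i/j/o/u). Precedence is fixed as `=` > `c` > `j` > `e` > `i` > `o` >
   `x` > `u` so that assignment is total and deterministic; permuting the
   reference never changes a code.
2. **Expression**: FPKM strictly greater than 0.1 in at least 20% of
   samples, with the sample count rounded up (`ceiling`) — the conservative
   reading of "at least 20%".
3. **Length**: spliced length strictly greater than 200 bp.
4. **Coding potential**: unanimous non-coding verdict across every
   predictor present in the consumed table. A transcript missing from the
   table is excluded and counted as a "no-call", never silently kept.

One predicate was genuinely open: a transcript that touches only intronic
sequence of a gene without being fully contained in one intron. We require
exonic overlap for `o`, so such transcripts fall through to `u`; the
alternative (calling them `o`) would only move transcripts between two
retained classes and does not change the candidate set.

The classifier is verified against a brute-force oracle that evaluates
every predicate on explicit per-base sets, over hundreds of random small
instances.

## Target pairing

A protein-coding gene within 100 kb of a lncRNA (nearest-edge gap; the
convention-free reading of "within 100 kb") is its cis candidate; each
lncRNA is assigned at most one cis gene — the nearest, ties broken by
distance then gene id — reflecting the one-to-one behaviour of cis pairs.
Trans candidates are the entries of the pairing-energy table beyond the
window or on another chromosome, and may be one-to-many. Every emitted pair
must satisfy Spearman |rho| > 0.9 with p < 0.05; rho is Pearson correlation
on mid-ranks and the p-value uses the t approximation on n − 2 degrees of
freedom. The free-energy cutoff applies to trans pairs only by default
(`energy_on_cis` extends it): the correlation requirement is what the
source protocol states for both modes, while the energy computation is
specifically a trans-discovery device. P-values are deliberately not
multiplicity-adjusted, matching the per-pair p < 0.05 rule; a BH flag is
available.

## Population genetics

*Diversity.* Per-site nucleotide diversity uses the unbiased estimator
`n/(n−1) · 2p(1−p)` with `n` the non-missing allele count; windowed pi
divides the per-site sum by the full window span in bp (the VCFtools
`--window-pi` convention, 50 kb default tiling) — not by the number of
variant sites. Both 50 kb tiling and per-feature windows are provided,
since either could underlie a per-feature diversity table. Sites with fewer
than 4 non-missing alleles in a group are skipped; missingness is
propagated, never imputed.

*Differentiation.* Fst is the two-population Weir–Cockerham (1984)
estimator computed from genotype counts (variance components a, b, c with
observed heterozygosity), aggregated as a ratio of sums across sites —
VCFtools' "weighted" Fst, appropriate when one value per group pair is
reported. The per-site mean is also emitted. Fixed differences give exactly
1; the estimator is slightly negative when between-group variance is
exactly zero, so small negatives are preserved and flagged rather than
truncated to zero (values below −0.05 are clamped).

*Haplotypes.* Haplotype strings are built per chromosome copy over a
feature's SNPs in positional order, from phased or fully homozygous
genotypes only — no statistical phasing. The major-haplotype rule is
within-group frequency **strictly** greater than 50%. The source wording
("more than 50% of the total number of subgroups") admits a second reading
— a haplotype shared by most subgroups — but only the within-group
frequency reading reproduces the reported usage (a 76.92% major haplotype
in a 13-accession durum group), so that is what we implement.

*Lineage shifts.* Diversity shifts are signed per parent→child edge of a
configurable lineage (defaults: wild einkorn → domesticated einkorn, wild
emmer → domesticated emmer → durum, landrace → cultivar), with ratio < 1
flagged as a bottleneck.

## ceRNA triangles

A triangle is a (lncRNA, miRNA, mRNA) triple in which both transcripts
carry a binding site of the same miRNA (exact id intersection after an
expectation-score cutoff of 5, the consumed predictor's conventional
default). The expression condition defaults to **negative** lncRNA–mRNA
correlation with |rho| ≥ 0.5 — classical ceRNA theory predicts a positive
sponge correlation, but the worked example this pipeline mirrors shows a
significantly negative lncRNA–mRNA relationship, so the sign is a flag with
`negative` as default. miRNA abundance is not required in the expression
matrix (small RNAs are not in an RNA-seq FPKM table). Triangles are not
restricted to previously emitted target pairs, matching the independence of
the two analyses; `network_export` can annotate which triangle edges are
also emitted pairs.

## Trait association

The per-SNP scan fits `phenotype ~ dosage + PC1..PCk` (k = 3 genotype
principal components by default). This is a stated stand-in for the
compressed mixed linear model of the original protocol: at desk scale, PC
adjustment plays the same inferential role (population-structure
correction) while remaining deterministic and dependency-free. The
significance threshold is `1/Ne` applied strictly, with `Ne` the effective
number of independent tests — the post-filter SNP count by default, or a
supplied value such as the 21,868 used with the real 660K array. Features
within 5 Mb of a passing SNP become candidates; the "(r² ≥ 0.2)" qualifier
attached to that window is read as its justification via LD decay, not as a
per-feature filter (an optional r² mode is provided). MAF and missingness
filters for the array are not stated upstream; the defaults (MAF ≥ 0.05)
are exposed and logged. Co-localization with QTL and introgression
intervals uses any-base half-open intersection, and enrichment is Fisher's
exact test implemented by full hypergeometric enumeration (two-sided rule:
sum of table probabilities not exceeding the observed table's), checked
against `stats::fisher.test` over all small tables.

## Conservation

The conservation score of an alignment hit is declared nowhere upstream
beyond "based on sequence coverage and identity"; we adopt
`score = coverage × identity` — both factors are cited, the product stays
in [0, 1], and the 0.6 retention threshold remains meaningful — with
`(coverage + identity)/2` selectable. Coverage is query coverage (the
subject-side convention is unknowable from the consumed table). Single-copy
lncRNAs are those with exactly one retained hit in every species. The
species tree is neighbour joining on distances `1 − mean pairwise
conservation` (per query, a species pair's shared conservation is the
minimum of the two scores; the focal species has self-score 1). NJ is a
deliberate desk-scale substitute for maximum-likelihood inference and is
labelled as such; on additive distances it is exact, which the tests
exploit.

## The synthetic-data generator

The generator's defaults are the study conditions, not tuning knobs:

* 186 expression samples; nine panel groups of 31/31/29/28/29/13/45/25/30
  accessions (A1–A3, AB1–AB3, ABD1–ABD2, D1; total 261).
* lncRNAs centred near the reported median of 1,584 bp with 89.2%
  single-exon; mRNAs centred near 3,953 bp and multi-exon; lncRNA mean
  abundance below mRNA abundance (log-normal FPKM — the upstream study
  reports medians only, so the noise model is a documented stand-in
  isolated behind the configuration).
* Planted cis pairs within 100 kb of their partner (Spearman target 0.95),
  trans pairs across chromosomes (same strength — the emission rule is
  identical for both modes), ceRNA triangles at rho −0.8 with 21-nt binding
  spans mirroring the worked example's span widths, and class-planted
  i/j/o lncRNAs constructed so the classifier provably returns the intended
  code.
* Correlations are planted through a Gaussian copula: a latent bivariate
  normal with Pearson correlation `2·sin(π·rho_s/6)` yields the target
  Spearman `rho_s` exactly, and the monotone log-normal transform preserves
  it.
* Population structure follows a Balding–Nichols model: ancestral
  frequencies Uniform(0.05, 0.95), per-group Beta-distributed frequencies
  whose drift parameter is calibrated so realised feature-level diversity
  hits per-group targets (defaults halve along each domestication/
  improvement edge — a bottleneck). With SNP spacing `s` inside features,
  the drift solves `pi = (1/s) · 0.365 · (1 − F)`, where 0.365 is the
  expected heterozygosity under the ancestral-frequency prior. Realised
  diversity lands within ~10% of target at a few thousand sites.
* One causal SNP per phenotype: the array SNP nearest a planted cis lncRNA,
  with Gaussian noise scaled to heritability 0.5 on 93 samples.
* A major-haplotype pattern is planted at one feature (all-alternate
  haplotype at frequencies 0.77/0.93/1.00 in the durum, landrace and
  cultivar groups), reproducing the reported 76.92%/93.33%/100% pattern.
* Each stage draws from its own RNG stream (`seed` + fixed offset), so
  stages are independently re-runnable and the whole generator is
  byte-deterministic.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: linkage disequilibrium within features
(sites are drawn independently given group frequencies), homoeologous
subgenome structure of hexaploid wheat, read-level noise, isoform
complexity, batch effects in FPKM, and selection. Recovery rates on
synthetic data are a check of the pipeline's correctness under its own
assumptions, not an estimate of real-data sensitivity.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; GTF/VCF are
  converted on read/write, BED passes through. A site at a feature's `end`
  is outside it.
* Genotypes collapse to dosage {0, 1, 2}; phase is kept only where the VCF
  provides it (or the call is homozygous) and is consumed solely by the
  haplotype builder. Multi-allelic sites and indels are skipped with a
  count, not split.
* Spearman correlation on a constant vector is an error, not an NA;
  `|rho| = 1` reports p = 0.
* Cis assignment ties break by distance then lexicographic gene id;
  best-hit ties in conservation break by e-value then subject id; NJ
  negative branch lengths are clamped to 0 and flagged.
* Fisher enumeration guards the probability comparison with a relative
  tolerance of 1e-7, the convention that avoids floating-point misses at
  ties.
* The run configuration is YAML (the R pipeline convention; thresholds all
  default to the protocol's printed values: 0.1 FPKM, 20%, 200 bp, 100 kb,
  |r| > 0.9, p < 0.05, 50 kb, > 50%, 0.6, 5 Mb, 1/Ne).

## Problem sizes

The shipped tests and the acceptance script use the full study conditions
where they matter (186 expression samples, 261 accessions, 93 association
samples, 100 association replicates) and scale the remaining dimensions to
desk size: 120 genes, 90 lncRNAs, three 40-Mb chromosomes, ~9,000 panel
SNPs, 1,200 array SNPs. These sizes keep every property measurable (e.g.
realised diversity within its calibration band needs a few thousand sites)
while a full run of generator plus all seven stages completes in well under
a minute.

## Known limitations

* The GWAS stand-in does not model kinship beyond principal components; on
  data with strong family structure it will be anti-conservative relative
  to a mixed model.
* Haplotype tables silently shrink when phase is absent; panels of
  unphased heterozygous calls yield empty tables (by design — no phasing is
  attempted — but worth knowing).
* The conservation score formula and the species-pair distance are
  package decisions documented above, not reproductions of an upstream
  formula; comparisons across scoring conventions should use the flags.
* miRNA–miRNA interactions are not modelled: the ceRNA graph has only
  miRNA–transcript binding edges and lncRNA–mRNA correlation edges.
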