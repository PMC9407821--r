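---
title: "Methods: convergent expression and promoter-methylation calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: convergent expression and promoter-methylation calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its statistical machinery: the
models behind each stage, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices a maintainer should know about. It states no empirical result
that the test suite and `scripts/acceptance.R` do not themselves compute.

## The scientific setting

Two focal species that independently evolved the same derived phenotype are
compared with a panel of outgroup species in two tissues, at two molecular
layers: ortholog-level RNA-seq counts (focal pair + three outgroups) and
whole-genome bisulfite cytosine counts (focal pair + one outgroup). The
quantity of interest is not differential expression per se but *convergence*:
a shift present in both focal lineages against every outgroup, and — at the
integration stage — an expression shift mirrored by an opposite promoter
methylation shift, the signature expected if promoter methylation represses
transcription.

## Expression normalization (GeTMM)

Cross-species ortholog counts confound two nuisance scales: transcript length
differs between orthologs of different species, and sequencing depth differs
between libraries. Normalization therefore combines within-sample
length correction with between-sample trimmed-mean-of-M-values (TMM) scaling:

1. `RPK[g,s] = count[g,s] / (length_bp[g] / 1000)`.
2. TMM factors on the RPK table. The reference sample is the one whose
   upper-quartile/library-size ratio is closest to the panel mean. For each
   sample, log ratios `M_g` and average log abundances `A_g` against the
   reference are computed over genes positive in both; the top and bottom
   30% of `M` and 5% of `A` are removed by rank; the factor is 2 raised to
   the precision-weighted mean of the surviving `M_g`, with inverse
   delta-method variances `(N−x)/(Nx) + (N_r−r)/(N_r r)` as weights. Factors
   are rescaled to geometric mean 1 (a convention that changes absolute
   values but no downstream call).
3. `GeTMM[g,s] = RPK[g,s] · 1e6 / (Σ_g RPK[g,s] · f_s)`, a per-million scale
   comparable across species.

Two numerical notes. First, if fewer than 10 genes survive the double trim
(possible in pathological fixtures where most `M_g` are tied), the factor
falls back to the untrimmed weighted mean with a warning. Second, scaling all
counts of one sample by a constant leaves its `M`, `A` and reference choice
unchanged but *not* the precision weights, which depend on library size; the
normalized column is therefore depth-invariant only to ≈ 1e-3 relative at
typical depths, not exactly. The test suite asserts the identity at that
tolerance.

Upstream of normalization, the low-expression filter keeps genes with
non-zero counts in **every sample of every species** (the strict reading;
`rule = "any_species"` gives the permissive alternative requiring complete
non-zero support in at least one species). Downstream, values are
`log2(x + 1)`-transformed — base and offset are a package choice — and the
variance filter drops the fraction `quantile = 0.5` of genes with the lowest
cross-sample variance, ties at the cutoff retained. The threshold "0.5" is
read as a quantile (drop the lowest-variance half), the common convention in
expression filtering, and is configurable; the filtered universe is what
enters the differential tests, and that choice also fixes the multiplicity
burden of the BH step.

## Differential expression and convergence

The per-contrast test is the exact conditional negative-binomial test.
Replicate counts are equalized to a common effective library size (the
geometric mean of `colSums(counts) × TMM factor`), rounded to pseudo-counts,
and summed within groups. Under a common dispersion φ and equal means, the
conditional law of the group-A sum given the total `t` is negative
hypergeometric — free of the unknown mean — and the p-value sums the
probabilities of all outcomes `k ∈ [0, t]` no more likely than the observed
one. With φ → 0 the law degenerates to Binomial(t, n_A/(n_A+n_B)). Outcomes
whose log-probability is within 1e-10 of the observed one count as ties and
are included; this keeps exactly-symmetric cases stable against floating-point
jitter. `t = 0` returns p = 1.

The common dispersion is method-of-moments: per gene, pooled within-species
variance s² and grand mean μ̄ on factor-scaled counts give
`φ_g = max(0, (s² − μ̄)/μ̄²)`; the common value is the median of φ_g over
genes with μ̄ > 5 (defaulting to 0.1 with a warning if no gene qualifies).
This deliberately implements the classic exact-test-with-common-dispersion
family rather than tagwise/quasi-likelihood machinery: the target estimand is
planted-truth recovery of convergent calls, not per-gene shrinkage.

Fold changes are computed on the GeTMM scale with a prior count of 1,
`log2((mean_focal + 1)/(mean_outgroup + 1))`, positive meaning higher in the
focal species. DEGs require `BH-adjusted p < 0.05` and `|log2FC| > 1`, with
BH applied within each contrast (per-comparison adjustment, matching how
pairwise contrasts are usually reported). Convergence is a strict
intersection: per focal species a gene must be a same-direction DEG against
*every* outgroup; direction conflicts exclude the gene; the convergent set is
the intersection of the two focal species' directional sets.

## Methylation quantification

Every methylation level in the package is a pooled read ratio
`Σ mC / Σ(mC + uC)`, never a mean of site levels — the two differ whenever
coverage varies, and pooling satisfies the exact identity that the overall
level is the coverage-weighted mean of any partition's levels. Contexts
(CG/CHG/CHH, H ∈ {A, C, T}) are read from the strandwise trinucleotide, with
the reverse complement used on the minus strand; sites within 2 bp of a
chromosome end with an incomplete triplet are classed CHH by convention and
reported. CpG sites are kept per strand (no symmetric merging) because the
counting unit is the cytosine.

Gene elements follow one coordinate convention — 0-based half-open
everywhere, converted only at the GFF3 (1-based closed) boundary — with the
promoter as the 1000 bp immediately upstream of the TSS, strand-aware.
Element levels pool all genes' sites (one number per element class);
overlapping genes are *not* resolved, so a site may count toward several
genes, mirroring the upstream tools this emulates. The metagene profile uses
20 bins per region (upstream 2 kb, length-normalized body, downstream 2 kb;
60 bins total), pools within gene × bin, then averages bins across genes
unweighted so long genes do not dominate; per-gene averaging versus global
site pooling is configurable in spirit — the element-level function pools,
the profile averages — and both choices are stated here because the source
conventions are ambiguous.

## Differential promoter methylation

The promoter matrix has one row per ortholog and one pooled level per sample;
cells without a covered CpG are missing; the same variance filter as the
expression arm (quantile 0.5) fixes the tested universe.

The key design decision is the Wilcoxon observation unit. With only 3–4
biological replicates per species, a per-sample rank-sum test cannot reach
BH-adjusted significance across thousands of genes (the smallest one-sided
p at 4 vs 3 is 1/35), so per-sample testing would return empty convergent
sets under any truth. The test therefore treats each (CpG site, sample) pair
with coverage ≥ 5 as one observation — the ≥ 5× stratum stabilizes levels —
grouped by species. Both one-tailed tests run per gene; BH is applied across
genes within each direction family; `hypo` means lower in the focal species.
A per-sample mode remains available (`unit = "sample"`) for designs with many
replicates. The Wilcoxon itself is `stats::wilcox.test`: exact enumeration
for tie-free samples (up to its standard n < 50 switch, wider than a minimal
implementation would use — strictly closer to the exact null), otherwise the
tie-corrected normal approximation with continuity correction. Swapping the
two groups maps the two one-sided p-values onto each other exactly, which the
tests assert as a direction-coherence property.

Convergent promoters intersect the two focal species' direction-consistent
calls, exactly as in the expression arm.

## Integration and enrichment

Genes present in a tissue's convergent DEG *and* convergent promoter sets are
joined; `inverse_consistent` is `(up ∧ hypo) ∨ (down ∧ hyper)`. The summary
counts (up∧hypo, down∧hyper, non-inverse) are a package addition — the
motivating analyses report per-gene examples rather than a genome-wide
inverse-consistency count — and are labeled as such in the attribute.
Over-representation uses the hypergeometric upper tail against a background
of expressed genes (configurable), BH across sets; term databases are out of
scope, user GMT files are the interface.

## The synthetic-data generator

The generator is the package's test bed and defines the study conditions its
guarantees are stated under.

*Expression.* Gene baselines are log-normal (`meanlog 3, sdlog 1.2`);
expected counts are `library size × relative weight`, with weights
proportional to baseline × length so longer transcripts attract more reads;
counts are NB with one common dispersion (variance μ + φμ²), matching the
test's assumption. Planted convergent genes shift by ±`effect_log2fc` in both
focal species; per-sample weights are renormalized, so the planted genes
induce a genuine composition bias in the null genes — precisely the bias TMM
exists to absorb, which makes the null calibration test meaningful.
Defaults: 2000 genes, 100 up + 100 down at |log2FC| = 2, φ = 0.1, libraries
0.8–1.2 M, 4 replicates per species per tissue, two focal + three outgroup
species. Tissues are independent runs under different derived seeds (no
shared-individual correlation, as the tissues are analyzed separately
throughout).

*Genome and annotation.* 100 genes per chromosome, ≥ 2 kb flanks, 2–4 exons,
random strand. The background sequence is CpG-depleted (accidental CG
dinucleotides are broken), then CG dinucleotides are planted: 20 per 1 kb
promoter, 20 per gene body, sparse intergenic — giving promoters the CpG
island structure real vertebrate genomes show.

*Methylome.* True site levels are Beta with concentration 30 around a mean
that follows a V-shaped trough centred on the TSS: body/intergenic baseline
0.7 tapering to promoter baseline 0.4 at the TSS over ±1 kb. The trough shape
is why the metagene minimum is localized at the TSS-adjacent bins rather than
anywhere in a flat plateau. Planted hypo (hyper) promoters shift the
promoter-region mean by −0.3 (+0.3) in both focal species; the default
promoter baseline of 0.4 keeps both shifts inside (0, 1) (shifted means are
clipped to [0.01, 0.99] with a warning when a configuration does push them
out, e.g. the +0.3 shift at the trough edge where the baseline nears 0.7).
Coverage is Poisson(10) truncated at 1 — every emitted site is observed, the
"covered by at least one read" stratum — and methylated counts are binomial.
Non-CpG cytosines are emitted for a sparse 2% subsample of positions at mean
level 0.01, reflecting the near-absence of non-CpG methylation in mammals
while keeping reports compact. In the pipeline, planted hypo promoters are
assigned to convergent-up genes first (hyper to convergent-down), so inverse
methylation–expression pairs exist by construction and the integration stage
has a measurable recovery target. All species share one assembly (the
ortholog map is the identity); the promoter-matrix interface nevertheless
accepts per-species annotations plus an explicit ortholog map, which is the
path real multi-assembly data would take.

What the generator does **not** emulate — and what passing tests therefore do
not show about real data: read-level artifacts (alignment error, bisulfite
conversion failure, M-bias), tagwise dispersion variation and outlier genes,
correlated replicates or batch structure, overlapping genes, assembly and
ortholog-inference error, and species-tree correlation among outgroups.
Recovery rates on real data will be lower than on these clean conditions; the
synthetic guarantees validate the machinery, not field performance.

## Problem sizes and determinism

The test suite runs each guarantee at its stated size: 50 random 200 × 6
fixtures for TMM-oracle equivalence, totals ≤ 200 for exact-test enumeration,
2000-gene global-null simulations (10 seeds) for calibration, five 2000-gene
seeds for convergent DEG recovery, five methylome seeds (20 CpGs/promoter,
depth 10, Δ = 0.3) for promoter recovery, and one full two-arm run of the
bundled `demo_config.yaml` for the end-to-end inverse-pair check. Every
stochastic step is driven by a single integer seed through a deterministic
derivation (`seed + 9973 × offset`, kept below 2³¹), so identical seeds give
byte-identical outputs; the test suite asserts this.

## Known limitations

- The common-dispersion estimator is slightly downward-biased (median of
  method-of-moments estimates), making the exact test marginally liberal;
  under the default null conditions BH still yields essentially zero
  discoveries, which the suite checks, but single-gene p-values near the
  threshold should not be over-read.
- Promoter-level testing with site-level observations treats sites within a
  promoter as exchangeable observations; spatial correlation within a
  promoter is ignored, which is anticonservative for genes with few, highly
  correlated CpGs. The coverage floor and BH correction mitigate but do not
  remove this.
- No smoothing-based DMR discovery outside promoters, no beta-binomial
  regression, no batch-effect correction, and no attempt at per-gene
  dispersion shrinkage; these are deliberate scope boundaries.
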