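---
title: "Methods: eQTL mapping, motif conservation and selection scans at a regulatory variant"
author: "fireqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eQTL mapping, motif conservation and selection scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models behind `fireqtl`, the
choices made where several defensible conventions exist, what the
synthetic-data generators do and do not emulate, and the numerical details
that matter for reproducing results.

## The scientific setting

A common A→G substitution (rs12553564, chr9:21,017,241 on GRCh38, minor
allele frequency around 30% worldwide) sits inside an LPS-inducible
enhancer located roughly 100 kb from *IFNB1*, within an intron of
*PTPLAD2*/*HACD4*. The G allele is associated with lower *IFNB1* induction
in stimulated monocytes, disrupts a C/EBP-β binding motif that is conserved
across mammals, and reduces C/EBP-β occupancy in heterozygous donors. The
package implements the computational arms of that dissection — association,
motif, population-genetic and prioritization analyses — against synthetic
inputs with known truth, since the original cohort is controlled-access.

## cis- and trans-eQTL mapping

**Transform.** Expression (log₂ FPKM) is mapped per condition to normal
quantiles, `Φ⁻¹((rank − 0.5)/n)` with average ranks for ties. The
`(r − 0.5)/n` offset keeps all values finite; the transform is idempotent
on ranks. A constant vector is an error: its ranks carry no information.

**Model.** For each SNP and condition, ordinary least squares of the
transformed expression on the dosage (0/1/2) with the population of origin
as a binary covariate (k populations would enter as k−1 indicators). The
reported p-value is the two-sided t-test on the dosage coefficient; `r2`
is the *partial* variance explained by genotype after the covariate,
`t²/(t² + df)` — the marginal and partial versions differ, and the partial
one is reported and labelled as such. The scan residualizes the phenotype
and all dosages on the covariates once (QR projection) and fits every SNP
from the partial regression; this is algebraically identical to per-SNP
`lm()` fits (tested to 1e-10) but vectorizes over SNPs and permutations.
Missing genotypes are mean-imputed per variant and population for the
regression only; allele frequencies and F_ST always exclude them pairwise.
A monomorphic genotype returns `beta = NA, p = 1` with a flag rather than
an error, so downstream set operations never crash.

**Family-wise error.** The significance threshold is calibrated by
permutation: the transformed phenotype is shuffled across individuals
*within each population stratum*, with the same permutation of individuals
applied to every condition — this preserves the covariate structure exactly
and the between-condition dependence of repeated measures on the same
individuals. Per permutation the minimum p over all SNPs *and* conditions
is recorded; the threshold is the k-th smallest of the `n_permutations`
minima with `k = floor(target_fwer × n_permutations)` (so 1000 permutations
at 1% use the 10th smallest, and `target_fwer × n_permutations < 1` is an
error). With independent SNPs this converges to the Šidák threshold
`1 − (1 − α)^(1/m)`; with LD it is appropriately looser. The threshold
itself is a Monte-Carlo estimate: the 1% quantile of 1000 minima has a
relative standard deviation near 30%, which is the dominant noise term when
the realized error rate is re-measured on fresh null data.

**Conditional and trans scans.** Conditioning adds the lead variant's
dosage as a covariate and drops it from the results. The trans scan fits
one SNP against every gene (each inverse-normal transformed within the
condition), adjusts with the Benjamini–Hochberg step-up rule, and keeps
associations with `q ≤ 0.01` and `|β| ≥ 0.2`, labelled by sign.

## Motif scanning and conservation

**PWM.** Counts are converted by the log probability ratio method:
`p = (count + 0.8·0.25)/(total + 0.8)`, `w = log₂(p/0.25)` — pseudocount
0.8 distributed by the uniform background, added per column. Max/min
attainable raw scores are stored so windows can be scored on the min–max
relative scale `(raw − min)/(max − min) ∈ [0, 1]`.

**The 85% rule.** "Binding score above 85% of the maximum" is implemented
as min–max relative score ≥ 0.85, the convention of the standard motif
scanning tools this mirrors; the literal reading `raw ≥ 0.85 × max` is
available behind `literal_max = TRUE`. Both strands are scanned (reverse
strand by reverse-complementing the matrix) and hits must overlap the focal
position (`start ≤ focal < start + L`). Windows containing `N` or gap
characters score nothing.

**Conservation.** For each species aligned in the 21-bp window (focal
± 10 bp), the row is degapped and rescanned; a species counts if at least
one hit overlaps its mapped focal position. When the focal column is a gap
in a species, the nearest aligned flanking base is used as its focal
position — the permissive choice, flagged per species in the output. The
call is conserved iff strictly more than 20 species carry the site, and is
invariant to species order and to all-gap padding. Whether hits must share
a strand across species is left open by the convention; any-strand hits are
counted.

**Allele impact.** Each allele is substituted at the focal offset and the
best *overlapping* relative score is taken regardless of the 85% threshold,
so the difference is always defined. `delta = (anc − der)/anc`, and binding
is called decreased iff `delta > 0.10`, strictly — a drop of exactly 10%
does not flip the flag. The expression filter then keeps impacted TFs whose
gene has mean raw (untransformed) FPKM at or above the cutoff in the stated
condition (1 for "expressed", 100 for "highly expressed").

## Selection statistics

**Tajima's D** uses the textbook constants derived from the haplotype count
and `D = (π − S/a₁)/√(e₁S + e₂S(S−1))`, with π the average pairwise
Hamming distance; `S = 0` yields `NaN`, not an error. The analysis window
is 100 kb around the focal site (± 50 kb).

**EHH and iHS.** EHH among carriers of a core allele is the probability
that two random carriers are identical from the core out to each successive
site, `Σ C(n_k,2)/C(n_core,2)` over haplotype classes; it starts at 1 and
is non-increasing. iHH is the trapezoid integral of EHH over physical
distance (no genetic map is used; none is available at this scale), both
directions summed, truncated at the first point where EHH drops below 0.05
(that segment is included) or at ±50 kb, with linear interpolation at the
cap; curves that never reach the truncation value are integrated to the cap
and flagged. `uiHS = ln(iHH_ancestral/iHH_derived)`, so a sweep on the
derived allele gives negative values. Standardization uses 40 *equal-width*
DAF bins over [0.05, 0.95] (equal-width rather than equal-count, so bin
boundaries do not depend on the data); sites outside the range are dropped,
bins with fewer than two sites are flagged and left unstandardized, and a
precomputed bin table (e.g. from a chromosome-wide or pooled neutral
reference) can be supplied — at desk scale a single 100-kb panel leaves
high-DAF bins too sparse, so the analysis scripts pool 30 neutral panels.

**F_ST** is the Weir–Cockerham (1984) variance-components estimator across
all populations at once (the multi-population estimate, not an average of
pairwise values), from diploid dosages with the heterozygosity terms, or
the haploid reduction (no within-individual component) for phased
haplotypes. Negative estimates are retained. "Global" over a region is the
ratio of summed components. The implementation is checked against an
independently coded nested-ANOVA oracle to 1e-10.

**Empirical p-values** use the add-one rank rule `(#{ref ≥ obs} + 1)/(N+1)`
(ties count as ≥, p is never 0), with `abs` applied first for iHS. At full
scale the reference is every value on the chromosome; the packaged analyses
use all other simulated sites.

## Prioritization and allelic imbalance

Candidates are the variants with r² ≥ 0.5 to the lead. Five boolean
criteria are evaluated from annotation tracks (ortholog-enhancer BED,
regulatory-build BED, ENCODE TFBS BED, per-base GERP scores with the
strict > 2 rule, and conservation calls). A missing track makes its
criterion *unknown* and excluded from the count — not false — so
partially annotated runs remain comparable. Ranking is by satisfied
criteria descending, ties broken by eQTL p ascending (the tie-break is a
package choice; any deterministic order would do, and the eQTL p is the
natural one). Ortholog-enhancer overlap is evaluated against a supplied
BED of ortholog-mapped intervals; no genome liftover is performed.

Allelic imbalance compares per-donor ChIP versus input allelic ratios with
a paired two-sided t-test on log ratios (logs make ratios symmetric, so a
joint A/B label swap inverts the enrichment exactly and leaves p
unchanged); with fewer than 6 donors, where normality is uncheckable, a
Wilcoxon signed-rank test is used instead. Summaries are mean ± s.e.m. on
the natural scale. Donors with non-positive signal are excluded with a
warning; fewer than 3 usable donors is an error.

## The synthetic generators

**eQTL cohort.** Two populations of 100 individuals, 500 SNPs with allele
frequencies uniform in [0.05, 0.5] and local LD from a first-order Markov
copy process on the latent allele uniforms (copy probability 0.9 per
adjacent SNP) — enough LD realism for the permutation and conditioning
machinery, with no demographic history. The causal SNP is the one with
overall MAF closest to 0.3, matching the worldwide frequency scale of the
motivating variant. The target gene is
`β · (dosage − mean) + pop_shift · I(pop₂) + ε` in every condition, with
`pop_shift = 0.3` and the noise SD defaulting to
`sqrt(1 − β²·var(dosage))` so the gene has unit total variance: the planted
effect is then expressed per allele copy *on the scale the rank transform
preserves*, and the fitted coefficient estimates β directly. (Planting on
standardized dosage instead would make the per-copy estimate β/sd(g); test
fixtures that only need detection power, such as the trans-scan
recovery experiments, plant on that standardized scale.) All other genes
are standard-normal noise; raw FPKM for expression filters are
`2^(baseline + value)` with per-gene baselines.

**Haplotypes.** A forward Wright–Fisher simulation of a haploid population
(compiled core), with infinite-sites mutation at a continuous position in
the region, uniform recombination (Poisson number of crossovers per
transmission), and optional positive selection at one site. Forward
simulation was chosen over a backward coalescent because selection and
recombination compose trivially and correctness is easy to audit; the cost
is desk-scale sizing. Defaults: population 400 haplotypes, burn-in
10 N generations (well past the ~2 N coalescent scale), 100 kb with
mutation and recombination densities 2.5e-7 per bp per generation, i.e.
θ = ρ = 20 per region and on the order of a hundred segregating sites in a
200-haplotype sample — a deliberately scaled-down human locus (real θ for
100 kb is ~100; scaling keeps a replicate under a second without changing
any statistic's calibration). Sweeps inject one derived copy after the
burn-in and evolve under selection (default s = 0.25 — a strong sweep — to
frequency 0.7), restarting from the burn-in state when the allele is lost;
exceeding `max_restarts` is an error that reports the count. Positions are
floored to integer bp at the end; collisions (rare under the continuous
model) drop the later site, never the focal one.

**Alignments.** A star phylogeny: each species is the root sequence with
independent substitutions (default 10% per base), and the motif consensus
written into exactly `n_species_with_motif` species at a fixed offset from
the focal column. There is no indel process by default (the column map is
then the identity); gap handling is tested on hand-built blocks. A star
tree cannot emulate phylogenetic correlation between species — conservation
counts on synthetic blocks are exact by construction, which is the point:
the threshold semantics, not the evolutionary model, are under test.

What passing tests on these generators shows: the estimators are unbiased
and calibrated under the generating models, thresholds and filters act at
their stated boundaries, and the pipeline's plumbing is correct end to end.
What they cannot show: robustness to real-data pathologies — batch effects,
genotyping error, population substructure beyond two labels, phylogenetic
non-independence, ascertainment of SNP panels.

## Numerical choices and problem sizes

- Internal coordinates are 0-based half-open everywhere; VCF and MAF
  positions convert at the I/O boundary, BED passes through.
- Multi-allelic and indel records are dropped at VCF read time; haplotype
  sets also drop sites whose ancestral allele is missing or matches
  neither allele (counted, since DAF and iHS are polarity-dependent).
  Ancestral alleles come from the `AA` INFO tag or a side table.
- Degenerate regressions (zero residual variance) report `p = 0`,
  `r2 = 1` rather than NaN; monomorphic genotypes report `p = 1`, flagged.
- Windows scoring exactly the PWM minimum sit on a floating-point boundary
  of the relative scale; comparisons at a relative threshold of 0 are not
  meaningful and the test suite uses −1 ("keep all") there.
- The statistical test suite runs at the sizes its claims need: FWER
  calibration uses one 1000-permutation threshold applied to 500 fresh
  null panels; cis recovery 300 panels; trans recovery 100 replicates of
  1050 genes; selection calibration 200 neutral and 100 sweep replicates
  of the default haplotype spec. These sizes are the study conditions of
  the checks, chosen once.

## Known limitations

- The eQTL model is single-variant OLS; no PEER/SVA covariate discovery,
  no imputation, no multi-variant fine-mapping beyond one-SNP
  conditioning.
- iHS integrates over physical distance; with a genetic map the integrals
  would weight recombination hotspots differently.
- The haploid Wright–Fisher population is panmictic and constant-size;
  Tajima's D under the default spec is mildly negative on average
  (finite-population sampling), well inside the neutral band used by the
  calibration tests.
- The β balancing-selection statistic and ancestral-recombination-graph
  TMRCA estimation are out of scope (the study consumed external
  precomputed scores and an external tool, with Neff = 10000 and
  mu = 2.5e-8 as its run parameters).
- ChIP-seq processing (alignment, peak calling) and chromatin-conformation
  analyses are wet-lab/upstream concerns outside this package.
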