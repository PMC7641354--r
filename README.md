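# fireqtl

Computational dissection of a regulatory variant controlling interferon-β
expression. The package re-implements, as tested R functions plus a
reproducible analysis workflow, the statistical pipeline that links the
non-coding variant rs12553564 — an A→G substitution inside a
lipopolysaccharide-inducible enhancer downstream of *IFNB1* — to the control
of *IFNB1* expression in activated human monocytes:

1. **cis-eQTL mapping** of *IFNB1* on inverse-normal-transformed expression
   (`y = Φ⁻¹((rank−0.5)/n)` per condition), ordinary least squares per SNP
   with the population of origin as covariate, and a 1% family-wise error
   threshold calibrated from 1000 within-population permutations (the
   per-permutation minimum p over all SNPs and conditions); conditional
   scans on the lead variant.
2. **trans-eQTL scanning** of the lead variant against all expressed genes
   with Benjamini–Hochberg FDR at 1% and a minimal effect size |β| ≥ 0.2.
3. **Motif conservation**: JASPAR position frequency matrices converted to
   log₂-odds PWMs (pseudocount 0.8, uniform background), scanned at ≥85%
   min–max relative score in a 21-bp window around the variant across the
   species of a multiz-style alignment; sites detected in **more than 20
   species** are called conserved, and alleles whose best overlapping score
   drops by **more than 10%** are flagged as binding-decreasing.
4. **Selection scans**: Weir–Cockerham variance-components F_ST, Tajima's D
   on 100 kb around the site, EHH/iHS (trapezoid-integrated haplotype
   homozygosity, `uiHS = ln(iHH_anc/iHH_der)`) standardized in 40
   derived-allele-frequency bins over DAF 5–95%, and rank-based empirical
   p-values `(r+1)/(N+1)` against chromosome-wide values.
5. **Variant prioritization**: a five-criterion ledger per candidate in the
   LD block (r² > 0.5) — ortholog-enhancer overlap, predicted regulatory
   element, ENCODE TFBS, GERP score > 2, conserved TFBS — plus paired
   allelic-imbalance tests for ChIP validation data.

Because the underlying cohort (monocyte expression + genotypes) is
controlled-access and the reference resources are versioned downloads, the
package ships seeded synthetic generators that emulate every input with
known ground truth: a two-population eQTL cohort with one planted cis
effect and first-order-Markov LD, a forward Wright–Fisher haplotype
simulator (compiled core) with recombination and partial selective sweeps,
and ortholog alignment blocks with a motif planted in a controllable number
of species.

## Worked example

The numbered scripts under `analysis/` run the whole study on the synthetic
cohort (each is a thin driver over the package functions and writes its
tables under `results/`):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_cis_eqtl.R
Rscript analysis/03_trans_eqtl.R
Rscript analysis/04_motif_conservation.R
Rscript analysis/05_selection_scan.R
Rscript analysis/06_prioritize.R
```

Output of a run (seeds are fixed in the scripts, so this reproduces
exactly):

```
causal variant: rs_sim0326 (MAF 0.30, planted beta 0.50)
FWER threshold (1%, 1000 permutations): p < 1.1e-05
lead variant: rs_sim0326 (p = 1.83e-07, partial R2 = 12.9%) - the planted causal variant
after conditioning on rs_sim0326: 0 significant associations remain
site detected in 30 of 46 species -> conserved (>20 species)
allele impact: relative score 1.000 (A) -> 0.889 (G), drop 11.1% (> 10%: binding decreased)
focal |iHS| = 2.84, empirical p = 0.003 (neutral reference, N = 1838)
top-ranked: rs_sim0326 with 5/5 criteria - the only variant satisfying all five
allelic ratio: input 1.16 +/- 0.05 -> ChIP 2.85 +/- 0.09 (p = 8.01e-07, paired t on log ratios)
```

Reading the numbers: the permutation threshold (p < 1.1×10⁻⁵) is what a 1%
family-wise error rate costs when 500 SNPs × 2 conditions are scanned; the
planted variant is recovered as the lead eQTL and explains ~13% of the
transformed expression variance after the population covariate; nothing
remains once it is conditioned on, as expected when a single causal variant
drives the signal. The A allele is a perfect match to the C/EBP-like motif
(relative score 1.0) and the G allele loses 11.1% of it — past the 10%
impact call — while the site is conserved in 30 of 46 species. In the sweep
panel the focal site's standardized |iHS| of 2.84 sits in the extreme 0.3%
of the neutral reference, and the prioritization ledger singles out the
planted variant as the only candidate satisfying all five criteria.

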