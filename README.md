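# mhctyper

Genotyping a classical MHC class II locus (DQB exon 2) from cloned
amplicon sequences, with the downstream evolutionary and population-level
analyses that validate a first allele catalogue in a non-model species.

The package is aimed at researchers running (or re-analysing)
cloning-and-Sanger MHC surveys: you have a few hundred to a thousand clone
sequences from tens of individuals, you need a defensible allele
catalogue, and you want to know whether the locus behaves like a
single-copy classical antigen-presenting gene.

## What it computes

**Allele calling.** Distinct clone sequences are tallied and low-count
variants are filtered as putative PCR artifacts when they occur at most
twice and lie within 2 nt (Hamming) of a strictly more common retained
sequence; alleles then require support from at least two individuals.
Per-individual genotypes, flags for individuals amplifying more than two
alleles, and Mendelian compatibility of mother–pup pairs (shared allele
or not) complete the quality control.

**Selection tests.** For the 89-codon exon, the 24 antigen-binding-site
(pABS) codons and the 65 remaining codons: mean pairwise amino-acid
divergence *d* with codon-bootstrap standard errors, and modified
Nei–Gojobori dN/dS with Jukes–Cantor correction,

    d = -(3/4) ln(1 - (4/3) p),   p_N = N_d / N,   p_S = S_d / S,

with potential sites weighted by a transition/transversion ratio R,
observed differences averaged over all minimal substitution pathways, and
codon-based Z-tests (`Z = (dN - dS) / SE_boot`) for neutrality and for
positive selection.

**Population genetics.** Weir–Cockerham θ (variance components, ratio of
sums across alleles and loci) with label-permutation p-values; private
alleles, rarefied allelic richness, observed and Nei-unbiased expected
heterozygosity and F_IS per colony; Queller–Goodnight pairwise
relatedness from microsatellites; standardised multilocus heterozygosity
(sMLH).

**MHC similarity vs. genomic background.** A neighbour-joining allele
tree on p-distances, unweighted UniFrac distances between individuals'
allele sets (fraction of spanning branch length not shared), a linear
mixed model of pairwise UniFrac on pairwise relatedness with crossed
random effects for the two individuals, and a binomial GLM of MHC
heterozygosity on sMLH.

**Primer-mismatch amplification bias.** Per-allele Hamming mismatches at
a primer pair's binding sites, shared-vs-unique group comparisons, and
bootstrap allele-detection curves: the expected number of distinct
alleles detected as a function of the number of resampled genotypes,
under thresholds on tolerated primer mismatches.

**Synthetic data.** A first-class generator produces allele pools with
elevated nonsynonymous variability at pABS codons, Hardy–Weinberg
genotypes in two colonies with maternal transmission, clone libraries
with point-error artifacts and optional mismatch-driven amplification
bias, and pedigree-consistent microsatellites — so the whole pipeline is
testable end to end without restricted study data.

## Worked example

```r
library(mhctyper)

cfg <- sim_config(seed = 42)        # two colonies, 56 individuals
st  <- simulate_study(cfg)          # pool, genotypes, pedigree, clones

tal     <- tally_variants(st$clones)
fl      <- filter_artifacts(tal)
catalog <- call_alleles(fl$retained)
s       <- typing_summary(fl$retained, catalog)
ag      <- assign_genotypes(catalog, st$clones,
                            st$genotypes[, c("individual_id", "colony")])
mend    <- check_mendelian(ag$genotypes, st$pedigree)
```

```
clones: 1168  retained: 928  individuals: 56
mean clones/individual: 16.57  mean clones/allele: 74.8
Mendelian-compatible pairs: 20 / 20
```

Of the 1168 simulated clone sequences, 240 are filtered as putative PCR
artifacts; the retained 928 support 12 alleles (each cloned from ≥ 2
individuals). With unbiased "intronic" primers there is no allelic
dropout, so every mother–pup pair shares an allele.

```r
selection_table(catalog$sequence, tstv_ratio = 1, n_boot = 999, seed = 1)
```

```
    region      dN   dN_se       dS    dS_se Z_neutral p_neutral Z_positive p_positive
1     exon 0.01396 0.00405 0.007710 0.004307      1.06  0.290571       1.06   0.145286
2     pABS 0.04394 0.01176 0.000523 0.000546      3.69  0.000226       3.69   0.000113
3 non_pABS 0.00234 0.00163 0.009741 0.005577     -1.27  0.202900      -1.27   0.898550
```

Nonsynonymous substitution dominates at the antigen-binding codons
(dN ≫ dS, one-sided p ≈ 1e-4) but not elsewhere — the signature of
balancing selection concentrated on the peptide-binding region that the
generator implants and the test recovers.

```r
f <- fst_permutation_test(ag$genotypes, n_perm = 999, seed = 2)
#> MHC FST = 0.0020 (permutation p = 0.335)
```

Both colonies draw from one allele-frequency law, and θ is
correspondingly indistinguishable from zero.

## Design notes

The methods vignette (`vignettes/mhc-clone-genotyping.Rmd`) documents the
model assumptions, what the synthetic generator does and does not
emulate, the artifact-filter rule and its rationale, the calibration
caveat of the codon Z-test at sparse divergence, and all numerical
choices (tie-breaking, rarefaction sizes, rooting invariance of UniFrac,
treatment of multi-allele individuals).
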