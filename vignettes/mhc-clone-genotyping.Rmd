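---
title: "Genotyping a classical MHC class II locus from cloned amplicons: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping a classical MHC class II locus from cloned amplicons: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhctyper)
```

## The problem

Classical MHC class II loci such as DQB are among the most polymorphic
genes in vertebrate genomes. A standard route to a first allele catalogue
in a non-model species is to PCR-amplify the 267 bp protein-coding exon 2
(which encodes the beta-1 peptide-binding domain), clone the products,
and Sanger-sequence a modest number of clones per individual. This
produces three intertwined inference problems that `mhctyper` addresses
as one pipeline:

1. **Allele calling.** Cloned PCR products carry polymerase point errors,
   so the set of distinct clone sequences over-counts the true alleles.
   Low-count variants lying within a couple of nucleotides of a more
   common sequence must be filtered before alleles are accepted, and
   acceptance should require support from more than one individual.
2. **Locus validation.** If the primers amplify a single classical locus,
   individuals should carry one or two alleles, and mother-offspring
   pairs should share at least one (Mendelian compatibility).
3. **Evolutionary and population context.** A classical antigen-presenting
   locus is expected to show an excess of nonsynonymous substitution at
   the antigen-binding codons, little population structure relative to
   neutral markers in a panmictic population, and an association between
   MHC similarity and genome-wide relatedness.

A fourth, methodological question motivates the final module: partial-exon
primers that anneal *inside* the exon can fail to amplify alleles that
carry mismatches under the primer binding sites, biasing diversity
estimates downward. The package quantifies per-allele primer mismatches
and computes bootstrap allele-detection curves under mismatch thresholds.

## The synthetic-data generator

Every stage is testable without restricted study data because the package
ships a generator (`sim_config()`, `simulate_study()`) that produces data
with the statistical structure the analysis assumes. Its defaults encode
the study conditions the pipeline targets:

* a pool of 19 distinct 267 bp coding alleles derived from a founder
  sequence, with substitution placement favouring the 24 antigen-binding
  (pABS) codons by a factor of 5 and, within those codons, favouring
  amino-acid-changing substitutions by the same factor. Each derived
  allele carries `1 + Poisson(1)` substitutions, which yields roughly
  30-35 variable nucleotide sites and 22-26 variable amino-acid sites
  across the pool — the scale observed in real exon-2 allele catalogues
  of this size. With the multiplier at 1 the generator is a neutral null:
  placement and base choice are uniform over stop-free changes, and no
  peptide-uniqueness constraint is applied (that constraint would itself
  select against synonymous variants);
* allele frequencies drawn once from a Dirichlet(1) and sorted, so the
  pool contains both common and rare alleles;
* two colonies ("SSB", "FWB") of 16 mothers each sharing one
  allele-frequency law (the null of no structure), with 10 sequenced
  mother-pup pairs and 2 motherless pups per colony — 56 individuals in
  all. Mothers are Hardy-Weinberg draws; each pup inherits one uniformly
  chosen maternal allele plus one population draw;
* clone libraries of 7-32 clones per individual (uniform), matching the
  observed range in cloning studies of this design; each clone's template
  is drawn from the carrier's two gene copies with weight
  `exp(-bias_beta * primer_mismatches)` (uniform at the default
  `bias_beta = 0`, i.e. primers annealing in conserved flanking introns);
  with probability `artifact_rate = 0.2` a clone receives 1-2 substitutions
  at uniform positions with uniform base choice, mimicking the roughly
  one-fifth of clone sequences such studies discard as artifacts;
* 41 microsatellite loci with 4-10 alleles each, i.i.d. multinomial
  within individuals but pedigree-consistent (pups inherit one maternal
  allele per locus), so parent-offspring pairs carry the expected
  first-degree relatedness signal.

What the generator deliberately does **not** emulate: deep,
coalescent-shaped allele genealogies (real MHC allele pools are far more
diverged than a star-shaped pool of recent mutants, often showing
trans-species polymorphism), chimeric PCR artifacts, microsatellite
mutation processes, and genotyping dropout other than primer-mismatch
bias. Consequently, passing tests demonstrate correctness of the
*computations* and calibration of the *statistics under the stated null*,
not that the pipeline's numerical outputs match any particular empirical
dataset.

## Allele calling rules

`tally_variants()` counts distinct sequences; `filter_artifacts()`
discards a variant iff its total clone count is at most 2 **and** it lies
within 2 nucleotides (Hamming) of a strictly more common retained
sequence. Candidates are visited from most to least common so chains of
errors collapse onto their source allele; low-count variants with no near
neighbour are retained but flagged, since they may be rare genuine
alleles. The option `doubleton_same_individual_only` additionally
restricts discardable 2-clone variants to those cloned from a single
individual — the pattern typically *observed* in real data — but it is
off by default: identical polymerase errors arise independently in two
individuals often enough (about one coincidence per thousand clones under
the generator's error model) that treating cross-individual doubletons as
unfilterable would promote them to false alleles.

`call_alleles()` promotes retained variants supported by at least two
individuals (`min_individuals = 2`); the observed minimum clone count per
allele in such datasets (seven) is an outcome, not a rule, so
`min_clones` defaults to 1 and is configurable. Alleles are named
`ArGa-DQB*01`, `ArGa-DQB*02`, ... in decreasing clone count with ties
broken by sequence, which makes naming deterministic.

Under the generator's study conditions the caller is exact in practice:
over 200 simulated libraries at `artifact_rate = 0.1` and at least 10
clones per individual it recovers every allele whose genuine clones occur
in two or more individuals, with zero false alleles (the acceptance suite
recomputes this). Alleles carried only by unsampled or single individuals
are not discoverable by any caller under the acceptance rule — recovery
is therefore measured against that discoverable truth.

## Selection tests

`translate_alignment()` applies the standard genetic code and treats an
internal stop codon as an error (a coding MHC exon must translate
cleanly). The codon partition is shipped as data, not code: the default
24 pABS codons follow the human DRB1-derived antigen-contact assignment
within the 89-codon exon, and any other partition can be supplied.
Codons are attributed whole to one region.

`nei_gojobori_dnds()` implements the modified Nei-Gojobori method:
potential synonymous sites are computed per codon position with
transitions weighted by a transition/transversion ratio `R` against
transversions (changes to stop codons excluded from the weighting), and
observed synonymous/nonsynonymous differences per codon pair are averaged
with equal weight over all minimal substitution pathways, excluding
pathways that pass through a stop codon (if every pathway does, all are
used). Proportions are Jukes-Cantor corrected,
`d = -(3/4) log(1 - (4/3) p)`, with `p >= 0.75` flagged undefined, and
averaged over all unordered sequence pairs. The default `R = 2` reflects
common practice for mammalian nuclear sequence; analyses of the package's
own synthetic data use `R = 1` because the generator's substitution
spectrum is uniform. Standard errors and the Z-tests
(`codon_z_test()`, one-sided for positive selection or two-sided for
neutrality) use bootstrap resampling of codon columns within the tested
region (999 replicates by default).

The region contrast `divergence_region_test()` is a paired t-test over
sequence pairs of per-pair amino-acid divergence (pABS minus non-pABS).
Sequence pairs overlap in sequences and are not independent, so the
paired construction is a descriptive convention rather than an exact
test; it is the natural reading of the published analysis and is exposed
as such.

### A calibration caveat

At low divergence — a few dozen variable sites among 19 alleles, as the
generator produces — the one-sided codon Z-test is markedly
anticonservative: with the generator fully neutral the test rejects at
nominal 0.05 about 14-15% of the time (200 seeds, 999 bootstrap
replicates). The point estimates are unbiased (mean dN - dS is
indistinguishable from 0) and the bootstrap standard error is the right
size *on average*, but it is nearly uncorrelated with the realized
deviation, so the normal approximation of the ratio has heavy tails
(null 95th percentile of Z near 3). Using the bootstrap variance of the
difference instead of the sum of variances does not change this. The
effect shrinks as divergence grows; at the divergence of real MHC allele
catalogues the approximation is much better. Users should treat marginal
Z-test p-values on sparse alignments with caution; the package keeps the
conventional construction deliberately.

## Population genetics

`weir_cockerham_fst()` implements the 1984 variance-components estimator:
per allele and locus the among-population (a), among-individual (b) and
within-individual (c) components, combined across alleles and loci as the
ratio of summed components. Note that on duplicated identical populations
the estimate is slightly *negative*, not zero — the among-population
variance is exactly 0 but the finite-sample correction terms remain; this
is a property of the estimator, verified in the tests against a nested-
ANOVA mean-squares computation. `fst_permutation_test()` permutes
individual labels and applies the `(1 + k)/(n + 1)` rule so p is never 0.
MHC genotype tables are treated as one diploid locus with homozygotes
doubled; individuals flagged with more than two alleles are excluded from
all diploid statistics (FST, heterozygosities, Fis) but kept for
detection curves and Mendelian reporting, since allele presence does not
require diploid validity.

`diversity_summary()` reports private alleles, hypergeometric rarefied
allelic richness (rarefaction size = the smallest population's typed gene
count), observed heterozygosity, Nei's small-sample unbiased expected
heterozygosity, and `Fis = 1 - Ho/He`. `queller_goodnight_r()` computes
the Queller-Goodnight estimator with reference allele frequencies over
*all* individuals including the focal pair (the choice differs between
published implementations, so it is explicit and configurable by
subsetting the input), numerators and denominators summed over loci
before the ratio, and the two directional estimates averaged. `smlh()`
standardises an individual's multilocus heterozygosity by the mean
heterozygosity of the loci at which it was typed; with complete data the
population mean is exactly 1.

## Allele trees, UniFrac and association models

`build_nj_tree()` runs Saitou-Nei neighbour joining on nucleotide
p-distances; negative branch-length estimates are clamped to zero because
UniFrac requires non-negative lengths. `unifrac_matrix()` computes
unweighted UniFrac between individuals' allele sets as the fraction of
the branch length of the subtree spanning the union that is not on both
sets' own spanning subtrees. Sharing is decided from the leaf bipartition
each edge induces, which makes the measure invariant to rooting (tested);
this "spanning subtree" form differs from rooted implementations that
classify an edge by its descendant set, which are root-dependent.
Branch lengths can be switched to unit (topological) lengths, since the
published description does not pin the choice; the default uses the NJ
lengths.

`fit_unifrac_lme()` models pairwise UniFrac on pairwise relatedness over
unordered pairs (each pair once) with crossed random intercepts for the
two member identities, the standard device for non-independence of
pairwise observations; the fixed effect is tested with an F-test using
Satterthwaite denominator degrees of freedom. Published mixed-model
degrees of freedom conventions vary, so the df are reported, not forced.
`fit_het_glm()` is a binomial GLM of MHC heterozygosity on sMLH with a
likelihood-ratio chi-square test; complete-separation and constant-
predictor designs return flags instead of tests.

## Primer-mismatch bias and detection curves

`primer_mismatch_count()` compares the forward primer with its
sense-strand window and the reverse-complemented reverse primer with its
window, summing the two Hamming distances by default (`mode = "max"` is
available because "maximum Hamming distance" is ambiguous in prose
descriptions of this analysis). Windows come from configured coordinates
or from the minimum-Hamming placement over all offsets. The shipped
primer pair is a clearly labelled synthetic placeholder delimiting a
141 bp partial-exon amplicon on the synthetic reference (the real
historical primer sequences are not public data in this packaging);
analyses of real data must supply the actual primers via the config.

`allele_detection_curve()` resamples whole genotypes (both alleles enter
together) with replacement, `n_rep = 999` per sample size, and counts
distinct alleles within a mismatch threshold; it reports the mean and the
bootstrap standard deviation (not the standard error) across replicates.
Curves for larger thresholds dominate pointwise exactly when computed
under one seed, because the same resamples are reused across thresholds.

## Numerical and interface choices

* Coordinates are 1-based closed intervals; codon indices run 1-89.
* Exon trimming (`trim_to_reading_frame()`) is alignment-free when the
  reference exon's 15-mer flanks match exactly, falling back to
  mismatch-tolerant placement (substitutions first, indels only as a
  last resort, and an indel-containing placement is an error). The
  packaged reference exon is synthetic; trimming 270 bp alignments to
  the 267 bp frame discards the trailing 3 nt by default, configurable.
* All tables are UTF-8 CSV with headers; missing microsatellite
  genotypes are empty cells and half-missing diploid entries are errors.
* Determinism: every stochastic routine takes a seed; one configuration
  (including its seed) yields byte-identical outputs.
* Problem sizes in the shipped tests and acceptance script — 200-seed
  recovery and calibration loops, 199-999 bootstrap/permutation
  replicates, populations of 26-56 individuals — were chosen as the
  smallest sizes at which the checked properties are statistically
  clear-cut.

## Known limitations

* Chimera detection is out of scope; the artifact model is point error
  only.
* The codon Z-test anticonservativeness at sparse divergence described
  above.
* Unweighted UniFrac need not satisfy the triangle inequality on
  multifurcating trees; no metric property beyond symmetry, zero
  self-distance and the [0,1] range is claimed.
* The paired region contrast treats sequence pairs as independent
  replicates, which they are not; its t statistic is descriptive.
* Rarefied richness uses the hypergeometric expectation per locus; loci
  with fewer typed genes than the rarefaction size are rarefied at their
  own gene count.
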