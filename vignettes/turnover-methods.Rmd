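---
title: "Models and methods for binding-site turnover analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for binding-site turnover analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfbsturnover)
```

This vignette documents the models behind `tfbsturnover`, the assumptions
they make, the tunable parameters and their defaults, the design choices
made where the design was genuinely open, and what the synthetic-data tests
do and do not demonstrate about real data.

## 1. PWM scoring and affinity classification

A binding site of length $L$ is scored against a position weight matrix
$M$ (columns sum to one) and a background distribution $b$ as

$$ S = \sum_{k=1}^{L} \log_2 \frac{M[s_k, k]}{b[s_k]} \quad \text{(bits)}, $$

so $S = 0$ means motif and background explain the sequence equally well.
Under the usual additivity assumption, $S$ is proportional to the physical
discrimination energy of the protein for the sequence, and a point mutation
$a \to a'$ at position $k$ changes it by

$$ \Delta S = \log_2 \frac{M[a', k]}{b[a']} - \log_2 \frac{M[a, k]}{b[a]}, $$

independent of the other positions. Mutations are classified
affinity-increasing when $\Delta S \ge \tau$, affinity-decreasing when
$\Delta S \le -\tau$, and uncertain otherwise.

**Parameters.**

* `tau` (bits, default 1): classification threshold. One bit is a two-fold
  change in the likelihood ratio; PWM predictions of the *direction* of an
  affinity change are unreliable below roughly this magnitude, so
  small-effect mutations are deliberately set aside as uncertain rather
  than misassigned. Results should be (and, on synthetic data, are) robust
  for thresholds between 0 and 2.
* `background` (default uniform): the background composition. Uniform makes
  toy examples analytic; supply genome composition when you have it. The
  boundary $|\Delta S| = \tau$ counts as classified ("within the bound" is
  read as the strict interior), so classification is deterministic.
* `pseudocount` (default: 0.01 per cell, applied only when the matrix
  contains zeros): keeps log-ratios finite for count matrices with empty
  cells. Matrices given explicitly with `pseudocount = 0` are honored as
  is; scoring an allele with zero motif probability then returns
  $-\infty$, which orders correctly in every comparison the package makes.

**Motif search.** `best_match()` scans every window on both strands and
breaks exact ties deterministically (lowest offset, then plus strand).
Footprints are strandless, so both strands are always scanned. In
`extract_tfbs()` the footprint is extended by `flank = 5` bases on each
side before the search, and the matched core columns — not a re-search —
are used to cut the orthologous and haplotype sequences, so all species are
scored over the same alignment columns on the strand chosen in mel. The
ancestor is likewise scored on those fixed columns; re-searching each
species separately could let the "core" wander between species and would
decouple the per-column variant bookkeeping from the presence calls. A
column is assigned to at most one core (first by extraction order), which
defines the spacer class as every reference column outside all cores.

## 2. Alignment filters and variant calling

Sites whose mel or sim sequences — reference or any haplotype — contain an
alignment gap in the core are excluded (reason `indel`); affinity scoring
across indels is not meaningful and gap-adjacent alignment error would
contaminate the polymorphism counts. Sim sites require at least two of the
six haplotypes non-missing. Columns with more than two observed bases are
excluded (reason `triallelic`): the MK and SFS machinery assumes biallelic
sites, and multiply-hit columns violate the single-mutation reading of a
variant. All exclusions are counted and reported in the run's exclusion
log.

## 3. Ancestral states and polarization

Ancestral bases at the mel–sim common ancestor are inferred by maximum
parsimony on the fixed topology `((mel,(sim,sec)),(yak,ere))`, implemented
as unit-cost dynamic programming re-rooted at that ancestor, which yields
the exact set of most-parsimonious states per column. If the set is not a
singleton the site is `ambiguous` and dropped (counted). Likelihood-based
reconstruction on such shallow trees gives practically identical states;
parsimony has no nuisance parameters and is exactly testable against
brute-force enumeration, which the test suite does for all $4^5$ single
columns. sec is used only to stabilize reconstruction (it compensates for
missing data in the sim reference), never as an ingroup sample.

A biallelic variant is polarized to the lineage whose sample carries the
non-ancestral allele; a derived allele seen in both lineages (possible
under homoplasy or ancestral polymorphism) cannot be assigned and is
dropped with reason `derived_in_both` — the package reports how many. On
data simulated with short branches, polarization recovers the planted
lineage, allele, and fixed/segregating status in over 99% of sites.

## 4. Turnover events

Presence is called per lineage by `S \ge` cutoff. Two cutoff modes exist:
a fixed score of 0 bits (site more likely motif than background), and
TF-specific empirical cutoffs taken as the value at rank
$\lceil 0.8\,n \rceil$ of that TF's footprint scores ranked in descending
order (i.e. the lower 20% quantile). The descending-rank reading of "the
80% quantile" is a convention choice — the phrase is ambiguous between the
upper and lower quantile — and the `q` argument makes it overridable. The
(mel, ancestor, sim) presence pattern maps onto an eight-way event table;
the two patterns implying parallel gain or loss are labelled `complex` and
counted, never merged, because reference-ascertained data should rarely
produce them and their frequency is itself a useful diagnostic.

## 5. Generalized MK tests

For each functional class on one lineage the package counts fixed
differences and common polymorphisms — segregating variants with derived
allele frequency at least `freq_cutoff = 0.15` of the non-missing sample.
The frequency denominator is the non-missing allele count at that site (a
choice: sample-size-corrected frequencies are the only consistent option
with variable coverage). The cutoff purges most weakly deleterious
variants, which otherwise depress the polymorphism counts of selected
classes and mask positive selection. Each class is compared with a neutral
reference class by two-sided Fisher exact test on the (fixed, poly) 2×2
table.

With coding data the reference is the synonymous no-change class: codon
changes between two preferred or two unpreferred codons
(`classify_synonymous()`). The shipped preferred-codon table is a default
single-preferred-codon-per-amino-acid table for *D. melanogaster*
(C/G-ending major codons in the Akashi tradition); it is an argument, not a
constant, because preferred-codon definitions differ among studies.
Synthetic datasets contain no coding sequence, so `run_pipeline()` defaults
to spacers as the neutral reference there.

The sim-lineage analysis can be restricted to sites with ancestral PWM
score at least `anc_score_min` (conventionally 2), excluding sites gained
on the mel branch whose sim orthologs were never under selection; the
threshold is a parameter because the conclusion should be, and is, robust
to it.

**Mutational-input test.** `mutational_probabilities()` enumerates every
possible point mutation on the inferred ancestral site sequences, weights
each by its relative rate in a 4×4 mutation matrix (by default uniform; in
practice estimated from fourfold-degenerate polymorphism), classifies it by
$\Delta S$, and averages the per-position class probabilities over all
positions of all sites. The three outputs sum to one by construction and
the test suite requires exact agreement with brute-force enumeration.
Observed class counts are then tested against these input probabilities
(renormalized over the two classified classes) by chi-square with a
Monte-Carlo null — multinomial draws of the same total — because expected
counts can fall below 5; the reported p uses the $(1 + k)/(R + 1)$
small-sample correction.

## 6. Ascertainment model

All footprints were discovered in a single mel assay. The model treats the
assayed allele as one haplotype drawn uniformly at random from the mel
sample — the concrete reading of "a random mel allele is used in the
assay", and the assumption from which everything else follows — and gives
the weaker-affinity allele probability $f$ of escaping detection. The
high-affinity allele is assumed always detectable (every site in the data
was detected). For derived count $i$ of $n$:

* affinity-decreasing (derived allele weak): detection probability
  $1 - f\,i/n$;
* affinity-increasing (ancestral allele weak): $1 - f\,(n-i)/n$;
* substitutions are the $i = n$ case ($1-f$, respectively $1$).

The neutral SFS becomes $\propto (1/i)\,d(i)$, *weighted then normalized*.
An alternative formulation would condition each site on its own
detectability before normalizing; the two coincide here because detection
is a Bernoulli filter applied independently per site, which is exactly what
the weighting expresses — the forward simulation in the test suite, which
implements the filter literally, confirms the weighted form. Expected
neutral MK ratios scale as
$r(f) = r_0 \cdot \frac{w_{\mathrm{fix}}(f)/w_{\mathrm{fix}}(0)}
{w_{\mathrm{poly}}(f)/w_{\mathrm{poly}}(0)}$ with
$w_{\mathrm{fix}} = d(n)$ and $w_{\mathrm{poly}}$ the $1/i$-weighted sum of
$d(i)$ over classes at or above the frequency cutoff; $r$ falls with $f$
for the decreasing direction and rises for the increasing one.

$f$ is estimated conservatively per TF as the fraction of observed weak
alleles whose site score falls below the lowest footprint score of that TF
(the "detection limit"), pooled across TFs by variant-weighted mean. $f$
is a per-TF scalar; per-site detection limits are not identifiable from
presence-only data.

## 7. Site frequency spectra

Variable sequencing coverage is handled by projection: each segregating
site with coverage at least the target (default 150 of a maximum 162) is
downsampled hypergeometrically. The default mode is the deterministic
expectation (the full hypergeometric pmf contributes fractionally to each
class), which is reproducible and commutes with pooling; `sample` mode
draws one projection per site under a seed, reproducing the procedure of
choosing 150 alleles at random. Sites below the target are dropped and
counted. Tajima's D is computed from the projected spectrum with the
standard variance constants; an excess of rare variants gives negative
values.

## 8. The synthetic-data generator

`simulate_dataset()` produces the complete input bundle with known truth:

* **Motifs and cores.** PWM columns are symmetric-Dirichlet draws
  (`pwm_concentration = 0.3`, informative but degenerate motifs of length
  8); ancestral cores are sampled from the motif distribution itself, so
  they score high but span a range of affinities, as footprint sites do.
* **Divergence.** Sequences evolve along the fixed five-taxon scaffold by
  independent per-branch substitutions (no full Wright–Fisher forward
  simulation — desk-scale and exactly controllable, sufficient to exercise
  every statistic). The neutral per-site substitution probability is
  `branch_scale` (default 0.02) times the branch's relative length; on the
  mel and sim tip branches, core mutations have their rate multiplied by
  the Kimura relative fixation weight $2\gamma/(1-e^{-2\gamma})$ of their
  affinity class ($\gamma_{inc}$, $\gamma_{dec}$, both 0 = neutral by
  default).
* **Polymorphism.** Segregating site numbers follow Watterson's
  expectation at `theta = 0.02` per site; derived-allele frequencies are
  drawn from the neutral $1/i$ spectrum, or from the standard
  Poisson-Random-Field selected density when the class's $\gamma$ is
  nonzero. Sample sizes are 162 mel and 6 sim haplotypes.
* **Missing data.** Per-site mel coverage is $162 - \mathrm{Bin}(40,
  0.15)$ (most sites at coverage 150+, emulating variable short-read
  coverage); sim haplotype bases are missing independently at rate 0.1.
* **Ascertainment.** One mel haplotype per footprint is designated the
  assay allele; any classified core mutation whose weak allele that
  haplotype carries hides the footprint with probability `f_true`. The
  truth table records everything pre-filter, so filtered analyses can be
  compared against the unfiltered truth. The same single-allele filter, in
  per-site form (`simulate_ascertained_sfs()`), is the forward simulation
  that validates the analytic ascertainment spectrum.

**What the synthetic data does not emulate:** recombination and linkage,
demography (growth, sweeps), alignment error, indel polymorphism (tests
exercise the indel filter with hand-built cases), overlapping footprints,
and real motif structure. Passing tests therefore demonstrate the
correctness and calibration of the statistics under the model's own
assumptions — not that real Drosophila data satisfy those assumptions.

## 9. Numerical and testing choices

* **Problem sizes.** The test-suite calibration uses 500 replicates with
  class counts of order 500–700, at which the discreteness of the exact
  tests is negligible and rejection rates sit at the nominal 5% within
  Monte-Carlo error; the mutational-input calibration uses 2000
  observations per replicate for the same reason. Power replicates scale
  the fixed counts of the decreasing class by the package's own fixation
  weight at $\gamma = 1$. Forward-simulation checks of the ascertainment
  spectrum use 8000 pre-filter sites at $n = 162$, compared bin-wise
  within simultaneous (Bonferroni) 95% binomial bands.
* **Determinism.** Every stochastic routine takes a seed; identical
  configuration and seed give byte-identical outputs, which the tests
  assert.
* **Degenerate inputs.** Zero-margin MK tables return p = 1 with a
  warning; empty spectra make Tajima's D an error rather than NaN;
  ambiguity codes in sequences raise a classed condition
  (`tfbs_ambiguous_sequence`) so callers decide about exclusion; a
  mutation observed in a zero-probability class floors the Monte-Carlo p
  at its resolution with a warning.
* **Coordinates.** All R-facing coordinates are 1-based closed intervals
  (the R/Bioconductor convention); BED-like inputs are 0-based half-open
  and converted at the boundary by `read_footprints()`.

## 10. Known limitations

* The PWM energy model is additive; epistasis within sites and
  dinucleotide preferences are out of scope, as is any thermodynamic model
  beyond the log-ratio score.
* The ascertainment model covers neutral expectations only; joint
  inference of $f$ with selection parameters (or an $\alpha$-style
  estimate of the adaptive fraction) is deliberately not attempted.
* Ancestral reconstruction ignores uncertainty (ambiguous sites are
  dropped, not integrated over).
* The MAF reader supports the plain UCSC dialect (stitching in file
  order) and is intended for small extracted regions, not genome-scale
  files.
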