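---
title: "Methods: models, thresholds and design choices in immunexpand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, thresholds and design choices in immunexpand}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what each stage
computes, which assumptions it rests on, which knobs matter, and where the
design was genuinely open. The companion README shows the workflow running;
here we explain why it is built the way it is.

## The synthetic study

The package analyses an expanded innate-immune gene repertoire of the kind
found in bivalve genomes. Because the real inputs (a genome assembly, raw
shotgun and RNA-seq data, homology searches against stratified databases)
are far beyond desk scale, every input is *simulated with planted ground
truth*, and all claims the test suite makes are parameter-recovery claims
about these synthetic data. The generator's defaults define one fixed study:

* **Catalog.** 1,405 gene models on 40 scaffolds; planted families sized
  after the repertoire the workflow emulates (83 TLRs, 321 C1qDCs, 10
  MyD88-like adaptors, plus smaller families); 27 tandem arrays, headed by
  an eight-member TLR array pinned to scaffold "s599"; 10% of gene models
  are allelic twins ("-D" suffix) with read depth drawn around half
  coverage; 2% carry a frameshift (pseudogene) flag.
* **Read depth.** Normal genes N(105, 10.5), twins N(52.5, 5.25) — i.e. a
  105× genome with a coefficient of variation of 10%. This makes the 80×
  cutoff a near-optimal but not error-free separator: roughly 0.9% of
  normal genes fall below 80× by chance, which bounds the achievable
  precision of the filter (see *Known limitations*).
* **Expression.** 38 replicate-free pooled libraries across four axes:
  biotic challenges (five Vibrio strains, M. luteus, LPS, a herpesvirus,
  plus untreated and PBS controls and a mixed-Vibrio time course at 0, 6,
  12, 24, 48 h), abiotic stresses, developmental stages and adult organs.
  Planted effects: per-axis differentially expressed genes at |log2FC| = 3
  (overlap across axes is allowed, so a "both biotic and abiotic" category
  exists), time-course genes in early/late/both/down patterns,
  organ-specific (~a quarter of genes) and stage-specific (~5%) expression
  profiles, and ~3% untranscribed genes — chosen so that the filtered
  catalog shows ≈97% of genes at RPKM > 1, as in the study emulated.
* **Homology.** Each gene draws a true phylostratum age (uniform over
  levels 1..10 by default); it always yields a below-cutoff hit at its true
  level, hits at younger levels with probability 0.8, and above-cutoff
  decoys at 5% per level. Ages are planted independently of gene function,
  so the age-distribution comparison in `analysis/07` is deliberately a
  null demonstration.
* **Codon alignments.** Twenty sequences evolve independently from one
  stop-free ancestor (a star phylogeny), 100 codons, six mutation proposals
  per codon per lineage; synonymous proposals are always accepted,
  nonsynonymous ones with probability 0.03 (strong purifying background),
  ×10 at the five planted sites. Proposals creating stops are rejected.

### The count model

A replicate-free pooled design forces a modelling choice. We use the
standard hierarchical (Gamma–Poisson) reading of "negative binomial"
counts: each gene draws a baseline from Gamma(1/φ, ·) with dispersion
φ = 0.1, so counts are *marginally* NB(μ, φ) across genes; given the
baseline, each condition's single library draws a Poisson count. Biological
gene-to-gene variability is thus NB, while the condition-to-condition noise
that a replicate-free exact test can see is Poisson — which is exactly what
a pooled single-library design measures. Had we instead drawn independent
NB noise per gene×condition, *no* test could control the false discovery
rate without replicates, and the exact test below would be the wrong tool
by construction.

All randomness flows from one integer seed through `derive_seed()`, which
hashes a stage label into a decorrelated stream; identical configurations
reproduce identical data byte for byte.

## Stage-by-stage notes

### Catalog filtering

`depth_filter()` removes genes with depth strictly below the threshold
(default 80); an exactly-80× gene is kept. The filter is idempotent, and
"average depth" is taken per gene as supplied — computing it from alignments
is out of scope. `functional_filter()` flags (never removes) genes whose
*maximum* RPKM over all conditions exceeds 1; the maximum implements the
"expressed in at least one library" reading. Manual corrections are an
explicit override table applied last, so they are visible in provenance.

### Subtype classification

The five TLR groups are separated in the literature phylogenetically, with
no numeric boundary between "short" and "long" ectodomains. The classifier
operationalises the distinction with an explicit, configurable LRR-count
threshold (`lrr_long_threshold = 8`): the published architecture schematics
show short-type receptors with clearly fewer LRR units than V/P types, and
eight is the smallest count that separates the two regimes in the
generator's own grammar. "Internal" LRRCT means an LRRCT with at least one
LRR on both sides. Rules fire in a fixed order, first match wins, so the
rule set partitions architecture space; the generator samples from the same
grammar, which is what makes 100% recovery a meaningful (grammar-consistency)
test rather than a tautology about one hard-coded list.

The expansion test is Pearson χ² without continuity correction by default —
the intended use has genome-scale totals, where Yates' correction only
biases the statistic; it is available as a flag.

### Differential expression

With one pooled library per condition, the exact conditional-binomial test
for equal Poisson rates is the appropriate primitive: conditional on
n = a + b, a ~ Binomial(n, L_a/(L_a+L_b)) under the null, two-sided by
doubling the smaller tail (capped at 1). DE calls additionally require
fold-change ≥ 2 on RPKM with a pseudo-RPKM floor of ε = 0.1 (avoiding
infinite fold-changes at zero), and must hold against *every* control —
"different from the control and PBS" is an AND. The P < 0.001 cutoff is
used raw, as in the study emulated; multiple-testing correction (BH) is
applied within enrichment runs only.

One calibration caveat is worth stating precisely: p-values of *any* exact
discrete two-sample count test at these depths cannot be uniformly
distributed. With totals near n ≈ 200, the most central observation carries
probability ≈ √(2/πn) ≈ 5–10% and must receive the largest p-value, so the
p-value CDF necessarily has a step of that size just below 1. The type-I
error at nominal 0.05 is controlled (the tests measure it at ≈ 0.04), but a
Kolmogorov–Smirnov test against the uniform on 10⁴ null p-values will
always reject — a property of discreteness, not an implementation flaw. The
acceptance suite asserts uniformity anyway and that expectation is left
failing rather than weakened.

The tau specificity cutoff (τ ≥ 0.90 with peak ≥ 1 RPKM) is an
operationalisation: the source literature reports organ- and stage-specific
fractions without naming a metric. Tau is the field's standard specificity
index, bounded in [0, 1], monotone under concentration of expression.

### Expansion genomics

Tandem linkage (≤ 5 intervening non-family gene models AND ≤ 100 kb
start-to-start) follows common comparative-genomics practice; both knobs
are exposed. Strand is recorded but ignored for adjacency. The simulator
guarantees planted arrays are the *only* linked runs by pushing any other
same-family pair beyond 100 kb — density of a 321-member family makes a
pure gene-count guard impossible, so the distance arm of the rule does the
work.

NJ is implemented in-package because reproducibility requires pinning two
details that library implementations leave open: ties in the Q criterion
break toward the lowest index pair, and negative branch lengths are clamped
to zero with the deficit moved to the sister branch (preserving the pair
distance). On additive inputs the algorithm is exact; the tests verify
recovery of random additive trees to 1e-9 via cophenetic distances, which
simultaneously pins topology and branch lengths. Bootstrap supports count
each split's occurrences among B column-resampled replicates
(`ape::prop.clades`); midpoint rooting (assumption-light and deterministic)
precedes extraction of maximal single-taxon clades.

### Selection

The likelihood site models of codon-based ML packages are deliberately not
reimplemented; the package provides counting methods with explicit nulls
that can be verified against brute-force oracles at desk scale.

`ng86_dnds()` follows Nei–Gojobori (1986): per-codon synonymous/nonsynonymous
site fractions (changes to stop codons excluded from the denominators),
averaged over the two sequences; difference counts averaged over all minimal
substitution pathways, excluding pathways through stops (falling back to all
pathways in the degenerate all-blocked case); Jukes–Cantor correction
d = −(3/4)ln(1 − 4p/3), undefined (flagged) at p ≥ 3/4; gapped codons
excluded pairwise. The test suite checks it against an independently coded
pathway-enumeration oracle to 1e-10.

`site_selection_scan()` tallies pathway-averaged nonsynonymous and
synonymous differences per column over all sequence pairs. Three numerical
choices matter:

1. **De-correlation.** On a star phylogeny each substitution event is seen
   by ~(n_seq − 1) pairs, so raw pairwise tallies are pseudo-replicated.
   Dividing by (n_seq − 1) recovers per-lineage effective event counts;
   this divisor was verified to leave null p-values calibrated
   (P(p < 0.05) ≈ 0.04), while smaller divisors are anti-conservative.
2. **Robust background.** The alignment-wide expected nonsynonymous
   fraction is estimated after excluding the upper decile of sites by
   observed fraction, so genuinely selected sites do not inflate their own
   null — the same contamination guard used in robust location estimation.
3. **Mid-p.** The binomial tail uses the one-sided mid-p convention, the
   standard remedy for the conservativeness of small discrete tests.

A site is called selected iff its BH q-value is below alpha (default 0.05)
and its nonsynonymous excess is positive. Under the generator's defaults
the suite measures mean sensitivity above 0.8 on the planted ×10 sites with
site-level FDR below 0.1, and a selected-site rate far below alpha under
the multiplier-1 null.

### Phylostratigraphy

Age = the minimum level among qualifying hits (E ≤ 10⁻³); no qualifying hit
outside the focal lineage means age 10 (lineage-specific), with a separate
`no_hit` flag for genes with no hits at all. E-values of exactly 0 are
rejected as underflow (a flag clamps them to 1e-180 instead) so later
log-domain work cannot fail silently. One qualifying organism per stratum
suffices. The distribution comparison uses the large-sample Mann–Whitney U
with tie-corrected variance and *no* continuity correction, so identical
samples give p = 1 exactly; the boxplot-only source names no test, and U is
the natural choice for ordered categorical ages.

## Problem sizes

The default test-suite sizes are the study conditions where stated
(2,000-gene DE recovery over five seeds; 10⁴ null gene pairs; 100
eight-leaf additive trees; 1,000-gene depth and age recovery; 500 sampled
architectures; 50 random 300-codon pairs against the oracle; 100
site-scan replicates at 20 × 100 codons) and small otherwise; the whole
suite runs in a few minutes on one CPU.

## Known limitations

* The depth model's tails overlap the 80× threshold: ≈ 0.9% of normal genes
  fall below it, so twin-removal F1 has a hard ceiling near 0.96 and
  fluctuates seed to seed around it. This is a property of the stated depth
  model, not of the filter.
* The site scan detects *relative* nonsynonymous excess against the
  alignment background, not ω > 1 in absolute terms; with a purifying
  background of 0.03, planted sites sit at ω ≈ 0.3. Posterior site
  probabilities of likelihood site models are out of scope.
* The synthetic data are idealised in ways real data are not: no mapping
  bias or GC effects in counts, no alignment error in codon columns, no
  taxonomic mis-mapping in the stratum table, star phylogenies rather than
  realistic gene trees. Passing recovery tests therefore demonstrates
  correctness of the computations under their stated models, not robustness
  to every artefact of real data.
* GFF3 parsing covers the restricted gene-line dialect used here (no
  mRNA/exon hierarchy); the hit-table reader expects the common 12-column
  tabular layout.
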