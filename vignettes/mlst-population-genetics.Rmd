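---
title: "MLST population genetics with mlstpg: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MLST population genetics with mlstpg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mlstpg` implements the standard analysis chain for multi-locus sequence
typing (MLST) of a clonal bacterial population — here parameterized for the
eight-locus scheme used for *Lactobacillus delbrueckii* subsp. *bulgaricus*
(clpX 508 bp, dnaA 598, groEL 470, murE 477, pheS 491, pyrG 563, recA 551,
rpoB 603; 4261 bp concatenated) — together with a synthetic population
generator whose event-level ground truth lets every stage be validated
without access to a strain collection. This vignette explains the models and
statistics, the conventions the implementation pins down where the published
methods literature leaves latitude, and what the synthetic tests do and do
not demonstrate about real data.

## Typing model

An *allele* is a unique nucleotide sequence at one locus; sequences differing
at a single position are distinct alleles. Allele numbers are assigned in
first-occurrence order of the input stream, so numbering is deterministic
given a fixed input manifest and idempotent on re-runs. This choice is an
explicit convention: typing GUIs assign numbers in whatever order records
were added, which is irreproducible; first-occurrence order over a sorted
manifest is the reproducible equivalent. A *sequence type* (ST) is the
8-vector of allele numbers; identical vectors share one ST id, assigned
contiguously in first-occurrence order.

Input sequences must be finished Sanger consensus: exact length for their
locus, unambiguous A/C/G/T only (ambiguity codes are rejected rather than
resolved — resolving them silently would fabricate alleles), and no stop
codon among the complete codons of the declared reading frame. Every
fragment defaults to frame offset 0 (amplicons in frame); the offset is
configurable per locus. Chromatogram processing and read reconciliation are
out of scope: the package consumes finished sequences.

## Diversity statistics

*Nucleotide diversity* π is the plain average number of pairwise differences
per site, `sum_{i<j} d_ij / C(n,2) / L`, with no multiple-hit correction —
that is the definition the classical MLST literature quotes, and at the
within-subspecies divergences involved (π of order 10⁻³) the correction
would be far below reporting precision. Pairs are taken over isolates, not
unique STs, so common genotypes weigh more. An exact identity follows from
the definition: π of the concatenated alignment equals the length-weighted
mean of the per-locus π values; the test suite asserts this to 1e-12 as a
cross-check between the two computation routes.

*Polymorphic sites* are columns with ≥2 observed bases. SNP sites inside
complete codons are classified by amino-acid effect: for every pair of
observed codons differing at the site, the site's base from one codon is
substituted into the other; if any such substitution changes the amino acid
the site is nonsynonymous, otherwise synonymous. When a codon segregates at
several positions this attributes to each site only the changes that site
itself causes, and the single-class assignment is conservative: a site
producing both synonymous and nonsynonymous pairs counts as nonsynonymous.
The per-locus nSNP/sSNP/polymorphic counts of the concatenated row are sums
of the per-locus values, matching how such tables are conventionally
reported.

*dN/dS* follows Nei & Gojobori (1986). Synonymous site counts are
fractional per codon position with mutations to stop codons excluded from
the denominator (a position whose only synonymous change would create a stop
contributes nothing); a non-stop alternative always exists, since at most
two of the three single-base changes at a position can reach a stop codon.
Differences between codons are averaged over minimal mutational pathways
with equal weights, pathways through stop codons excluded (if all pathways
pass through a stop — possible only for inputs that themselves violate the
no-stop precondition — all pathways are used as a fallback). Per pair,
proportions pN and pS are Jukes–Cantor corrected; dN and dS are averaged
over all isolate pairs *before* the ratio is taken, which is the behaviour
of the START typing-analysis tool; both corrected and raw values are
returned because tools differ on whether the correction is applied.
Conventions for degenerate cases: dN = 0 gives ratio 0 (purifying-selection
reading); dS = 0 with dN > 0 is undefined and flagged, never coerced; pS ≥
3/4 makes the correction undefined (NaN, flagged). Identical sequences give
ratio 0 with an `identical` flag. The concatenated dN/dS pools the
pair-averaged site and difference counts across loci before correction.

## eBURST clustering

STs are linked when their profiles differ at exactly one locus
(single-locus variants, SLVs); clonal groups are the connected components of
this graph. Components with ≥3 STs are clonal complexes (CCs), 2-ST
components doubletons, isolated STs singletons — the three-way breakdown
used in population snapshots. The group founder is the member with the most
SLVs; ties are broken by larger double-locus-variant count, then larger
isolate count, then smaller ST id. eBURST proper ranks tied founders by
bootstrap support; a deterministic chain was chosen instead so that founder
calls are exactly reproducible — the bootstrap variant is out of scope.
Subgroup founders are non-founder members with at least two SLV links beyond
their link to the founder; published snapshots name subgroup founders
without stating the criterion, so this convention is the package's own and
is documented rather than enforced against any published example. Profiles
with missing alleles are rejected; partial-profile distances are not
defined. Snapshots are exported as GraphML and DOT with isolate counts as
node weights.

## Recombination statistics

**PHI.** The pairwise homoplasy index is computed on the
parsimony-informative sites (≥2 states each carried by ≥2 sequences). For a
site pair, the incompatibility score is the minimum number of homoplasies
any genealogy must invoke to explain both sites: `e − v + c` of the
partition intersection graph whose vertices are the observed states and
whose edges the observed joint states (0 exactly when the pair is
compatible). PHI is the mean score over pairs within `window` positions of
each other on the informative-site subalignment (default 100). Under clonal
descent homoplasy is positionally random, so the null is generated by
permuting the site order; recombination makes nearby sites more compatible
than distant ones, pushing the observed statistic below the permutation
distribution. The p-value is the plus-one-corrected fraction of
permutations with PHI ≤ observed; the plus-one form avoids zero p-values.
With fewer than two informative sites the statistic is flagged not
computable and p = 1 is reported. When the window covers all pairs the
statistic is permutation-invariant and the test has no resolution (p = 1);
the window must be small relative to the informative-site count for the
test to discriminate.

A consequence worth stating explicitly: a site-order permutation test has,
by construction, *no power* against alignments whose columns have been
independently shuffled across sequences. Shuffling makes the columns
exchangeable in position, which is precisely the null hypothesis of the
permutation scheme, so p-values on fully shuffled data are uniform and the
rejection rate equals the nominal level. The test suite verifies the
underlying exchangeability property directly: p-values on site-order
permutations of a fixed input pass a Kolmogorov–Smirnov uniformity check.
Column shuffling is therefore a *calibration* null, not a power
alternative. Genuine power is demonstrated against whole-locus replacement
recombination, which preserves the distance structure PHI exploits
(within-locus pairs stay compatible, cross-locus pairs conflict): the
property suite asserts that the rejection rate increases strictly across
replacement rates 0, 0.3 and 0.8 per transmission while mean I_A^S falls
toward zero.

**Standardized index of association.** For profiles over l loci, `V_D` is
the variance of the pairwise mismatch-count distribution and
`V_e = sum_j h_j (1 − h_j)` its linkage-equilibrium counterpart, with
`h_j = n/(n−1)(1 − sum_k p_jk²)` the unbiased allelic diversity of locus j
(the lian definition). Then `I_A^S = (V_D/V_e − 1)/(l − 1)`: ≈0 under free
recombination, 1 when all loci carry the same partition. Two conventions
are pinned by exact identities: `V_D` is the *population* variance (divisor
`C(n,2)`), and `h_j` is the unbiased estimator — with these, the mean
mismatch equals `sum_j h_j` exactly and l identical loci give exactly
I_A^S = 1; either a sample-variance `V_D` or a biased `h_j` breaks both
identities. Significance uses Monte-Carlo resampling (independent
within-locus allele permutations, plus-one-corrected upper tail). By
default I_A^S is computed on the rows as given; the pipeline passes unique
STs, the convention used when linkage tables are labelled by ST counts, and
per-isolate computation is available via `collapse_to_sts = FALSE` on
isolate-level input. Per-lineage rows take lineage membership as an input
label file; lineage inference itself (Bayesian mixture modelling) is out of
scope.

## Subspecies classification

Isolates are classified against a panel of type-strain records: per locus,
the nearest reference by p-distance casts a vote (exact ties cast an
unresolved vote, never a random one); the final call is the strict
plurality, with tied pluralities reported as `unresolved` for manual
review; any split vote sets a mosaic flag, the signature of inter-lineage
recombination at housekeeping loci. Neighbor joining on p-distance is
provided as supporting visualization (`nj_tree`, via ape, negative branch
lengths clamped to zero); the decision rule is nearest-reference voting, not
tree topology, so maximum-likelihood tree inference with model fitting is
deliberately not reimplemented.

## The synthetic population generator

The generator emulates the structure of a natural-fermentation strain
collection: K divergent ancestral lineages, clonal expansion, rare
whole-locus imports. Ancestor 1 is a random in-frame stop-free sequence per
locus; ancestors 2..K differ from it by independent per-site substitution at
`ancestor_divergence`. Isolates are born sequentially: each is assigned a
lineage (each lineage seeded once, then uniform), descends from a uniform
earlier member of its lineage, and is separated from its parent by
`generations` transmissions. Each transmission applies per-site point
mutation at rate `mu` (substitutions that would create an in-frame stop are
resampled, so emitted sequences always validate — mirroring the empirical
absence of premature stops in housekeeping fragments) and then, with
probability `rho`, replaces one uniformly chosen locus with that locus from
a uniformly chosen co-existing isolate. Whole-locus replacement matches
MLST resolution, where any import appears as an allele replacement;
intragenic conversion tracts shorter than a fragment are not modelled, and
site-shuffled alignments (`shuffle_sites`) serve as the no-linkage null
instead. Every event is logged with enough detail that `replay_truth`
reconstructs all sequences byte-exactly — the simulator's own correctness
oracle.

Defaults describe the emulated study conditions: the eight-locus scheme
above, K = 6 lineages, 251 isolates, `ancestor_divergence = 0.005`
(between-lineage divergence of a few tenths of a percent to one percent,
the within-species range typical of housekeeping fragments in lactic acid
bacteria), `mu = 2e-4` per site per transmission (≈0.85 expected mutations
per 4261-bp genome transmission, so roughly 40% of births are
mutation-free and share their parent's ST — yielding an ST/isolate ratio in
the range such collections report), `rho = 0.02` (imports an order of
magnitude rarer than mutation events, the clonal end of the spectrum), and
`generations = 1`. Seeds are mandatory; nothing is seeded from the clock.

What passing synthetic tests show — and what they do not: the generator
produces gap-free, stop-free, equal-length fragments with lineage structure,
neutral mutation and uniform-donor imports. Real collections add
sequencing error, unbalanced sampling, selection (real housekeeping dN/dS
is ≪1, while neutral simulation gives ≈1), geographically structured
migration, and tract-length recombination; agreement on synthetic data
validates the *statistics*, not the biology of any particular collection.

## Numerical and design choices

- Ties in founder election are resolved by the deterministic chain above;
  input order never affects results (asserted by permutation tests).
- PHI experiment design in the test suite: clonal single-locus alignments of
  400 bp, 40 sequences, mutation rate 1.2e-2 per site per transmission
  (≈50–110 informative sites), window 20, 400 permutations. These sizes
  give the permutation distribution enough distinct values that the
  plus-one-corrected p-value is effectively continuous — with sparse scores
  the test is conservative, as any tie-inclusive permutation p-value is —
  while keeping the whole calibration (200 replicates) at desk scale.
- I_A^S equilibrium checks use 500 profiles × 8 loci × 50 replicates;
  eBURST oracle checks use ~200-profile random walks; lineage-recovery
  checks use 120 isolates at divergence 0.05. Problem sizes are the
  package's choice of smallest scales at which the asserted properties are
  statistically unambiguous.
- Degenerate inputs are reported, not patched: empty subsets, single
  sequences (π undefined), monomorphic profile sets (V_e = 0) and <2
  informative sites all produce typed errors or flagged results.

## Known limitations

- Allele calling is exact-match only; a sequencing error produces a novel
  allele rather than a fuzzy match (query mode reports novelty; extend mode
  registers it).
- The eBURST implementation does not perform goeBURST's global link
  optimization; for data sets where a tie in link assignment changes
  component structure the partitions can differ.
- PHI is implemented with the window on the informative-site subalignment;
  implementations that window on physical coordinates will include slightly
  different pair sets on sparse alignments.
- The concatenated dN/dS pools counts across loci (ratio of pooled means),
  which differs in principle from averaging per-locus ratios; with
  realistic per-locus counts the difference is far below reporting
  precision.
- Bayesian lineage inference, composite-likelihood recombination-rate
  estimation (ρ/θ per site), split networks and maximum-likelihood
  phylogenetics are out of scope; lineage labels are inputs, not outputs.
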