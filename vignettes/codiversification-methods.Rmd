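---
title: "Methods: community co-diversification from amplicon sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community co-diversification from amplicon sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the design

`codiv` asks a comparative-phylogeography question at the scale of a
whole community: when many taxa are sampled from the same habitat on
both sides of a biogeographic barrier, do more of them show population
genetic structure concordant with the barrier than chance would
predict? The motivating system is the inquiline community of
*Sarracenia alata* pitcher fluid, sampled at five Louisiana locales —
two west and three east of the Mississippi River — with a single 28S
amplicon (~275 bp after trimming) sequenced from every pitcher. The
host plant is known to be strongly structured across the river, so each
commensal OTU's structure statistics can be read as evidence for or
against a shared history with the host.

The pipeline is: trim and dereplicate reads; cluster them into OTUs by
greedy abundance-sorted identity clustering at 97% with a chimera
screen; keep OTUs with at least 10 sequences and at least 3 on each
side of the barrier; align each OTU; compute per-OTU diversity
(π, Watterson's θ, Tajima's D) and structure statistics (haplotype
G~ST~, AMOVA Φ statistics, the genealogical sorting index on an NJ
tree, a Mantel test of isolation by distance), each with a permutation
or parametric null; and synthesise the per-OTU significance calls into
a community-level chi-squared goodness-of-fit test: under the null that
no OTU is structured, α·(number of OTUs) tests are expected significant
at level α.

## Clustering model

Reads are truncated to a common `trim_length` (default 275 bp; shorter
reads are dropped) because clustering length-variable pyrosequencing
reads biases OTU assignment. Identical reads are collapsed with
abundances, sorted by abundance with lexicographic tie-breaks — this
makes every later step invariant to the input order of reads — and
clustered greedily: the most abundant sequence founds the first OTU,
and each subsequent sequence joins the centroid of maximum identity if
that identity reaches the threshold, is discarded if the chimera screen
flags it, and otherwise founds a new OTU. Centroids are therefore
pairwise below the threshold, and members are within it of their
centroid, by construction; both invariants are re-verified on every
run.

Pairwise identity is computed from a Needleman–Wunsch global alignment
with free terminal gaps (match +1, mismatch −1, a gap of length *L*
costs 5 + (*L* − 1)), as matching columns over alignment columns. One
numerical guard goes beyond that definition: with free terminal gaps,
the *optimal* alignment of two unrelated sequences is a short chance
overlap (typically ~9 bp) of near-perfect identity, which would merge
unrelated OTUs. An alignment covering less than half the shorter
sequence is therefore treated as non-homologous (identity 0). Amplicons
of a common locus trimmed to a common length always overlap nearly
fully, so the guard never affects genuine comparisons.

The chimera screen models a chimera as a prefix of one existing
centroid joined to a suffix of another, scanning breakpoints on a 5 bp
grid with both segments ≥ 50 bp; a query is chimeric when its best
two-parent identity reaches the clustering threshold and beats its best
single-parent identity by ≥ 0.01. The false-positive rate on unrelated
random queries is below 1% (tested over 1,000 draws).

## Per-OTU alignment

Each OTU's unique sequences are aligned with a center-star aligner: the
highest-abundance sequence is the center, every other sequence is
pairwise-aligned to it, and the pairwise alignments are merged under
"once a gap, always a gap". For ~275 bp amplicons within 3% of their
centroid this is adequate, and it keeps the pipeline self-contained;
externally produced aligned FASTA is accepted as a first-class
alternative (`ingest_alignment()`). Stripping gaps from any row of the
output reproduces the input sequence exactly — asserted
property-style in the tests. Unique-sequence rows are then expanded to
read level so that all statistics weight haplotypes by observed
abundance.

## Diversity statistics

Gaps and `N` are handled by pairwise deletion: for each pair of rows,
columns with a gap or `N` in either row are excluded. π is the mean
over pairs of (differences / pair-valid sites); k̂ is the mean raw
difference count; *S* counts columns with ≥ 2 distinct called bases;
θ~W~ = *S*/(a₁·L) with a₁ = Σ 1/i and *L* the number of columns
carrying at least one base. Tajima's D uses the standard variance
constants; it is reported as missing — never as 0 — when *n* < 4 or
*S* = 0.

Two nulls are available for D. The *beta* null (the default, matching
the original analysis) rescales D onto its support [D~min~, D~max~]
(functions of *n*) and assumes a beta law with mean 0 and variance 1;
the two-tailed p-value is 2·min(F(D), 1 − F(D)). The *simulation* null
draws neutral coalescent genealogies at the observed *n*, places the
observed *S* mutations on branches with probability proportional to
branch length, and recomputes D per replicate. The two disagree more
than is often appreciated: the beta law approximates the
*unconditional* null, and against the conditional-on-*S* simulation
null its two-tailed p-values deviate by up to ~0.1 near the centre of
the distribution and by up to ~0.05–0.08 at tail quantiles, most
strongly at small *n*. The simulation null (cross-validated against an
independent `ape::rcoal`-based implementation) is the more defensible
reference; the beta mode is retained as the default because it is what
the published asterisks rest on, and both are exposed through
`tajima_pvalue()`.

## Structure statistics

**G~ST~.** Haplotypes (distinct aligned row strings) are alleles.
Per-locale gene diversities use the unbiased n/(n − 1) correction and
average (unweighted) into H~S~; total diversity uses unweighted mean
haplotype frequencies with the small-sample correction
H~T~′ = H~T~ + H~S~/(ñ·P). G~ST~ = (H~T~′ − H~S~)/H~T~′; the
uncorrected form is available via `corrected = FALSE`. Locales with a
single sequence are excluded from the corrected estimator. Note a
finite-sample quirk: at *exactly* equal haplotype frequencies the
corrected estimator is slightly negative (−0.026 at n = 20 per locale),
because the correction inflates H~S~; it is unbiased over sampling, and
the uncorrected form is exactly zero there. Significance is by
permuting individuals among locales.

**AMOVA.** Squared distances (raw pairwise difference counts by
default — the convention under which difference counts *are* the δ²;
K2P optionally) are decomposed into among-region,
among-locale-within-region and within-locale components with the
standard unequal-size coefficients, yielding Φ~CT~, Φ~SC~ and Φ~ST~.
Each has its own permutation scheme: individuals among locales
(Φ~ST~), individuals among locales within regions (Φ~SC~), whole
locales among regions (Φ~CT~). With five locales the Φ~CT~ null has
only `choose(5, 2)` = 10 distinct assignments, so its p-values cannot
fall below ~0.1; the attainable floor is reported as `p_ct_floor`. The
variance decomposition is verified against a brute-force scalar nested
ANOVA (and R's `aov`) to 10⁻¹⁰ on random unbalanced instances.

**GSI.** Genealogies default to neighbor joining on K2P distances
(negative branches clamped with the deficit moved to the sister branch;
external newick trees can be used instead), midpoint-rooted. The
genealogical sorting index is *n*/Σ(deg(u) − 2) over the internal nodes
of the group's minimal connecting subtree, normalised between its
full-dispersal minimum (0) and monophyly maximum (1); it depends only
on topology. One subtlety discovered during calibration: duplicate
haplotypes sit at distance zero, and NJ resolves zero ties by input
position; because input order is locale-blocked, this inflated the GSI
type-I error threefold. The tip order is therefore shuffled (seeded)
before tree estimation, restoring exactness of the label-permutation
test.

**Mantel.** Genetic distances are aggregated to locale level (mean
between-locale K2P) and correlated with great-circle distances in km
(haversine, sphere radius 6371 km, or a user matrix). The test is
one-tailed — isolation by distance predicts positive correlation. With
five locales the complete permutation set is enumerated, giving exact
p-values.

All permutation tests use p = (1 + #{perm ≥ obs})/(B + 1): never zero,
conservative under ties. Discrete statistics (haplotype G~ST~, GSI on
small trees) tie often, so their p-values are valid but conservative —
their type-I error sits at or slightly below α rather than exactly at
it.

## Community synthesis

Each test's significant OTUs (strict p < α, α = 0.05 by default) are
counted against the OTUs for which that test was computable — tests can
be inapplicable per OTU (a locale below two sequences for AMOVA,
saturated K2P pairs for the tree, fewer than three sampled locales for
Mantel), and every exclusion is logged in the run manifest. The
chi-squared goodness-of-fit statistic compares the observed count to
α·total on 1 df. No multiple-testing correction is applied across OTUs,
matching the original analysis; the community-level chi-squared is the
guard against over-interpreting individual asterisks.

Rarefaction (per-locale survey mode) uses the hypergeometric
expectation E[S~m~] = Σ(1 − C(N − N~i~, m)/C(N, m)), computed via
`vegan::rarefy` and checked against Monte-Carlo subsampling.

## The synthetic-data generator

Calibration and power claims rest on a structured-coalescent simulator,
since the real survey has no ground truth. Time is scaled so a lineage
pair within a deme coalesces at rate 1; `tau` (the region split, looking
back) and the migration rates are in these units. Mutation is
finite-sites Jukes–Cantor at rate θ/2 per lineage per unit — finite
sites deliberately, so K2P saturation handling is exercised. Defaults
emulate the survey: five demes (2 west / 3 east), θ = 5 per locus
(matching θ~W~ ≈ 0.02/site × 275 bp), per-OTU totals from a truncated
log-series on [14, 2507] with the parameter set once so the median OTU
size is ~54 sequences, and a structured/panmictic OTU mixture
(`fraction_structured`, default 0.5).

The default split depth is `tau = 0.5`, shallow deliberately: expected
cross-barrier divergence is θ(τ + 1)/L ≈ 2.7%, inside the 97% OTU
envelope, matching the survey's observed π ≤ 0.02. A deep split like
τ = 10 produces ~20% cross-barrier divergence, and 97% clustering then
*splits* every structured OTU into two single-region clusters that the
comparative filter removes — a real limitation of single-locus OTU
co-phylogeography worth keeping in mind with real data. The deep-split
regime (τ = 10, m = 0, θ = 5) is still what the power analysis uses,
applied to per-OTU alignments directly: there Φ~ST~ and GSI are
significant in ≥ 90% of OTUs (measured: 100%) at B = 199.

What the simulator does *not* emulate: sequencing error and real
chimeras (an optional uniform error flag is out of scope), primer bias,
taxon-specific mutation rates, recombination, and selection. Passing
calibration therefore shows the statistical machinery is correct and
calibrated on clean coalescent data, not that the laboratory pipeline
upstream is unbiased.

## Numerical choices and test scales

Permutation counts default to 10,000 in the configuration (as in the
original analysis); the test-suite calibrations use B = 199 with 400
panmictic OTUs for type-I error and 100 deep-split OTUs for power, and
the estimator checks use 1,000 replicates — sizes chosen to give
3-standard-error resolution around the quantities asserted. Seeds:
every stage derives its stream from the single configuration seed, and
identical configuration + seed yields byte-identical report files
(timestamps are deliberately excluded from the manifest).

## Known limitations

- The exact OTU counts of any particular survey are not reproducible
  across clustering engines: greedy identity clustering is
  deterministic here, but different engines' heuristics (and chimera
  models) partition borderline sequences differently. The comparative
  statistics, not the OTU count, are the stable surface.
- The beta null for Tajima's D is a coarse approximation (see above);
  borderline asterisks should be confirmed with
  `tajima_pvalue(mode = "simulation")`.
- Φ~CT~ significance is structurally out of reach with five locales
  (p-value floor ~0.1); it is reported for effect size, and its
  community chi-squared row tests a hypothesis the design cannot
  reject.
- The center-star aligner does not refine among non-center sequences;
  for OTUs near the identity threshold an external aligner may place
  indels better, and its output can be ingested directly.
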