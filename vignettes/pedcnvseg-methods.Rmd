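---
title: "Methods: co-segregation analysis of CNVs in extended pedigrees"
author: "pedcnvseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-segregation analysis of CNVs in extended pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Rare, inherited copy number variants (CNVs) are a recognized component of
the genetic architecture of complex neurodevelopmental phenotypes such as
autism spectrum disorders. In extended multiplex families -- families with
two or more affected cousin-or-more-distant relatives -- a variant shared
by all affected members is a strong candidate, because distant relatives
share little of their genome by chance: an avuncular pair is expected to
share 25% of the autosomal genome identical by descent, first cousins
12.5%, and second cousins only 3.125%. `pedcnvseg` implements the full
analysis path from per-sample CNV calls and pedigrees to a prioritized
candidate table, together with a seeded generator of synthetic cohorts
with the same statistical structure.

## Data model and conventions

A CNV call is a chromosome, two integer boundary positions (the positions
of the first and last supporting array probe), an integer copy number in
{0, 1, 3, 4} and a probe count. Copy number 2 is the diploid state and is
not representable as a call, matching the behaviour of HMM-based callers
that emit only non-diploid segments. The type of a call is derived: `del`
below two copies, `dup` above.

**Length convention.** The length of an interval is `end - start`, the
span between its boundary probes -- equivalently, intervals behave as
half-open position sets `[start, end)`. All overlap arithmetic uses this
convention, and input `length=` tokens are recomputed from the boundaries
rather than trusted (a discrepancy above 1 bp is warned about). BED input
(0-based, half-open) therefore maps onto internal coordinates without a
shift. Whether array boundary coordinates "should" be treated as 0- or
1-based cannot be decided from call files alone; this convention is chosen
because it reproduces the reference candidate lengths exactly, and it is
documented rather than asserted as universal.

**Same-CNV rule.** Two records describe the same CNV when their types
match (deletion with deletion, duplication with duplication) and they
overlap by at least 50% of their lengths. The phrase "of their lengths" is
read *reciprocally* -- the shared span must cover at least the fraction of
*both* records -- which is the conservative, field-standard reading; an
`either`-sided mode is available in the configuration
(`overlap_mode = "either"`) for sensitivity analyses. The fraction itself
(`overlap_fraction`, default 0.5) is configurable.

## Quality control

Sample-level gates (defaults): standard deviation of the normalized
intensity (SDLRR) must be below 0.4, at most 300 CNVs detected, and
genotyping call rate at least 95%. Samples with 0.3 < SDLRR < 0.4 *and*
100--300 detected CNVs fall in a review zone: historically such samples
were inspected manually for mosaicism, which cannot be automated, so the
faithful default is to keep them with a `review` flag; `strict_qc = TRUE`
excludes them instead. The boundary values SDLRR = 0.3 and 100 CNVs lie
outside the review zone (the printed inequalities are strict), while
SDLRR = 0.4 itself fails. A missing metric is an error, never a silent
pass.

Call-level gates: at least 3 supporting probes, autosomes only
(hemizygosity in males and X inactivation in females make sex-chromosome
dosage uninterpretable with autosomal thresholds).

Families in which a branch contains no genotyped affected individual have
that branch pruned before analysis -- a documented heuristic standing in
for the source study's manual removal of "uninformative" samples, which
it did not define per-sample.

## The filter cascade

1. **Shared-CNV detection.** Within each family, for each chromosome and
   CNV type, the pipeline finds groups of calls, one or more per
   genotyped affected member, that are all pairwise the same CNV; the
   candidate interval is the intersection (`[max(starts), min(ends)]`) of
   the group. Every genotyped affected member must contribute a call,
   otherwise no candidate is emitted at that locus. Groups are maximal
   cliques of the pairwise same-CNV graph; when several maximal groups in
   one connected component qualify (nested calls), the longest
   intersection is reported. Clique-then-longest is a deterministic,
   conservative resolution of a case the underlying procedure leaves
   unspecified.
2. **Married-in / segregation exclusion.** Carriers of any affection
   status are collected for each candidate (everyone whose call matches
   it) and partitioned into affected, unaffected blood-relative and
   married-in carriers. A candidate carried by more than one married-in
   unaffected individual is rejected: two unrelated entries into the
   family cannot be identical by descent from one source, so such
   variants co-occur with affection by chance. A candidate whose carriers
   admit no single-introducer explanation (below) is rejected as showing
   no clear segregation. Unaffected blood-relative carriers are
   *permitted* -- the genetic model is dominant inheritance with
   incomplete penetrance, and the variant is expected to pass through
   unaffected relatives.
3. **Population-frequency evaluation.** The control carrier frequency is
   computed per ancestry as the number of distinct control individuals
   matching the candidate under the same-CNV rule divided by the cohort
   size; an individual with several matching records counts once. A
   candidate is rejected when its *ancestry-matched* frequency reaches
   `frequency_threshold` (default 1.5%); unmatched-ancestry frequencies
   are reported but never ground rejection. Event counts in a
   DGV-style population database are annotation only -- a database has no
   usable cohort size for a frequency, and database presence alone does
   not reject (a common-in-DGV candidate with zero matched controls is
   retained and simply tiered lower).
4. **Prioritization.** Tier 1: absent in controls and the database and
   overlapping a literature region (either with similar breakpoints --
   reciprocal 50% overlap with the reported CNV -- or contained within a
   larger reported region). Tier 2: absent in both, no literature overlap
   (novel). Tier 3: present at sub-threshold frequency in controls or
   present in the database.
5. **Gene context.** Overlapping genes are classified as whole-gene
   (gene span inside the candidate), exonic-portion (at least one exon
   touched without containing the gene), or intronic (candidate inside
   the gene, no exon touched); with no overlapping gene the nearest gene
   is reported with distance and orientation relative to its strand.

Every candidate receives a verdict (`retained`/`rejected` plus reason
code) at every stage it enters, recorded in a filter trace in which
counts are conserved stage to stage.

## Kinship and transmission

The kinship coefficient is computed recursively: founders are unrelated
and non-inbred, phi(i,i) = (1 + phi(father, mother))/2, and recursing on
the individual of greater generation depth, phi(i,j) = (phi(father_i, j)
+ phi(mother_i, j))/2. Expected autosomal sharing of a non-inbred pair is
2 phi. The test suite checks the recursion against an independent
path-counting enumeration over common ancestors on 200 random pedigrees.

Transmission inference searches for a single *introducing ancestor* such
that every known carrier is the introducer or its descendant and each
carrier's ancestral path to it passes only through carriers or
genotype-unknown individuals. Untyped members are deliberately permissive:
real extended pedigrees have many members without DNA, and requiring
typed carriers along every path would reject families that are perfectly
consistent with single-origin descent. Genotyped non-carriers block
paths. The transmission label is evaluated from each affected carrier's
perspective -- the parent through which the variant arrives -- and
aggregated: all-maternal gives `maternal`, all-paternal `paternal`,
mixed `both`, ambiguous-per-individual `undetermined`. Ties among
feasible introducers are broken toward the most recent one, with
alternatives reported. Individuals who are blood relatives of the lineage
through a second path are not specially handled; pedigrees are validated
as acyclic and effectively non-inbred, and the kinship recursion's native
behaviour applies otherwise.

"No clear segregation with affection status" has no formal definition in
the source procedure; this package operationalizes it as the failure of
the single-introducer search, and exposes the choice as
`require_single_introducer` in the configuration.

## Statistics

Association in 2x2 tables uses the two-sided Fisher's exact test with the
point-probability convention: the p-value sums hypergeometric point
probabilities (margins fixed) of every table no more probable than the
observed one. This is the convention of `stats::fisher.test`, which backs
the implementation; the test suite verifies it against exhaustive
enumeration for every table with total at most 40. With a zero margin
only one table is possible and p = 1. Group comparisons of per-sample CNV
counts use the Kruskal--Wallis rank-sum test on mid-ranks with tie
correction and the chi-square approximation on k-1 degrees of freedom
(group sizes in this design are large); an exact permutation p-value is
available for totals up to 10. Displayed frequencies and p-values round
half away from zero to 3 decimals; threshold comparisons always use the
exact fraction, never the rounded display value.

## The synthetic cohort generator

The generator's defaults are the study conditions the package targets: 42
extended families (28 with two, 8 with three, 6 with four affected
cousin-or-more-distant relatives) and a control cohort of 727 European-
ancestry plus 111 African-American children -- the post-QC analysis
sizes, which are the denominators of all reported control frequencies.
Two-affected families are drawn from first-cousin, avuncular and
second-cousin templates in a fixed 2:1:1 pattern; pedigree topologies are
canonical 3--4 generation structures with married-in spouses, typed
descendant generations and untyped founders.

Gene dropping is standard: founders receive copies either by designation
(a planted risk CNV starts as one copy in a named founder) or by
population carrier frequency (per-allele frequency 1 - sqrt(1 - f), so
the founder carrier fraction matches f); each child inherits one allele
per parent with probability copies/2, keeping hom/het states
representable. Affection is assigned with penetrance 0.6 for carriers and
phenocopy rate 0.001 for non-carriers -- the source material gives no
penetrance estimate, so these are stated configuration, not empirical
claims. Planted-variant families are resampled (variant drop and
affection together) until the ascertainment condition -- the required
number of affected cousin-generation members -- holds; the resampling
count is logged. Families without a planted variant take their affection
pattern from the template instead: under a dominant-CNV-plus-phenocopy
model alone, a non-carrier family would essentially never ascertain, and
the non-planted families model the heterogeneous remainder of a
multiplex-family cohort.

Background CNV polymorphisms (default: 30 autosomal loci at 3--10%
carrier frequency) are dropped independently of affection in families and
controls alike; per-sample boundary jitter (default +/- 500 bp, capped at
an eighth of the locus length so reciprocal 50% overlap with the locus
definition is preserved) emulates probe-level boundary uncertainty. A
truth log records every planted variant, its introducer and its carriers,
and is the oracle for the sensitivity and specificity properties in the
test suite.

What the generator does *not* emulate: raw intensity data (QC metrics
are drawn within passing ranges rather than computed from intensities),
genotype-level SNP data, ancestry admixture, de novo events, and
cell-line artifacts. Passing tests on simulated cohorts therefore
demonstrate the correctness of the filter logic under the stated model,
not robustness to array noise or to CNV-calling error.

## The reference fixture

`paperFixture()` deterministically writes a complete input set realizing
the published candidate table of the study design this package follows:
eleven European-ancestry families carrying twelve validated CNVs (five
deletions, seven duplications; one family carries two duplications in the
same four individuals), with control tables realizing the reported
bracketed per-cohort carrier counts over cohort sizes 727/111, a
DGV-style table realizing the reported event counts (">300" as 301 --
any value above the presence threshold is equivalent to the pipeline),
literature regions for the two previously reported loci, and synthetic
gene models reproducing the described gene contexts (gene placements are
synthetic and labelled as such; only their topological relation to the
candidates is meaningful). Fixture pedigrees are documented canonical
simplifications -- a founding couple, two branches, one affected cousin
per branch -- preserving each family's affected-relationship class,
carrier counts and transmission routes (the five deletions maternal, the
seven duplications both maternal and paternal, the doubly-affected
family's two duplications identical in carriers and label). The original
drawn pedigree topologies are not machine-readable from text, and the
acceptance checks rest on counts, lengths and frequencies, not on drawn
topology.

Two internal inconsistencies of the source tables are carried as-is
rather than reconciled: one locus shows zero control and database
carriers yet is absent from the prose list of database-absent loci (the
pipeline tiers it "novel", as the data imply), and the prose transmission
counts (5 + 6) do not sum to the twelve loci; the fixture realizes the
per-family labels, and only the within-family identity of the
doubly-affected family's labels is asserted.

## Numerical choices and degenerate inputs

* Zero-length intervals are valid points but error inside the same-CNV
  predicate (an overlap fraction of a zero-length record is undefined).
* Frequencies compare as exact fractions; display rounding is half-up to
  3 decimals.
* Chromosome labels are compared after stripping any `chr` prefix,
  case-insensitively; report ordering is deletions before duplications,
  then chromosome (1--22, X, Y), then start.
* Pedigrees with a single known parent gain a synthetic placeholder
  founder (logged); unknown parent ids and duplicated individuals are
  structural errors; parent cycles are rejected by validity checking.
* Tie-breaks: among feasible introducers, the deepest (most recent) then
  lexicographically smallest id wins, alternatives are reported; among
  maximal call cliques covering the affected set, the longest
  intersection wins.

## Problem sizes used by the test suite

The packaged checks run at deliberately modest scale chosen to make every
property decidable in seconds to a few minutes: exhaustive Fisher
verification over all 2x2 tables with total at most 40; kinship versus
path-counting on 200 random pedigrees of up to 5 generations; 100 seeded
replicates for planted-variant sensitivity (penetrance 1); 50 replicates
each for specificity of common background variants and for
penetrance-0.6 retention calibrated against an exact enumeration of the
first-cousin template; 10,000 null replicates for Kruskal--Wallis
p-value uniformity.

## Known limitations

* The pipeline consumes CNV calls; it does not call CNVs from intensities
  nor refine boundaries with trio information.
* The married-in definition assumes married-in individuals carry no
  parent links in the pedigree file; a married-in person who is also a
  blood relative through an unrecorded path is not detected.
* Transmission inference assumes a single mutational origin per family
  and does not model de novo recurrence.
* The exact Kruskal--Wallis permutation is limited to 10 observations;
  beyond that the chi-square approximation is used.
* No multiple-testing machinery is provided: the procedure is a filter
  cascade validated by orthogonal assays in its source design, not a
  genome-wide association scan.
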