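---
title: "Detecting allopolyploidy from multi-labeled gene family trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting allopolyploidy from multi-labeled gene family trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybsignal)
library(ape)
```

## The model

An allopolyploid species inherits one full subgenome from each of two
parental lineages. In a nuclear gene family tree this leaves a
characteristic footprint: the hybrid contributes two homeologous copies,
one nested inside (or sister to) each parental lineage. `hybsignal`
operationalizes this signal. Each multi-copy gene family tree is reduced to
a **multi-labeled (MUL) tree**: a single-copy tree in which every ordinary
species appears once and the hybrid appears as up to two tips, `A-<hybrid>`
and `B-<hybrid>`, one per subgenome. Counting, across many gene families,
how often each labeled tip clusters with each candidate parental lineage
turns an anecdotal observation into a per-clade tally of concordant and
conflicting gene trees, and the labeled trees can additionally be combined
into a summary species tree in which the hybrid genuinely occupies two
positions.

The method assumes (i) hybrids are *hypothesized*, not inferred — the user
names each putative hybrid and two disjoint candidate parental taxon sets;
(ii) gene trees are rootable with a shared outgroup; and (iii) paralogy
within non-hybrid species is noise to be pruned, whereas the hybrid's
multi-copy structure is the signal to be kept.

## Pruning and labeling

`mul_convert()` performs the core conversion in three deterministic steps.

**Rooting.** The tree is rooted on the edge separating the outgroup tips.
If the outgroup is not separable (e.g. an ancient duplication spans it), the
tree is rooted above the largest outgroup-only clade — ties broken by the
clade holding the lexicographically smallest tip label — and the decision is
logged as a warning record rather than discarding the tree.

**Pruning.** Every non-hybrid species keeps one *best copy*. "Best" is
primarily the longest sequence (a gene-id → bp table, the natural criterion
for transcriptome isoforms); when no length table is available the terminal
branch length is the documented fallback, and remaining ties go to the
lexicographically smallest gene id so reruns are identical. If a species'
copies are not monophyletic the globally longest copy is kept and the tree
is flagged, rather than discarded: paraphyletic copies are often caused by a
single misplaced isoform, and the conversion log preserves the audit trail.
Pruning is pure restriction — the output topology is exactly the induced
tree on the kept tips, an invariant the test suite checks against
`ape::keep.tip` on every simulated tree.

**Labeling.** For each copy of each hybrid we walk rootward from the tip to
the first ancestor whose descendants include at least one *non-hybrid*
taxon; those taxa are the copy's witnesses. A copy is labeled `A` if all
witnesses lie in lineage A, `B` if all lie in lineage B, and `unassigned`
otherwise (dropped, logged). Tips of **all** hypothesized hybrids are
skipped as witnesses, not only the focal one: two co-occurring hybrid
cultivars of the same parents are routinely each other's nearest neighbors,
and skipping them breaks that circularity without biasing the witness set.
If several copies receive the same label, the longest wins and the hybrid is
flagged uninformative for its A/B split; the tree is still emitted since it
remains informative about the rest of the phylogeny.

An optional `min_support` collapses weakly supported internal edges to
polytomies before labeling; a polytomous witness set is evaluated by exactly
the same rule.

## Concordance counting

`count_support()` classifies every (gene tree, reference clade) pair after
mutually restricting both trees to their shared taxa, with MUL labels
treated as distinct taxa. A clade reduced below two members, or with no
surviving non-member, is uninformative. Otherwise the gene tree is
concordant if some clade equals the restricted reference clade and
conflicting if some clade properly overlaps it. Polytomies are *soft*: an
unresolved gene tree that neither matches nor properly overlaps counts as
uninformative, never as conflict. Counts therefore always sum to the number
of gene trees at every clade — a conservation invariant asserted in the
tests. Rooted-clade semantics (rather than unrooted bipartitions) are used
deliberately: the counts annotate a rooted reference phylogeny and the
shared outgroup makes rootings comparable.

`hybridization_report()` then reads off, per (hybrid, label), the smallest
reference clade joining the labeled tip to its candidate lineage, and calls
the hypothesis supported when both labels' attachment clades show more
concordance than conflict. When conversion logs are supplied it also
reports the modal witness set per label — a donor estimate driven purely by
the gene trees, used by the moderate-ILS recovery checks.

## Quartet summary

`infer_summary_tree()` maximizes the number of (gene tree, 4-taxon subset)
pairs whose induced quartet agrees with the candidate tree — the consistent
statistic at the heart of ASTRAL-class summary methods, reimplemented here
explicitly so its behavior on MUL-labeled taxa is fully specified. Quartet
topologies are resolved through the four-point condition on unit-branch-
length path distances, which maps polytomy-crossing quartets to
"unresolved" exactly. Exact mode enumerates all `(2n−5)!!` unrooted
topologies (capped at 8 taxa; enumeration order is `phangorn::allTrees`,
ties broken by the first maximizer and flagged). Heuristic mode starts from
neighbor joining on quartet-mismatch distances (the fraction of resolved
gene quartets that separate a pair) and performs steepest-ascent NNI until a
local optimum; on the 20-taxon simulated datasets below it recovers the
generating topology exactly. Each internal branch is annotated with the
fraction of resolved gene quartets spanning it (two taxa a side) that agree
with it. Supermatrix maximum-likelihood summarization of the labeled
alignments is an external step and out of scope; its natural insertion
point is the MUL trees written by the pipeline.

## The simulator and what it emulates

`simulate_dataset()` draws gene trees under the multispecies coalescent on
a species tree with branch lengths in coalescent units (implicit population
size 1 per branch, one haploid lineage per taxon per gene — the minimal
structure the subgenome model requires; within-species polymorphism is out
of scope). `build_mul_species_tree()` grafts each allopolyploidy event as
two tips, `A-H` on the A donor's lineage and `B-H` on the B donor's, both
diverging `t_hyb` units before present; donors are extant leaves. Each
hybrid subgenome then coalesces within its donor lineage exactly like an
ordinary taxon, which is what makes the generated trees a faithful fixture
for the pruning/labeling rules. Paralogs are injected by a Poisson number
of duplications, each copying the subtree below a uniformly chosen edge to
its midpoint as a sister with fresh gene ids; sequence lengths are normal
(default mean 900 bp, sd 200 bp, floored at 100 bp — typical conserved-CDS
scale), with injected copies drawn at 40–90% of their source's length by
default so that longest-copy pruning corresponds to the truth, as it does
for real fragmentary isoforms.

The generator is deterministic: gene `i` uses a fixed sub-seed derived from
the master seed and `i` alone, so per-gene output is independent of
`n_genes` and whole datasets replay byte-identically. The RNG contract is
R's default generator with one `set.seed` per gene; cross-language ports
should match topological distributions, not bitstreams.

Per-tip dropout is available (`missing_rate`, outgroup protected) but
**defaults to 0**: the simulator emulates the downstream product of an
orthogroup pipeline that has already filtered for coverage and group
representation — curated multi-copy families carrying both hybrid copies —
not raw transcriptome incompleteness. Tests that exercise the coverage
filter turn dropout up explicitly (0.25–0.35). Features of real data the
simulator deliberately omits: gene-tree estimation error (all "inferred"
topologies are true coalescent genealogies), alignment-length variation
tied to phylogenetic signal, gene loss beyond dropout, and repeated
hybridization into the same hybrid. Passing the recovery tests therefore
shows the *method* is correct under its model, not that real transcriptome
noise is harmless.

`waterlily_scenario(units)` bundles the built-in study design: 18 taxa (15
water-lily-like ingroup species, two aquatic outgroup-family taxa, one
distant outgroup), two hybrid cultivars formed from the *N. colorata* and
*N. caerulea* lineages at `1·units` and `2·units` before present, the nine
required taxon groups, the >50% coverage rule and the hybridization
hypotheses. Every internal branch is a multiple of `units` coalescent
units, so `units = 5` gives a low-ILS regime (per-branch discordance
(2/3)e^(−5) ≈ 0.45%) and `units = 0.5` a moderate one (≈ 40%). The two
hybridization times differ so that the two A (and two B) subgenome tips
attach at nested, distinguishable positions. The nine groups follow the
historical study design and are *not* disjoint — the two hybrids belong to
two groups — so group definitions are validated against the universe but
not for disjointness.

## Numerical choices and degenerate inputs

* "More than 50% coverage" is strict (`>`), configurable via
  `coverage_strict`; multiple copies of a taxon count once.
* Monophyly constraints use taxon-set clade equality on the rooted tree,
  absent members ignored (vacuously true with a warning when none are
  present); by default they are evaluated *after* pruning non-hybrid
  paralogs, since a single stray isoform inside a family clade would
  otherwise fail trees the curated analysis would keep.
* All tie-breaks (copy selection, exact-mode enumeration, NNI moves) are
  fixed and documented; reruns are identical.
* Fewer than four taxa yield a star summary tree with an explanatory note;
  a filter that keeps zero trees aborts the pipeline with a stage-named
  error; a hybrid with no assignable copy flags the tree uninformative
  rather than failing.
* Quartet tallies and scores use exact integer distance comparisons (unit
  branch lengths), so polytomy detection has no floating-point fragility.

## Problem sizes used by the checks

The shipped verification uses 300 genes for the low-ILS recovery run, 5 ×
300 genes for moderate-ILS replicates, 200 trees for the invariant sweep,
10,000 4-taxon genes per point for the coalescent calibration
(|observed − (2/3)e^(−T)| within three binomial standard errors at T = 0.5
and 2), and 20 six-taxon datasets for brute-force oracle equivalence of the
quartet and concordance machinery. These sizes give the calibration tests
sub-percent standard errors while keeping a full run in the minutes range
on a single core.

## Known limitations

* Hypotheses are inputs: the package localizes and quantifies a
  hybridization signal but does not search for unknown hybrids (no
  GRAMPA-style search over MUL placements, no reconciliation costs).
* Witness-based labeling degrades gracefully but noticeably under strong
  ILS: copies become `unassigned` (mixed witnesses) before they become
  mislabeled, which is the conservative failure mode.
* The summary step claims quartet-score optimality (exact mode) or local
  optimality (heuristic), not equivalence with any external ASTRAL
  implementation; branch lengths in coalescent units are not estimated.
* Newick is the only tree format; NEXUS/PhyloXML are out of scope.
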