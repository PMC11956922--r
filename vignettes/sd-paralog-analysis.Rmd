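---
title: "Paralog identity, gene conversion and regulatory sharing in segmental duplications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paralog identity, gene conversion and regulatory sharing in segmental duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

The human *NOTCH2NL* genes sit inside segmental duplications (SDs) on
chromosome 1 that are hundreds of kilobases long and more than 99% identical
to each other. Five canonical positions carry family members: the ancestral
*NOTCH2* and the pseudogene *NOTCH2NLR* on the p-arm, and *NOTCH2NLA*,
*NOTCH2NLB*, *NOTCH2NLC* on the q-arm. At this identity level, a paralog's
own sequence is an unreliable witness to which genomic position it occupies:
interlocus gene conversion (IGC) can overwrite one copy with another's
sequence while leaving the surrounding megabase of genomic context
untouched, and non-allelic homologous recombination deletes or duplicates
whole copies. `sdparalog` implements the computational workflow for
characterizing such a family across a cohort of haplotype-resolved
assemblies: synteny and identity of the paralogous regions, duplicon
barcodes for map location, a tripartite identity assignment whose internal
disagreements expose gene conversion, haplotype-configuration
classification, strict-clock dating of the duplications, and the sharing
structure of accessible chromatin elements across the copies. A synthetic
cohort generator with complete ground truth makes every stage testable
without any external data.

# The tripartite identity workflow

Each assembled locus is assigned three independent identity signals:

1. **Best transcript match** — the locus CDS is globally aligned (unit
   mismatch and gap costs) against the reference CDS panel; the label with
   the fewest mismatches (substitutions plus indel bases) wins, with the
   margin to the runner-up retained. An exact tie is reported as
   `ambiguous` together with the tied labels; a tie between the A and B
   panel entries is the operational signature of an A/B-hybrid coding
   sequence.
2. **Phylogenetic clade** — intron 2 of the locus is placed in a
   neighbor-joining tree of the reference intron panel plus outgroup, built
   from Jukes–Cantor distances; the clade label is the reference leaf at
   minimum patristic distance, with a monophyly check and tie flagging.
3. **Map location** — the ordered, oriented duplicon tokens within a window
   around the gene form a *barcode*; the locus is assigned to the reference
   barcode at minimum Levenshtein distance over (token, orientation)
   symbols. Token lengths are ignored: the comparison mirrors the
   qualitative, order-and-orientation use of duplicon tracks. A zero margin
   between the two nearest references is reported as `ambiguous` rather
   than resolved arbitrarily.

The calling rules are applied in order: agreement of all three signals is a
clean call; agreement of the two sequence signals against the location is an
IGC call with the sequence label as donor and the location as acceptor
(donor *NOTCH2* at the *NOTCH2NLR* location is the *NOTCH2tv* state); a tied
A/B transcript at the NLC location is the hybrid state; any remaining
transcript/clade disagreement, or an ambiguous location, leaves the call
ambiguous. The rule order and the ambiguous catch-all are this package's
construction — conflict cases that a human curator would resolve by
inspection are deliberately left unresolved rather than guessed.

Conversion tracts are delineated from a windowed identity profile of the
acceptor against the expected donor and the location's own reference: the
maximal run of at least `min_run = 3` consecutive windows in which the donor
identity both exceeds the location-reference identity and reaches the
threshold. Windows are 1 kbp and non-overlapping; the threshold is 99.9%,
the near-perfect-identity signature of recent conversion. The source bin
size behind that visual signature is not published; 1 kbp windows make the
±1-window tract tolerance concrete.

# Identity and synteny semantics

The synteny engine seeds on k-mers unique in both sequences (both strands,
k = 21 by default), extends them to maximal exact matches, chains colinear
anchors (gap ceiling 10 kbp, minimum chain span 1 kbp), and aligns the
inter-anchor gaps exactly by banded unit-cost dynamic programming (the band
doubles until the optimum provably fits, so the result equals the full DP).
Identity is `100 * matches / aligned_columns` with every indel base counted
as one column ("blast identity"); a `gap_compressed` flag counts each indel
run once instead, since the source definition — "number of base matches" —
does not fix the denominator. The *longest non-overlapping stretch of
syntenic sequence* between two regions is the query span of the longest
chain after resolving query overlaps by score (ties leftmost); overlap
resolution is likewise unstated at the source and is fixed here by that
rule. `N` and lowercase handling: comparison is case-insensitive and any
non-ACGT symbol matches nothing, including itself.

Pairwise region matrices are computed once per unordered pair and mirrored,
so identity and length are exactly symmetric by construction. The published
five-region homology table ships as a plain-text fixture; its derived
statistics (mean longest-synteny length, maximum off-diagonal identity) are
recomputed from the file by the same code that summarizes simulated
matrices. Recomputing the matrix from the actual reference assembly is
supported by the same `identity_matrix()` call but requires the assembly
sequence, which is not shipped.

# The synthetic cohort generator

The generator is first-class, tested code that defines the study
conditions; it is not a tuning knob.

**Family model.** A uniform-random ancestral locus evolves along a
divergence ladder under Jukes–Cantor substitutions (Poisson counts per
branch, no indels on gene bodies), with per-lineage clock rate `mu`
(substitutions/site/Myr). Two copies split T Myr ago are expected to differ
at `2 mu T` of sites. Default ladder: family origin 4.5 MYA, NLC split 2.8
MYA, NLA/NLB split 1.6 MYA; the outgroup splits at 15.2 MYA, the calibration
point. *NOTCH2NLR* is not dated by the source analysis; the ladder places it
at 3.5 MYA, between the family origin and the NLC split, consistent with
its intermediate divergence from the ancestral gene. `mu` itself is a free
parameter (the source pipeline's rate is internal to its dating tool):
the default 1e-3/site/Myr per lineage gives the >99% inter-paralog
identities characteristic of these SDs.

**Geometry.** Default loci are 20 kbp with five exons (400 bp each; four
N-terminal exons plus a distal fifth exon whose sequence stays
acceptor-specific under the *NOTCH2tv* conversion) and 5 kbp flanks tiled
with ~300 bp duplicon tokens. Real regions are 1 Mbp with megabase barcode
windows; the simulated scale keeps a 100-haplotype cohort's full workflow in
minutes while preserving every structural relationship the caller depends
on. The barcode window in the simulated pipeline is therefore the whole
record rather than ±1 Mbp.

**Barcodes.** Each paralog receives `barcode_fixed_edits = 5` distinctive
token substitutions at token slots disjoint across paralogs — guaranteeing
reference barcode separation — plus Poisson(1) random token insertions.
Haplotype-level barcode noise is Poisson(0.5) token edits clamped at 2.
The source states only that barcodes differ; the edit counts are chosen so
that reference separation (≥ 6) strictly dominates query noise (≤ 2),
the regime in which location assignment is provably unambiguous.

**Configurations and conversions.** Each haplotype draws a configuration
from the catalog frequencies (or receives one by exact largest-remainder
apportionment). Conversion events are placed as: B→A tracts covering the
full gene span with geometric margins (mean `igc_tract_mean`); *NOTCH2tv*
tracts from the locus start (promoter side) through intron 4, never
touching exon 5 — the converted pseudogene keeps its own terminal exon; NLC
hybrids copy donor A then donor B around a breakpoint chosen so the exonic
mismatch counts to the two donors tie exactly (an odd difference count is
balanced by one site matching neither donor). Private polymorphism
(5e-4/site, human-heterozygosity scale) is applied before conversion, so
converted tracts are exact donor copies — which is what makes the
100%-identity tract signature in the window profiles exact, and is the
truth invariant the tests verify. Deletions remove the locus record
entirely; deleted loci carry no conversion events.

**Determinism.** Every public generator entry point seeds (and restores)
the RNG from `config$seed` and consumes a single stream in documented order
(ancestor → family → cohort), so identical configurations give identical
cohorts.

**What the generator does not emulate.** No indels inside gene bodies, no
inversions at sequence level (orientation is a token attribute only), no
NAHR breakpoint mechanics, no sequencing reads or chromatin fibers, and no
population structure. Passing the end-to-end tests therefore demonstrates
the correctness of the calling logic under the stated conditions — clean
divergence, exact conversion tracts, separated barcodes — not robustness to
assembly error or to conversion tracts much shorter than the window size.

# The configuration catalog

Configurations are templates over the five canonical positions with states
drawn from {paralog label, converted label, `absent`, `hybrid`}; the
catalog is an editable table, not hard-coded logic, because the full
per-configuration composition of the published set is only partly stated in
text. The default encodes every textual constraint: H1 canonical;
H2/H4/H8/H9 deletion-class; H3/H6 carrying *NOTCH2tv*; H4/H5/H6 carrying
B→A; H7/H8 lacking NLC; H10 an NLC A/B hybrid. Two compositions are genuine
catalog choices. **H9** is fixed as NLR deleted + NLC deleted + B→A — the
only deletion-class template distinct from H8 under this state alphabet —
so its A-state at the B position counts toward the B→A fraction. **H10** is
additionally assigned an NLR deletion: the published counts (21
deletion-class + 7 *NOTCH2tv* haplotypes, yet 30 of 69 lacking NLR) are
mutually inconsistent by two haplotypes if NLR loss occurs only in the six
configurations listed for it, and placing the two missing NLR losses on the
two H10 haplotypes is the minimal resolution that reproduces every printed
fraction simultaneously. Users with access to the full figure-level
composition can swap in their own catalog TSV.

Summary percentages are rounded half away from zero — the convention
required to reproduce the printed 28/43/30/20/10 values. The union IGC
fraction counts haplotypes with a B→A or *NOTCH2tv* state once (hybrids are
not counted in the union, matching the printed arithmetic of 14 + 7 − 2
events). The combined NOTCH2NLA + NOTCH2NLB copy number is checked to be 2
on every haplotype and violations are flagged rather than silently
accepted.

# Dating under a strict clock

For a pair of lineages and an outgroup aligned over the same columns,
`T = (d_pair / d_outgroup) * calibration` with JC69 distances,
`calibration = 15.2` MYA, and `d_outgroup` the mean of the two
lineage-to-outgroup distances. The estimator is scale-invariant in the
distances. Confidence intervals are a percentile bootstrap (2.5/97.5) over
alignment columns, resampling all three pairwise comparisons jointly so
their correlation is preserved; 1000 replicates by default. This replaces
the source's maximum-likelihood tree plus least-squares dating machinery,
which is out of scope here; the point estimates are comparable at the
simulated divergences (far from saturation), but the interval convention is
different and interval widths are not expected to match the published ones.
Neighbor joining (via `ape`) with label-ordered taxa and negative branch
lengths clamped to zero stands in for ML tree inference for the same
reason; on additive matrices the two agree exactly, which the tests verify
against an exhaustive topology oracle for 4 and 5 taxa.

# Accessible chromatin elements

Percent actuation of an element is `100 * fibers_fire / fibers_total`
(undefined at zero coverage). Elements are lifted through syntenic block
alignment paths; a projection is retained when at least `min_cover = 0.5`
of the element lies inside the block — the operational meaning of "shares
duplicated sequence", for which the source states no overlap criterion.
Categories partition the elements: `UNIQUE` (no retained projection),
`XCHR_ONLY` (projections exclusively outside the paralog set),
`SHARED_MULTI_ACCESSIBLE` (some within-set projected site overlaps an
accessibility peak by ≥ 1 bp — "some level of accessible chromatin",
likewise unquantified at the source), else `SHARED_SINGLE_ACCESSIBLE`. The
TSS window defaults to 300 kbp and is configurable. The published
real-data fractions require the original Fiber-seq data and are not
reproduced here; the category logic is exercised on constructed fixtures
with known expected fractions.

# Numerical choices and degenerate inputs

* Alignment tie-breaks: the DP traceback prefers diagonal over
  query-consuming over target-consuming moves, making every path
  deterministic; `nw_align()` therefore returns identical output on
  repeated calls, and block identity equals full-DP identity exactly.
* Anchor chains allow ≤ 50 bp anchor overlap, trimmed at stitch time;
  chains split at gaps above the DP limit (5 kbp) with a message.
* Zero-length loci, empty cohorts, empty barcodes, windows larger than the
  acceptor, and zero-length conversion tracts are all defined no-ops or
  single-window cases rather than errors; saturation (`mu * T ≥ 0.75` or
  `p ≥ 0.75`) and zero outgroup distance are hard errors.
* Integer apportionment of exact cohort counts uses largest remainder with
  deterministic tie-break by catalog order.

# Problem sizes

The test suite and the acceptance script run the full workflow on cohorts
of 69–100 haplotypes with 20 kbp loci and 5 kbp flanks, 200 random
alignment pairs up to 2 kbp against the full-DP oracle, 20 additive
matrices against the exhaustive topology oracle, and 50 dating replicates
with 1000 bootstrap columns resamples each. These sizes were chosen so the
complete suite runs in a few minutes on one core while every statistical
check retains enough replication to be meaningful. The end-to-end recovery
cohorts use `mu = 2e-3` so that the youngest paralog pair (1.6 MYA) exceeds
0.5% divergence, the floor under which the recovery guarantees are stated.

# Known limitations

* Identity assignment presumes the reference panel spans the true donors;
  a conversion from an unmodeled donor will surface as `ambiguous`, never
  as a wrong confident label.
* Barcode distance treats tokens as symbols; two loci with identical token
  strings but different token lengths are indistinguishable.
* The chainer bridges gaps up to `max_gap` regardless of gap content, so
  "shares duplicated sequence" at coarse `max_gap` can include
  non-homologous insertions; projection-sensitive analyses should tighten
  `max_gap` (the regulatory driver uses 500 bp).
* Strict-clock dating inherits the constant-rate assumption; rate variation
  across lineages biases the estimates and is not modeled.
* The window profile attributes target-only (deletion) columns to the
  acceptor window at the deletion point, which can depress that single
  window's identity.
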