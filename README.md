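# sdparalog

Paralog identity, interlocus gene conversion and regulatory sharing in
high-identity segmental duplications, modeled on the human *NOTCH2NL* gene
family.

## The problem

*NOTCH2NL* genes — implicated in human cortical expansion — live inside
segmental duplications (SDs) on chromosome 1 that are hundreds of kilobases
long and >99% identical. Five canonical positions carry family members
(*NOTCH2*, *NOTCH2NLR*, *NOTCH2NLA/B/C*). At this identity, the sequence of
a copy does not tell you which position it occupies: interlocus gene
conversion (IGC) overwrites one paralog with another's sequence while
leaving the flanking megabase untouched, and recurrent deletions remove
copies outright. `sdparalog` is an analysis toolkit for geneticists working
with haplotype-resolved assemblies of such regions. It provides:

* a **synthetic cohort generator** with complete ground truth (divergence
  times, substitutions, conversion tracts, deletions, configuration
  labels), so the whole workflow is testable without downloads;
* a **pairwise synteny engine**: unique-k-mer anchors, colinear chaining,
  exact unit-cost gap alignment, longest-syntenic-block identity matrices,
  1 kbp windowed identity profiles, indel extraction;
* **duplicon barcodes**: ordered, oriented duplicon tokens flanking a locus
  compared by edit distance to assign map location;
* the **tripartite identity workflow** — (i) best transcript match (fewest
  CDS mismatches), (ii) phylogenetic clade (neighbor joining on intron
  distances with an outgroup), (iii) map location (nearest barcode) — whose
  internal disagreements call gene conversion, including the *NOTCH2tv*
  state (a *NOTCH2*-converted *NOTCH2NLR*) and A/B-hybrid calls;
* **haplotype-configuration classification** against an editable H1–H10
  catalog, with cohort summaries (conversion fractions, deletion classes,
  copy-number constancy checks) and Fisher-exact enrichment tests;
* **strict-clock dating**: `T = (d_pair / d_outgroup) * T_cal` with JC69
  distances, calibrated at the 15.2 MYA outgroup split, percentile
  bootstrap over alignment columns;
* **accessible-element categorization**: percent actuation
  (`100 * fibers_fire / fibers_total`), projection of elements through
  syntenic blocks, and the UNIQUE / SHARED_MULTI_ACCESSIBLE /
  SHARED_SINGLE_ACCESSIBLE / XCHR_ONLY partition.

Identity everywhere is `100 * matches / aligned_columns` with each indel
base one column; every identity reported by the anchored engine equals the
full global-DP identity exactly.

## Worked example

Simulate a small cohort, run the tripartite workflow, and date the
youngest paralog split:

```r
library(sdparalog)

cfg <- sim_config(seed = 42, n_haplotypes = 8, mu = 2e-3)
cohort <- simulate_cohort(cfg)
res <- call_cohort(cohort)
res$summary
#> Cohort summary over 8 haplotypes
#>   configurations:
#>     H1       2 (25%)
#>     H2       1 (13%)
#>     H3       1 (13%)
#>     H5       1 (13%)
#>     H7       1 (13%)
#>     H8       2 (25%)
#>   lacking NOTCH2NLR: 4 (50%)
#>   deletion-class configurations: 3 (38%)
#>   B-to-A conversion: 1 (13%)
#>   NOTCH2tv: 1 (13%)
#>   any gene conversion (union): 2 (25%), both: 0
#>   A+B copy-number violations: 0

subset(res$calls, status == "igc",
       select = c(haplotype, position, transcript, clade, location,
                  consensus, tract_start, tract_end))
#>  haplotype  position transcript     clade  location consensus tract_start tract_end
#>     hap003 NOTCH2NLB  NOTCH2NLA NOTCH2NLA NOTCH2NLB NOTCH2NLA        2000     16000
#>     hap004 NOTCH2NLR     NOTCH2    NOTCH2 NOTCH2NLR  NOTCH2tv           0     13000
```

Read the conversion calls: on `hap003`, both sequence signals say
*NOTCH2NLA* but the barcode places the locus at the *NOTCH2NLB* position —
a B→A conversion, with the tract delineated to 2,000–16,000 (the simulated
tract covers the full 2,000–15,400 gene span plus margins). On `hap004`
the *NOTCH2NLR* locus carries *NOTCH2* sequence over its promoter through
intron 4 — the *NOTCH2tv* state. The configuration classifier turns these
calls into H5 and H3 labels, and `res$summary` aggregates the cohort.

```r
fam <- cohort$family
date_divergence(
  c(locus_sequence(fam$records$NOTCH2NLA),
    locus_sequence(fam$records$NOTCH2NLB)),
  locus_sequence(fam$outgroup), calibration = 15.2)
#> <time_estimate> 1.72 MYA (95% CI 1.44-2.03), calibration 15.2 MYA
```

The A/B split was simulated at 1.6 MYA; the strict clock, calibrated on the
15.2 MYA outgroup, recovers it within the bootstrap interval.

The `analysis/` directory contains the numbered drivers of the full study
workflow (`01_simulate_cohort.R` … `06_regulatory_elements.R`); each writes
its tables under `results/` and prints a one-paragraph account of what it
found. The methods vignette (`vignettes/sd-paralog-analysis.Rmd`) documents
the models, parameter choices and limitations.

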