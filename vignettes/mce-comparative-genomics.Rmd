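---
title: "Comparative genomics of MCE-domain proteins: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative genomics of MCE-domain proteins: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcetools)
```

## The problem

MCE (Mammalian Cell Entry) domains are ~81-residue modules of bacterial
inner-membrane lipid-transport proteins. In *E. coli* the single-domain
protein MlaD works inside an ABC transporter maintaining outer-membrane lipid
asymmetry, while PqiB and YebT carry three and seven MCE domains
respectively. Comparative questions about this family — which architectures
exist, how they distribute over phyla, how the multi-domain forms relate to
the single-domain ones, and which genes co-occur in their operons — reduce to
four computations that this package implements as a tested pipeline:

1. **Architecture assignment**: per-protein domain hits → one ordered
   architecture → a type label.
2. **Prevalence**: phylum × type percentage matrix over one representative
   genome per species.
3. **Similarity network**: representative selection plus a thresholded
   all-vs-all alignment graph whose components approximate families.
4. **Gene neighbourhoods**: slot-indexed operon contexts around MCE genes,
   clustered with a centre-weighted similarity.

## Architecture assignment

Hits below their family's gathering bit-score threshold are discarded
(`filter_significant()`; unlisted families fall back to a configurable
default, 25 bits). Overlapping predictions from the same Pfam clan are
redundant readings of one region, so only the most significant survives.
The resolution is greedy in descending bit score (ties: smaller start, then
lexicographic name): a non-MCE hit is dropped iff it overlaps an
already-retained non-MCE hit of the same clan. MCE hits are exempt in both
directions — never removed, never the cause of a removal. This greedy rule
equals the unique maximal hit subset in which no two retained same-clan
non-MCE hits overlap and every removal is justified by a retained
higher-scoring overlapping clan-mate; the test suite checks that equivalence
against an exhaustive subset-enumeration oracle on a thousand random
proteins. Note the closure of repeated *pairwise* "keep the more significant
hit" resolution is exactly this greedy rule, not "one survivor per overlap
component": in a chain A(60)–B(50)–C(40) where only adjacent hits overlap,
B's removal by A frees C, and {A, C} survive.

Two numerical choices are deliberate: overlap means ≥ 1 shared residue on
closed envelope intervals (envelope, not alignment, coordinates — the
standard choice for architecture building), and equal-score ties break by
start position then name so the pipeline is deterministic under input
shuffling.

Surviving domains sorted by start position form the architecture; the type
scheme is: type I = `MCE` alone; type II = `MCE, DUF3407` in that order and
nothing else ("followed by" is read as strictly ordered); type III / IV =
exactly three / seven MCE domains in tandem, where tandem means consecutive
list entries with no intervening domain and **no** constraint on residue
gaps (none is defined for this family); anything else with an MCE domain is
`other_mce`. Architecture strings that annotate the same gene product
differently are canonicalised through a synonym map (default:
`ABC_tran, AAA_21` → `ABC_tran`); the map is validated at load time so that
canonicalisation is idempotent.

## Prevalence

Sequence databases over-represent well-studied species, so one genome per
species is chosen uniformly at random — but, unlike ad-hoc selection, from a
recorded seed, making the matrix reproducible. A species is positive for a
type iff its representative genome encodes ≥ 1 protein of that type;
phylum percentages use all sequenced species of the phylum in the input as
the denominator (species with no MCE protein still count). Phyla with zero
species are omitted rather than shown as 0% — the denominator is undefined.
Row ordering is presentation, not computation, and stays alphabetical.
MCE-containing proteins whose metadata is non-bacterial are flagged for
review (`flag_suspect_eukaryote_hits()`), automating the
bacterial-contamination screen up to — but not including — removal.

## Similarity network

Representative selection re-implements the greedy incremental semantics of
CD-HIT at 50% identity over a caller-supplied identity table: proteins are
processed longest-first (ties by id) and join the earliest-founded cluster
whose representative they match at or above the cut-off, else found a new
cluster. CD-HIT's short-word heuristics are deliberately **not** reproduced;
this is a semantic, not bit-level, stand-in, and the identities come from
the alignment table (planted, in the synthetic world) rather than from an
internal aligner, keeping the package deterministic and download-free.

The network keeps an edge iff the best directional e-value is ≤ 1e-15 —
inclusive, matching BLAST-community convention; the boundary case is
asserted in the tests. Reciprocal hits collapse to one undirected edge
(min e-value, max bit score). Edgeless representatives are retained as
singleton nodes: dropping them would silently change component counts and
phylum compositions. Components are labelled in decreasing size order and
exported with per-phylum/per-type composition; GraphML and SIF exports are
Cytoscape-ready.

## Gene neighbourhoods

For each focal MCE gene (types I, III, IV), up to 10 genes per side within
10 kb are taken in order of increasing distance, where distance is measured
between nearest gene boundaries (not midpoints — stated here because the
choice is otherwise invisible). Minus-strand focal genes have their sides
swapped so slot −1 is always the first gene upstream in reading direction.
Neighbour genes carry their canonical architecture string; genes with no
significant domain get the matchable string `"NONE"`, so shared
domain-less genes count as agreement. The focal gene itself is not a slot —
it would be identical by construction.

The similarity between two neighbourhoods is the weight-normalised fraction
of agreeing slots over the slots occupied in either, with weights
`w(i) = r^(|i|−1)`, `r = 0.5` by default. Only the monotonicity of the
weighting ("closer genes matter more") is inherent to the method; the
exponential form and its ratio are this package's concretisation, exposed as
configuration so alternatives are a one-line change. Normalising by the
occupied-slot weight sum means short neighbourhoods at contig ends are not
penalised for absent-vs-absent slots, while present-vs-absent counts as a
mismatch. Worked example: with `r = 0.5`, slots ±1 agreeing and slot +2
disagreeing (all else empty) give S = (1 + 1)/(1 + 1 + 0.5) = 0.8.

Clustering is agglomerative with single linkage ("nearest neighbour
joining"), merging the most similar pair of clusters until the best
similarity falls below τ = 0.5, with a deterministic lexicographic
tie-break and a recorded merge trace — replacing manual selection of common
neighbourhoods from diagrams with a threshold plus a reviewable trace.
Complete and average linkage sit behind the same interface. Each cluster is
summarised by its majority architecture per occupied slot and by the
percentage of all focal genes of that type it contains, so percentages over
clusters sum to ≤ 100 with singletons included.

## The synthetic world

`simulate_dataset()` emits the four input files with planted truth. Its
defaults are the stated biological world, chosen once and not revisited:

* **Taxonomy**: 8 phyla × 10 species × 1 genome (all configurable), real
  phylum names with one Actinobacteria-like and one Proteobacteria-like
  phylum. Type I is planted widely (probability 0.9 per species; 0.4 in one
  early-branching phylum), type II only in Actinobacteria (0.9), types
  III/IV only in Proteobacteria (0.8/0.5) — the qualitative distribution the
  field reports. Presence is planted at species level and copied to every
  genome of the species, which is what makes representative-genome choice
  provably inert.
* **Operon contexts** per focal type mirror the *E. coli* operons: ATPase +
  permease upstream and DUF330 downstream of type I (mlaFEDCB-like), a
  twin-PqiA-domain gene upstream and DUF330 downstream of type III
  (pqiA–pqiB–ymbA), the PqiA gene but no DUF330 for type IV (yebS–yebT).
  Intergenic gaps are uniform on 50–500 bp; blocks are isolated by
  > 10 kb gaps so planted contexts cannot bleed into each other, and a
  configurable fraction of filler genes sits beyond the window to exercise
  the 10 kb cut. Half the filler genes (default) carry no significant
  domain — realistic for Pfam coverage of bacterial genomes — and the rest
  draw 1–2 domains from a fictional `NBR###` vocabulary disjoint from all
  planted names.
* **Noise**: decoy hits (fictional `DCY###` names) score strictly below the
  gathering threshold; planted same-clan overlap conflicts (`CONF_A/B`,
  clan `CL_CONF`) have their intended survivor recorded in the truth.
* **Families**: each (phylum, type) pair of MCE proteins forms a family;
  within-family e-values are log-uniform at or below 1e-15, cross-family
  strictly above 1e-12, so the network recovery criterion is exact by
  construction. Identities are 55–95% within and 10–35% between families.
* One eukaryote species with a planted type I protein (default) feeds the
  contamination screen.

What the generator does **not** emulate: amino-acid sequences (scores and
identities are planted, never computed from sequence), rate variation across
lineages, horizontal transfer, assembly or annotation error beyond the decoy
model, and operonic read-through across the planted isolation gaps. A green
recovery test therefore establishes that the pipeline's logic is faithful to
its contracts — not that real HMMER/BLAST scores behave like the planted
ones. Format fidelity against real tools is tested separately on static
`hmmsearch --domtblout` and `blastp -outfmt 6` outputs.

`ecoli_fixture()` is the deterministic, hand-written miniature of the three
*E. coli* operons used in the README worked example; running the pipeline on
it labels the three focal proteins I, III, IV and recovers the PqiA/DUF330
flanks of *pqiB*.

## Design decisions that were genuinely open

* **Clan-overlap scope.** Pairwise "most significant survives" admits two
  closures: one survivor per overlap component, or greedy descending-score
  resolution. They differ on chains (see above); the greedy closure is the
  one consistent with an exhaustive maximal-subset oracle and with
  `pfam_scan`-style behaviour, so it is the implementation.
* **MCE exemption.** MCE hits are immune to removal; symmetric analysis of
  the oracle shows they also cannot justify removing a clan-mate (the
  subset keeping both is valid and larger), so the exemption is two-sided.
* **Type II order.** `MCE, DUF3407` is required in that order; the reversed
  architecture is `other_mce`. An N-terminal transmembrane helix is treated
  as descriptive, not a classification criterion.
* **Window distance.** Nearest-boundary distance, not midpoint; a gene
  overlapping the focal gene has distance 0 and sides are assigned by
  midpoint.
* **Config format.** JSON only; the pre-installed R stack has no YAML
  parser, and a second config dialect buys nothing.
* **Similarity of two empty neighbourhoods** is defined as 1 (identical
  occupied-slot patterns); it cannot arise from extraction, which always
  has a focal gene, but the function is total.

## Limitations

Greedy representative clustering is order-dependent by design (that is the
CD-HIT semantic); it is not a globally optimal clustering. The neighbourhood
similarity ignores neighbour strand and intergenic distances — only
architecture content per slot matters. Phylum-level prevalence inherits
whatever taxonomy the input tables carry; no name reconciliation is
attempted. The agglomerative clustering is O(n²)–O(n³) and intended for the
hundreds-to-thousands of neighbourhoods typical per type, not for millions.
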