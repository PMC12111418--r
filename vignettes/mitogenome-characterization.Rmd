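---
title: "Characterizing circular mitochondrial genomes with mitochar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing circular mitochondrial genomes with mitochar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochar)
```

## The problem

A newly sequenced vertebrate mitogenome — here the ~16.6 kb circular
genome of a teleost fish, carrying 13 protein-coding genes (PCGs),
22 tRNAs, 2 rRNAs and a control region (D-loop) — is routinely
characterized by a standard battery of descriptive and evolutionary
statistics: gene arrangement on the circle (intergenic spacers and
overlaps, strand usage, start/stop codon forms), base composition with
strand-asymmetry skews, relative synonymous codon usage (RSCU),
selective pressure on the PCGs (Ka/Ks), and a phylogenetic placement
from concatenated PCGs. `mitochar` implements this battery as a single
auditable pipeline, together with a synthetic-data generator so that
every stage can be exercised and validated without downloading
accessions.

## Coordinate model

Coordinates are 1-based and fully inclusive, the convention of published
mitogenome structure tables; light-strand (L) genes are printed with
descending coordinates and normalized on input (`normalize_feature()`).
The signed spacer between consecutive features is
`start(next) - end(prev) - 1` (positive gap, negative overlap), and the
wrap-around pair closes the circle with
`(length - end(last)) + (start(first) - 1)`. This yields an exact
integer identity used as a pipeline-wide invariant:

```{r closure}
tpl <- fish_mito_template()
adj <- compute_adjacencies(tpl)
sum(tpl$features$size) + sum(adj$spacer) == tpl$length
```

Features that wrap the origin of the circle are not supported: in the
canonical vertebrate order the control region ends at the last position
and tRNA-Phe starts at position 1, so no feature needs to wrap. This
simplifies the adjacency arithmetic and is a documented limitation.
Feature order is `(start, end, name)` — a stable tie-break for abutting
features sharing a start. A printed "intergenic spacer" column is never
trusted on input: it is redundant with the coordinates, so it is
recomputed and mismatches are surfaced as validation warnings.

## Composition and skews

AT-skew `(A - T)/(A + T)` and GC-skew `(G - C)/(G + C)` are computed
from exact base counts, never from rounded percentages; rounding to the
published precision (percentages to 1 decimal, skews to 3) happens only
in reports. `N` bases are excluded from all denominators, and degenerate
denominators (e.g. a G+C-free region) yield flagged `NA` rather than 0.

Two orientation conventions coexist in published composition tables and
are kept deliberately distinct here:

* **Per-region composition rows** (`region_compositions()`) count the
  published (heavy) strand for every region, including light-strand
  genes. ND6 therefore shows strikingly inverted skews relative to the
  other PCGs — exactly as in published tables.
* **Codon-level analyses** (`codon_position_composition()`,
  `count_codons()`, Ka/Ks) use coding-strand orientation, because the
  reading frame lives there.

The concatenated "PCGs" region is built codon-trimmed: the 1–2
overhanging bases of incomplete stop codons (five genes ending `T--`,
one ending `TA-`) are excluded, so the region size is exactly 3 times
the pooled codon count (11,403 bp = 3 × 3,801 for the packaged
template, rather than the 11,410 bp interval sum). This choice makes
the region row, the per-position rows and the amino-acid total mutually
consistent. Bases shared by overlapping genes (ATP8/ATP6 and ND4L/ND4
overlap by 7 bp each) are counted once per gene, matching printed
per-gene sizes; the same rule applies to codon counting, so each gene's
codons are counted independently of its neighbors.

## Codon usage

RSCU for codon *c* in a synonymous family of size *k* with family total
*n* is `count(c) * k / n`; single-codon families are identically 1 and
empty families are flagged undefined rather than zero. The genetic code
defaults to NCBI translation table 2 (vertebrate mitochondrial) — never
stated in most mitogenome papers but implied by the taxon and by the
GTG start / AGA-AGG-as-stop conventions; it is a parameter everywhere.
Alternative start codons (the GTG of COX1) are counted as their table-2
amino acid (Val), not forced to Met: the simplest defensible rule, noted
here because it shifts one codon per genome relative to the other
convention. Incomplete stop codons contribute no codon.

## Selection: NG86 Ka/Ks

The Nei–Gojobori (1986) counting method is implemented from scratch:

* **Sites.** Each codon position contributes fractional synonymous
  sites according to its three single-nucleotide neighbors; mutations
  to stop codons are excluded from both the synonymous and
  nonsynonymous tallies, so `S + N <= 3` per codon with equality only
  when no neighbor is a stop. Site totals are averaged over the two
  sequences of a pair.
* **Differences.** Codons differing at 2–3 positions average their
  synonymous/nonsynonymous step counts over all minimal mutational
  pathways with equal weights, excluding pathways through stop codons.
* **Correction.** `pS` and `pN` receive the Jukes–Cantor correction
  `d = -(3/4) log(1 - 4p/3)`; proportions at or beyond the 0.75
  saturation point are flagged undefined rather than clamped.

Equal pathway weighting with JC correction is the textbook form of the
method and the default of the standard desktop tools for this
statistic. Gene-wise summaries average over all `C(n,2)` pairs and emit
*both* `mean(Ka)/mean(Ks)` and the mean of defined pairwise ratios,
because published per-gene bar charts rarely state which aggregation
they used. The implementation is validated against an independent
exhaustive-enumeration oracle on random codon pairs, and `S`, `N`,
`Sd`, `Nd` are exactly symmetric in the two sequences.

## Phylogenetics

Distance-based support only: Jukes–Cantor distances with pairwise
masking of gaps/`N` (saturated pairs flagged), neighbor-joining via the
standard Saitou–Nei agglomeration (delegated to `ape::nj()`, with
negative branch-length estimates clamped to zero and warned about), and
Newick output. Maximum-likelihood and Bayesian inference, model
selection and alignment are deliberately out of scope — they belong to
dedicated external tools — so inputs must be pre-aligned; the simulator
emits gap-free homologous sequences.

## The synthetic-data generator

`simulate_mitogenome()` realizes the packaged 38-feature template
exactly: every gene at its printed coordinates, every PCG an ORF on its
coding strand with the printed start codon (GTG for COX1) and stop form
(complete TAA/TAG or incomplete `T--`/`TA-`), light-strand genes
materialized as reverse complements. Overlapping reading frames are
handled by pinning all start/stop codons first and then sampling
internal codons conditional on pinned bases, restricted to sense
codons; with the vertebrate gene order all overlaps (ATP8/ATP6,
ND4L/ND4, ND5/ND6, ATP6–COX3) are satisfiable, and an infeasible
template raises a generation error rather than emitting a broken ORF.

Base probabilities: PCG codons and intergenic spacers are sampled from
the genome-wide probabilities (A .314, T .251, C .274, G .161); the
control region (A+T target 0.661), rRNAs and tRNAs use their own
region-specific probabilities mirroring published per-region values.
RNA-gene and control regions are sampled i.i.d. on the heavy strand
(orientation is immaterial for an i.i.d. model; only PCGs, where the
reading frame matters, are built strand-aware). Because the sampled
regions target the *per-region* published compositions, the realized
genome-wide mixture is the size-weighted combination of those targets —
which for the published table differs from its own printed genome-wide
row by about one percentage point; the published per-region and
genome-wide rows are not exactly consistent with each other, and the
generator follows the per-region values.

`evolve_family()` evolves a codon sequence along a guide tree: an
HKY-style proposal kernel (transition/transversion ratio `kappa`,
default 2), stop-codon proposals rejected, synonymous changes always
accepted, nonsynonymous changes accepted with relative rate `omega`.
Branch lengths are expected accepted substitutions per codon site, so
zero-length branches reproduce the parent exactly.
`simulate_clade_dataset()` combines both: a star-of-clades guide tree
with within-clade branches (default 0.02) much shorter than
between-clade branches (default 0.15), values chosen to emulate
congeneric/confamilial fish mitogenome divergence, with `omega = 0.1`
for the strong purifying selection universally reported for
mitochondrial PCGs.

What the generator does *not* emulate: real tRNA secondary structure,
conserved control-region blocks (ETAS/CSB), indels, rate variation
across sites, and compositional strand asymmetry arising from
replication mechanics (regions are i.i.d. given their probabilities).
Passing tests on synthetic data therefore validate the *computations*,
not the biological realism of any particular accession.

## Numerical and calibration choices

* Skews from counts; report-time rounding only; comparisons against
  3-decimal published skews tolerate the published tables' own 1-decimal
  percentage rounding.
* The neutral-limit calibration of the Ka/Ks estimator runs the
  simulator at `omega = 1` with `kappa = 1`, because NG86 assumes an
  equal-rate mutation process; this is the model-matched check of the
  estimator, while realistic `kappa = 2` is used everywhere else.
  At interspecific divergence (Ks ~ 0.4–0.6, star families of 5–7 taxa,
  200–400 codons) the purifying regime `omega = 0.1` is recovered as
  mean Ka/Ks well below 1 for every simulated gene.
* Desk-scale problem sizes throughout the tests and the acceptance
  script — families of 200–400 codons, 4–7 taxa, 6-taxon clade
  datasets — are the package's chosen trade-off between statistical
  resolution and a suite that runs in about a minute.
* The hairpin search maximizes stem length with ties broken by smaller
  loop then leftmost position, and requires exact Watson–Crick arm
  complementarity with loops of at least 3 nt; it agrees with an
  exhaustive enumeration oracle on short windows.

## Worked example

```{r example, eval = FALSE}
rec <- simulate_mitogenome(seed = 1)
summarize_structure(rec)
head(region_compositions(rec)[, c("region", "size", "AT_pct", "AT_skew", "GC_skew")])
counts <- count_codons(extract_cds(rec))
attr(amino_acid_usage(counts), "total")   # 3794 amino acids

recs <- simulate_clade_dataset(6, 3, seed = 7)
tree <- neighbor_joining(jc_distance_matrix(concatenate_pcgs(recs)))
plot(tree)
```

## Known limitations

* Origin-wrapping features are rejected rather than handled.
* The GenBank reader covers the common single-record flat-file subset
  (simple and `complement()` spans, `/gene` / `/product` qualifiers),
  not joins across the origin or multi-record files.
* Ka/Ks is counting-based (NG86); maximum-likelihood omega estimation
  and site/branch models are out of scope.
* Composition comparisons against published percentage tables inherit
  those tables' internal rounding inconsistencies; exact parity with a
  specific accession requires its sequence.
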