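---
title: "Methods: rumen virome analysis with rumenvirome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rumen virome analysis with rumenvirome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumenvirome)
```

## Scope and model

`rumenvirome` implements the analytical core of a rumen virome survey
*downstream* of raw viral detection. Assembly, viral identification,
completeness estimation, gene-sharing clustering and functional
annotation are upstream tools whose outputs (FASTA, BLAST tabular hit
tables, GFF-like gene tables with controlled-vocabulary labels,
completeness calls) this package consumes. What it computes itself:

1. **Species-level vOTU clustering.** Viral contigs above the 5 kb
   admission floor (strict `> 5000` bp; shorter contigs carry too high a
   false-positive risk in viral detection) are clustered at **95% average
   nucleotide identity (ANI) over 85% aligned fraction of the shorter
   contig of each pair**. ANI is the alignment-length-weighted mean
   identity over the retained local-alignment blocks; the aligned
   fraction uses the *union* of block intervals, so overlapping blocks
   never inflate it. Clustering is greedy and centroid-based: contigs are
   processed longest-first (ties by completeness, then id) and join the
   first *centroid* they match — membership is never tested against
   non-centroid members. This mirrors the behaviour of the standard
   ANI-clustering script used for viral species delineation and makes
   the partition a deterministic function of the input set.

2. **Taxonomy rules.** Family assignment uses the protein-majority rule:
   hits below bitscore 50 are discarded (50 itself qualifies), each
   protein votes with its single best hit (score ties across families
   abstain), and a family is called only when strictly more than 50% of
   *all* proteins of the vOTU vote for it. crAss-like vOTUs are flagged
   when blocks of at least 80% identity cover at least 50% of a
   crAss-like *reference* (coverage is measured on the reference, not the
   query). A vOTU is lysogenic iff it derives from an excised prophage or
   encodes an integrase. For marker-gene phylogeny input, concatemers
   must show strictly more than 3 markers and markers must occur in
   strictly more than 5% of concatemers; the two row/column filters
   interact, so they are iterated to a fixed point (the order of the two
   prints is ambiguous in common protocol descriptions; fixed-point
   iteration makes the result order-independent, which we consider the
   defensible reading).

3. **Two-channel host linkage.** A prophage-based link requires blocks
   with identity strictly above 90%, at least one block strictly longer
   than 2,500 bp, and at least 75% of the vOTU covered by the union of
   qualifying block intervals. These three thresholds are stated jointly
   in the field's host-prediction protocols; we bind each to its natural
   object (per-block identity, single-block length, union coverage) and
   treat the coverage bound as inclusive. A CRISPR-spacer link requires a
   literal full-length match of the spacer in the vOTU on either strand —
   100% identity, 100% coverage, ambiguity codes never match. Host-range
   roll-ups flag multi-species (≥2 host species) and cross-phylum (≥2
   phyla) vOTUs; per-genus statistics report distinct linked vOTUs,
   phages per genome (distinct vOTUs / genomes in the genus) and the
   lysogeny rate among linked vOTUs.

4. **AMG/ARG curation.** Auxiliary metabolic gene (AMG) screening is
   restricted to *complete* viral genomes strictly longer than 10 kb;
   candidates at the first or last gene of a contig are dropped, flanks
   must be hallmark+viral-like (either order) or hallmark+hallmark, and
   only annotation-confidence categories 1–2 qualify. Contigs are then
   excluded as probable genomic islands when their viral genes are only
   integrases/transposases/tail fibers, when none of the eight structural
   gene classes (capsid, portal, coat, baseplate, head, tail, virion
   structural, terminase) is present, or when any island-marker gene
   (endonuclease, plasmid-stability protein, LPS biosynthesis, GT11/GT25
   glycosyltransferases, nucleotidyltransferase, carbohydrate kinase,
   nucleotide-sugar epimerase) occurs. The literal phrasing "or any
   nonviral genes" cannot be meant verbatim (every AMG is nonviral); we
   read it as "no viral gene other than mobile elements", which is the
   only reading under which AMG-carrying genomes can survive at all.
   Antimicrobial resistance genes (ARGs) require 80% identity and 40%
   reference coverage (both inclusive); end-of-contig calls survive only
   with a viral inward neighbour. Representative ARG contigs maximize
   completeness, then minimize cellular gene count, then take the
   smallest id. Every drop decision carries exactly one machine-readable
   reason code.

5. **Virome ecology.** Read alignments must reach 95% identity and 75%
   aligned read fraction. Abundance is the **trimmed mean**: zero if
   fewer than 70% of positions are covered, otherwise the mean after
   removing `floor(0.05·L)` positions from each sorted extreme — a
   positional reading of "top/bottom 5% of regions" that matches the
   cited coverage tool. Richness is detections per Gbp. The core virome
   is defined per sample group (dietary concentrate level): a vOTU is
   core when its within-group prevalence exceeds 50%. The two phrasings
   in circulation ("exceeded 50%" vs "at least 50%") disagree on the
   boundary; strict `>` is the default and an inclusive switch is
   provided, with the rule echoed in the output metadata. Prevalence
   classes are individualized (exactly one sample), or one/two/three
   concentrate levels. Study-level structure uses shared-vOTU counts
   between studies with strictly more than 12 samples, clustered with
   average linkage on `1 − shared(a,b)/min(richness_a, richness_b)`;
   no particular transform or linkage is canonical for this analysis, so
   the choice is explicit and configurable.

## The synthetic community generator

Real inputs at survey scale (hundreds of metagenomes, tens of TB) are
out of reach for routine testing, so every stage is exercised on seeded
synthetic communities with planted ground truth:

- **Viral genomes** of 5–200 kb (the size range of the real admission
  window) with uniform base composition at GC 0.5; host genomes are
  MAG-scale fragments (80–200 kb by default — real MAGs are larger, but
  host length is immaterial to every rule under test).
- **Mutations are substitution-only** (exactly `floor(d·L)` positions,
  drawn without replacement). Planted identity therefore equals
  `1 − divergence` exactly, and the generator can emit the *ideal*
  alignment block of every planted prophage analytically. This is a
  deliberate design: the host-link rule is testable without an aligner
  in the loop. The built-in seed-and-extend aligner (`local_align`) is
  validated separately against global-alignment identity on ≤5 kb pairs.
- **Planted prophages** at 3% divergence must be recovered (identity 97%
  ≫ 90%); decoys at 15% divergence (identity ≈85%) and 2 kb fragments
  (below both the 2,500 bp block rule and the 75% coverage rule) must
  not. **CRISPR arrays** carry exact protospacer copies of a source
  virus (forward or reverse-complement, recorded); one spacer per
  community is corrupted by a single substitution and must produce no
  link.
- **Clustering variants**: full-length copies at 2% divergence
  (co-cluster), at 10% (fail the 95% ANI bar) and 60%-length fragments
  (fail the 85% aligned-fraction bar).
- **Gene tables** plant one AMG/ARG configuration per rule branch
  (retained, end-of-contig, bad flank, bad category, island marker,
  missing structural gene, mobile-only) and integrase carriers for
  lysogeny.
- **Prevalence matrices** follow the study design of the core-virome
  analysis: three dietary-concentrate groups with 84/80/119 cattle.
  Background occurrence probability is 0.08 per group; three vOTUs are
  forced core (probability 1), two are group-restricted (0.9 in one
  group), one is forced individualized. The core-vOTU truth is computed
  from the *realized* binary matrix under the strict rule, so recovery
  is exact by definition of the rule, not approximately.
- Sample metadata assigns four round-robin "studies" and two breeds so
  the sharing and clustering analyses have structure to find.

What the generator does **not** emulate: read-level noise, assembly
artifacts, chimeras, indel divergence, uneven GC, real taxonomic
signal in sequence composition. Passing tests therefore demonstrate the
correctness of the decision rules and their boundary behaviour, not
robustness to upstream noise — by design, since the upstream tools are
out of scope.

All randomness flows from a single integer seed; identical
configurations produce byte-identical output files, which the pipeline
manifest verifies with md5 checksums (used purely as file fingerprints
for cache invalidation and determinism checks).

## Numerical and boundary conventions

- Coordinates are 0-based half-open internally; BLAST tabular and the
  GFF-like gene tables are 1-based inclusive at the boundary, and
  minus-strand subject blocks (`sstart > send`) are normalized before
  interval unions.
- All stated thresholds keep their printed strictness: `>5 kb`
  admission, `>90%` identity, `>2,500` bp, `≥75%` coverage, `≥50`
  bitscore, `>50%` majority, `≥80%/≥50%` crAss rule, `>3` markers,
  `>5%` marker prevalence, `>10 kb` vMAGs, `≥80/≥40` ARG thresholds,
  `≥95%/≥0.75` read filters, `<0.70` coverage gate, `>50%` core rule
  (switchable), `>12` samples per study.
- Representative selection ranks length before completeness (the field's
  phrasing "longest and most complete" lists length first; the converse
  ordering differs only when a shorter contig is more complete, and the
  choice is isolated in `select_representative`).
- Ties everywhere fall back to lexicographic id order, making every
  output order-independent and reproducible.
- The CRISPR array finder determines repeat boundaries by minimum
  agreement across all repeat-copy pairs. When the flanking base of
  *every* spacer in an array coincides by chance (probability
  `4^-(n-1)` per side for `n` repeat pairs), the repeat boundary shifts
  by one and spacers are trimmed accordingly — the same boundary
  ambiguity real array finders exhibit. Trimmed spacers remain exact
  substrings of the protospacer source, so linkage is unaffected; tests
  tolerate ±2 bp at spacer boundaries.

## Problem sizes

Unit and acceptance tests run on deliberately small instances: clustering
oracles on ≤8 contigs × 1,000 random instances, host-link recovery on
100 communities of 8 viruses (5–15 kb) × 4 hosts, core-virome recovery
on 15-sample matrices, and the end-to-end determinism check on the same
reduced community. The default configuration (24 viruses of 5–200 kb,
8 hosts, 283 samples) is used for single pipeline runs. These sizes were
chosen to make the full suite complete in about a minute while keeping
every decision rule exercised on both sides of its boundary.

## Known limitations

- The greedy centroid clustering is the contract implemented and tested;
  other published vOTU clusterings (e.g. single-linkage at the same
  thresholds) give different partitions on chained similarity.
- Genus-level taxonomy is consumed from an external gene-sharing table,
  never computed.
- The built-in aligner is a gapless seed-and-extend stand-in suitable
  for the substitution-only synthetic data; real data should bring
  BLAST-tabular hits from a production aligner.
- Statistical testing around the ecology outputs (Wilcoxon,
  Kruskal–Wallis, PERMANOVA) is intentionally left to standard packages;
  the module emits tidy tables they consume directly.
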