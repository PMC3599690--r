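---
title: "Mining bacterial cytochrome P450 complements: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining bacterial cytochrome P450 complements: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypminer)
```

## The problem

Bacterial cytochromes P450 (CYPs) are heme-thiolate monooxygenases.
Streptomycetes typically carry dozens of them, wired into secondary
metabolism and xenobiotic degradation, often next to the ferredoxins and
ferredoxin reductases that supply their electrons and to the regulators
that control them. Given an annotated proteome and gene-coordinate table,
cypminer answers four questions:

1. which proteins look like CYPs, judged by the three classic sequence
   signatures;
2. which named CYP family and subfamily each candidate belongs to, judged
   by pairwise amino-acid identity against a labeled reference panel;
3. how the candidates relate to each other (a neighbor-joining paralog
   tree);
4. which candidates sit next to electron-transfer partners, ATP/GTP-binding
   proteins, transcriptional regulators or other functional genes, and what
   their per-gene properties are (G+C content, length, molecular weight,
   isoelectric point).

## Motif model

Three signatures identify most CYPs:

* **Heme pocket** — the cysteine that ligates the heme iron, in a
  `G-x-x-x-C-x-G` context. This is the only signature present in every
  known CYP region we model, so the candidacy rule requires it. Documented
  exceptions exist: the relaxed form accepts any cysteine with a glycine
  within four residues on at least one side. That radius was chosen as the
  smallest that covers the published exception strings (e.g. `...GHRCPG`,
  `...RLCCG`) while staying local to the pocket.
* **K-helix** — the `E-x-x-R` salt bridge. CYP157-family proteins replace
  the arginine (`EVLW`, `EQILW`); the relaxed form is `E-x(2,3)-W`, which
  covers exactly those two published shapes.
* **I-helix** — the oxygen-activation window. The classic consensus
  `GXXTT` is too strict for real streptomycete CYPs, so the scanner uses
  the residue-class window `[AGFT]-x-x-[TSAIP]-[TV]`, generalized from the
  observed variant windows (`GHETT`, `FAPTT`, `GVIST`, `GHQPT`, ...). A hit
  is *canonical* only when position 4 is the conserved threonine; all other
  matches are reported but flagged atypical, preserving the "conserved Thr"
  claim as a report rather than a filter.

Scanning conventions: 1-based inclusive spans; overlapping matches resolved
leftmost-first (a deterministic choice — published motif tables print one
motif per protein without stating a tie-break); the ambiguity code `X`
matches wildcard positions but never a conserved position. The K-helix is
searched between the best I-helix hit and the best heme hit when both
exist, enforcing the structural order the three motifs always show; when
that window has no hit the kind is reported missing rather than rescued
from elsewhere in the sequence.

**Candidacy rule.** A protein is called a CYP candidate when it has a heme
hit plus at least one I- or K-helix hit. In `strict` mode (the default)
only canonical hits count; `relaxed` mode admits the exception forms and
annotates each with a note. Strict mode is the right default for discovery
on noisy annotations — a lone relaxed heme hit is common in random
sequence — while relaxed mode reproduces published exception calls when
you already trust the candidate list.

## Family classification

CYP nomenclature assigns two sequences to one family above 40% amino-acid
identity and one subfamily above 55%, with strict "more than" semantics
(40.0% exactly is *not* the same family). Identity is computed from an
affine-gap Needleman–Wunsch global alignment (BLOSUM62, gap open 10,
extend 0.5 — community defaults, configurable) as identical columns over
all columns after trimming terminal-gap columns. The trimming approximates
the local-overlap identities that database searches report without
implementing seeded local alignment; for same-length proteins it coincides
with plain global identity. A best hit to an *unlabeled* reference yields
a `new_family` verdict with a cross-reference note regardless of identity:
a family name cannot be inherited from an unnamed sequence. Field practice
occasionally overrides thresholds by tree position; that judgment call is
deliberately not automated.

## Phylogeny

Distances are `1 - identity` on the same alignments; neighbor joining is
the standard Saitou–Nei recursion, re-implemented rather than wrapped so
its tie-breaking is fully specified: equal-Q pairs are resolved by the
lexicographically smallest pair of cluster labels, making the tree
invariant to input order. Negative branch lengths are clamped to zero with
a warning (the usual practical convention). Output is an unrooted
`ape::phylo` tree with a trifurcating root; the Newick writer emits
6-decimal branch lengths and quotes labels containing metacharacters. On
additive matrices the implementation reconstructs path lengths to below
1e-9 (property-tested against random trees, and cross-checked
topologically against an independent NJ implementation).

## Gene-neighborhood context

Published neighborhood reports are qualitative ("adjacent to", "lies next
to"), so adjacency is measured in gene ranks, not base pairs, with a
default window of 2 genes per side. Strand is recorded (`same_strand`)
but never required to match, and operon inference is not attempted — the
reports are co-localization only. The census assigns each clustered CYP an
exclusive type: `ferredoxin_plus_reductase`, `ferredoxin_only`, `atp_gtp`,
`regulator`, or `mixed`; type counts therefore sum to the number of
clustered CYPs.

## Sequence properties

* G+C content: `100 (G+C) / (A+C+G+T)`, `N` excluded from both terms;
  full precision kept, integer rounding applied only at reporting.
* Molecular weight: average (not monoisotopic) residue masses plus one
  water, matching the kDa style of standard proteomics tools.
* Isoelectric point: Henderson–Hasselbalch net charge over the termini and
  the D/E/C/Y/H/K/R side chains with the Bjellqvist pKa set, including
  residue-specific N-terminal (and D/E C-terminal) values — the convention
  behind the ExPASy Compute pI/MW tool — solved by bisection on pH 0–14.
  The iteration stops only when the interval is below 1e-4 pH units *and*
  the residual charge is below 1e-3: for long chains the charge slope is
  steep enough that a width criterion alone leaves a visible residual.
  Both computations are verified against an independent implementation of
  the same conventions (Biopython's ProtParam) on fixed peptides.

## The synthetic-data generator

Real CYPome censuses cannot be re-derived at desk scale (they depend on
unpublished genomes and live databases), so validation rests on generated
data with exact ground truth. The generator emulates:

* **a proteome** of 400-residue proteins (typical P450 length) in which a
  known subset carries implanted motifs at realistic relative positions —
  I-helix near 55% of the chain, K-helix near 68%, heme pocket in the
  C-terminal third, with small jitter;
* **families at controlled identity**: 13 named families plus one
  new-family singleton, member counts 5, 11, 1, 1, 1, 1, 1, 2, 1, 3, 4, 1,
  1 (a realistic streptomycete CYPome census of 33), members at 0.60
  identity to their family seed, family seeds at ~0.48 identity to one
  common ancestor so that seeds sit near 0.25 identity to each other —
  comfortably inside `new_family` territory across families and
  `same_subfamily` within;
* **exception profiles**: one singleton lacks the I-helix and another the
  K-helix (emulating published "Unidentified" cells) while keeping the
  heme pocket plus one partner motif, so all 33 synthetic CYPs satisfy the
  candidacy rule;
* **a 300-gene single-contig layout** with planned neighborhoods — 3
  ferredoxin-only, 1 ferredoxin-plus-reductase, 3 ATP/GTP, 4 regulator
  (LysR/LuxR/AraC/TetR), 1 mixed and 4 other-functional clusters, plus
  standalone partners bringing totals to 7 ferredoxins and 3 reductases —
  separated by filler genes, fixed 50 bp intergenic gaps (neighborhood
  logic is rank-based, so spacing only needs to be valid), mixed strands,
  and contig DNA at ~70% G+C.

Background residues are uniform over the 20 amino acids with two rejection
rules that make ground truth exact: no accidental canonical heme pocket
anywhere (so strict-mode scans have zero false positives by construction),
and, within motif-carrying proteins, no accidental canonical I/K window
away from its implant (so implant positions are exactly the best hits).
The mutation engine uses uniform substitutions at uniformly chosen
unprotected sites, with the substitution count tuned in a short search
until the *measured* alignment identity lands within 0.02 of target; no
biological realism is claimed for the substitution process. Everything is
a pure function of one RNG seed — identical specifications write
byte-identical files.

What passing these tests does **not** show about real data: real CYPs are
not mutually alignable at a single controlled identity, real neighborhoods
have variable spacing and operonic structure, real annotations mislabel
partners, and real proteomes contain relaxed-form motif noise that the
strict default deliberately ignores. The synthetic suite validates the
machinery, not the biology.

## Numerical choices and degenerate inputs

* Identity undefined (no aligned residue columns) raises an error naming
  the pair; empty sequences cannot be aligned.
* Distance matrices must be symmetric, finite, zero-diagonal; NJ requires
  at least 3 taxa and emits a trifurcating root at exactly 3.
* `gc_content` of an empty or all-`N` sequence is an error, not 0.
* A pI search that never crosses zero in pH 0–14 returns the boundary
  with a warning.
* Thresholds must satisfy `0 < family < subfamily < 1`; reversed
  thresholds are rejected before any pipeline stage runs.
* Problem sizes used by the validation suites — a 300-gene genome with 33
  CYPs over 10 seeds for end-to-end recovery, 1000 random sequences for
  scanner/oracle equivalence, alignment enumeration up to length 8, NJ
  additive recovery up to 12 taxa — were chosen as the smallest sizes that
  exercise every code path at the census scale the generator models.

## Worked example

```{r example, eval = FALSE}
lay <- generate_genome_layout(synthetic_spec(rng_seed = 1))
res <- run_pipeline(pipeline_config(
  proteins = lay$proteins, genes = lay$genes, genome = lay$contig,
  panel = lay$panel, seed = 1))
length(res$candidates)   # 33
res$census$counts        # 3 ferredoxin_only, 1 ferredoxin_plus_reductase,
                         # 3 atp_gtp, 4 regulator, 1 mixed
head(res$assignments)
```

## Known limitations

* No HMM/profile detection; purely pattern-based scanning will miss CYPs
  whose heme region diverges beyond the relaxed rule.
* No BLAST-style seeding or E-values: classification is exhaustive global
  alignment against the user-supplied panel, which is exact but scales
  linearly in panel size.
* No multiple alignment; the paralog tree uses pairwise identity
  distances, which are not additive for real protein families.
* No operon model; gene-rank co-localization over- and under-calls true
  transcriptional units.
* Nomenclature-committee naming is out of scope: `new_family` means "no
  panel reference above 40%", nothing more.
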