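---
title: "Cataloging RING finger domains: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cataloging RING finger domains: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RINGcat)
```

## The biological model

RING domains are Cys-rich zinc-binding domains of roughly 40--60 residues
whose eight metal ligands (ml1--ml8, normally Cys or His) chelate two
Zn²⁺ ions in a cross-brace arrangement: ligand pairs ml1--ml2 and
ml5--ml6 bind one zinc, ml3--ml4 and ml7--ml8 the other. The cross-brace
geometry constrains the short gaps (ml1--ml2, ml3--ml4, ml4--ml5,
ml5--ml6, ml7--ml8) tightly, while the two long loops (ml2--ml3 and
ml6--ml7) tolerate wide length variation. RINGcat encodes the eight
plant RING types on this backbone:

* **RING-H2** -- His at ml4 *and* ml5;
* **RING-HCa / RING-HCb** -- His at ml4, Cys at ml5, split by the
  ml7--ml8 gap (2 versus 3--4);
* **RING-v** -- Cys at ml4, His at ml5, with the diagnostic 1-residue
  ml3--ml4 and 7-residue ml4--ml5 spacing;
* **RING-C2** -- all-Cys ligands;
* **RING-D / RING-S/T / RING-G** -- Asp at ml5/ml6, Ser/Thr at ml2/ml6,
  or Gly at ml5 substituting the Cys-His-Cys pattern.

`ringTypeSpecs()` is the machine-readable form of this taxonomy; it can
be serialized with `writeTypeSpecs()` so users can add types observed in
other lineages.

## Classification: residues first, spacing second

`classifyChain()` decides the type from the residue signature alone and
consults spacing only to split RING-HCa from RING-HCb. The long-loop
windows recorded in the specs are *observed ranges over surveyed
domains*, not definitions, so a chain with an HC signature and an
ml2--ml3 gap of 50 is still RING-HCa -- with a `gapWarning` attribute,
never a rejection. RING-D, RING-S/T and RING-G take precedence over the
plain HC reading whenever their distinguishing residue is present,
because they are defined as substitutions of that pattern.

A chain with the C4HC3 signature can also be a PHD finger.
`isPhdLike()` separates the two purely by spacing: PHD fingers show 2--4
residues between ml3--ml4 and 4--5 between ml4--ml5, RING-v exactly 1
and 7. The two gap regions are disjoint, so no chain satisfies both
readings; PHD-like chains are excluded from the catalog and also mask
the relaxed searches (a PHD finger must not resurface as a "modified
RING").

## Scanning

`findLigandChains()` enumerates, exhaustively and deterministically,
every eight-position chain whose residues lie in the union slot
alphabets and whose gaps lie in the union windows
(`scanWindows()`: ml2--ml3 in 8--77, ml6--ml7 in 4--64, short gaps as
tabulated). `scanProtein()` then layers three searches:

1. canonical chains, classified and PHD-filtered;
2. a one-slot-relaxed search (each slot in turn allowed to be any
   residue *except* its canonical set) emitting **modified** domains --
   chains with exactly one substituted ligand;
3. a two-slot-relaxed search emitting **incomplete** domains (at least
   6 of 8 ligands with consistent spacing). The 6-of-8 floor is this
   package's choice: "two or more ligands missing" has no published
   lower bound, and 6/8 keeps false positives manageable.

Overlaps are resolved deterministically: fewer substituted ligands
first, then type priority in canonical abundance order
(H2 > HCa > HCb > v > C2 > D > S/T > G), then -- among competing
single-substitution readings of the same type -- the interpretation
whose long-loop spacing is most typical for that type, then smaller
span, then leftmost start. The typicality rank reflects the survey
observation that domains of one type share preferred loop lengths
(e.g. RING-H2 prefers 14--15 residues between ml2--ml3 and 10--11
between ml6--ml7); it is implemented as a modal-versus-tail
log-probability over the type window and is what lets the scanner pick
the right frame for most modified domains whose substituted ligand sits
at the chain terminus (see *Limitations*).

Coordinates are 1-based inclusive everywhere inside the package and in
the catalog TSV (the protein-coordinate convention); BED export
converts to 0-based half-open. The ambiguity letter `X` never matches a
ligand slot.

## Modified-domain tie-breaks

`classifyModified()` finds the specs matching a chain at seven of eight
slots (a spec with an "at least one of" requirement -- RING-D's Asp,
RING-S/T's Ser/Thr -- can only claim a chain if the requirement is
satisfiable by the non-substituted slots). Candidates whose
structure-fixing gaps fall inside the type windows are preferred; if
several types still tie, the most frequent type wins and the result is
flagged ambiguous. The frequency-order proxy replaces the orthology and
tree placement used in manual surveys, which a self-contained tool
cannot consult; the ambiguity flag preserves auditability.

## Spacing statistics and frequency matrices

`typeCensus()` counts complete classified domains (modified domains
under their assigned type, incomplete excluded); `gapHistograms()` and
`spacingConsensus()` are the machine forms of per-type spacing tables.
`anchoredFrequencyMatrix()` builds the numerical equivalent of a
sequence logo: columns anchored on each ligand with a fixed flank
(default 3) on each side, frequencies over *observed* residues per
column and the observation count kept as coverage -- variable loops
contribute only their ligand-adjacent columns, so coverage varies by
design. `overRepresentedResidues()` reports single residues, or the
conservative equivalence pairs F/Y, I/V, E/D, K/G, S/T, A/V, whose
combined frequency crosses a threshold.

`architectureGroups()` groups proteins by the N→C tuple of additional
(non-RING) domain names from a user-supplied annotation table.
Consecutive repeats collapse to one key element by default, so
"one or more trans-membrane segments" is a single group, with the copy
number retained per protein.

## Ligand-anchored alignment

`anchorAlign()` fixes the eight ligand residues of every domain in eight
shared columns and fills each inter-ligand block independently with
`loopSubalign()`. The default `pad-right` mode simply pads each loop to
the block maximum: it is deterministic, keeps the width law
(width = 8 + sum of maximal gaps) and guarantees that removing gap
characters reproduces each input sequence. Manual curation with an
external aligner, as used in published surveys, is deliberately not
emulated; users wanting residue-level loop homology can select
`center-star`, which picks the loop with maximal summed pairwise
identity (global alignment, match 1 / mismatch 0 / gap −1, ties to the
first and to diagonal moves) as the center and merges the pairwise
alignments -- at the cost that insertions into the center can widen a
block beyond the longest loop. Tree building is out of scope; the
aligned FASTA plus anchor-column sidecar is the hand-off to standard
phylogenetics software.

## Expression clustering

Profiles are clustered exactly as in the original survey's pipeline:
uncentered Pearson distance
\(d = 1 - \sum x_i y_i / \sqrt{\sum x_i^2 \sum y_i^2}\)
(for non-negative FPKM profiles \(d \in [0,1]\)) under complete
linkage, via `stats::hclust`. FPKM values are clustered raw by default
-- whether the original analysis log-transformed is unstated, so the
weakest assumption is the default and `log2 = TRUE` is a flag.
All-zero genes are removed first (`filterAllZero()`): their profile
direction is undefined.

`cutTreeGroups()` labels the k groups with Roman numerals in dendrogram
leaf order; the labels are descriptive, not algorithmic. Subgroup
delimitation in the original survey was manual; here an optional deeper
cut (`k2`) assigns letters within groups.

A tissue is *preferential* when its signal exceeds `fold` (default 2)
times the **mean of the other tissues**. Mean-of-rest is the weakest
reading of ">2-fold higher" that is consistent with whole groups being
preferential in one tissue; `baseline = "max"` is the stricter option.
The inequality is strict, and a tissue with positive signal while all
others are zero is always preferential.

## The synthetic generator

`plantProteome()` emulates the statistical structure the analysis
assumes, with defaults matching the surveyed census: type mix
371:215:47:44:38:10:5:1, ~2.6% modified (one substituted ligand),
~1.5% incomplete (two substituted ligands), a small PHD-decoy fraction,
10% domain-free proteins, and a 16/715 chance of a second domain per
canonical protein. Gap sampling puts 80% of its mass on the modal
values per type (e.g. RING-H2 ml2--ml3 ∈ {14,15}) with a uniform tail
over the type window; conserved flank motifs (Phe/Tyr before ml5 in
RING-H2 at 0.85, Ile/Val before ml2, Ala/Val before ml5 in RING-v) are
planted at their observed rates. Loops and flanks are drawn from the 14
residues that occur in no ligand alphabet ("clean background"), so the
planted truth is the unique interpretation and recovery can be asserted
exactly; `hardMode = TRUE` restores the full alphabet outside planted
domains, and recovery should then be evaluated by overlap. What the
generator does *not* emulate: homologous sequence similarity between
domains, compositional bias of real proteomes, and ligand letters in
real loops -- passing recovery tests therefore demonstrates the
scanner's correctness, not its false-positive rate on real proteomes.

`simulateExpression()` plants seven groups (proportions matching the
surveyed group sizes) with one preferential tissue each -- two for the
small mixed group -- at fold 10 over baseline FPKM 5 under
multiplicative log-normal noise (sd 0.2 on the log scale by default),
plus a configurable fraction of all-zero rows. With at most three high
tissues per pattern, the mean-of-rest rule recovers every planted
tissue exactly at zero noise.

## Numerical choices and problem sizes

Seeds are mandatory in both generator configs; the same seed gives
byte-identical output. Frequency-matrix columns must sum to 1 within
1e-9. Agglomeration ties follow `stats::hclust`; distances are clipped
at 0 to absorb floating-point negatives. The test suite exercises the
scanner against a brute-force cross-join enumerator on 200 random
sequences of up to 200 residues, recovery on 1000-protein planted
proteomes (≥800 canonical domains), the classifier on the exhaustive
signature × decisive-gap grid (~41k chains), clustering against a cubic
complete-linkage oracle on 20 six-tissue profiles, and expression
recovery on 600 genes -- sizes chosen to give the invariants real
coverage while keeping a full run in minutes.

## Limitations

* **Terminal modified ligands are locally aliased.** A domain whose ml1
  or ml8 is substituted always admits a second, equally valid
  single-substitution reading that shifts the frame by one slot and
  changes a long-loop gap by exactly 3. Both readings use the same
  seven canonical ligands; sequence information alone cannot decide.
  The spacing-typicality rank resolves the alias whenever the true
  long-loop gap is modal for its type; when it falls in the uniform
  tail, the smaller-span reading wins and the reported
  `modified_position` is off by one with coordinates off by three.
  Published surveys resolved such cases with orthology and phylogeny,
  which are outside this package's scope by design.
* The incomplete-domain search reports *a* maximal-consistency
  interpretation of a degraded region; with two free slots several
  framings can tie, and only the overlap, not the exact frame, is
  guaranteed.
* Architecture grouping reproduces published group inventories only up
  to the annotation vocabulary supplied by the user; domain detection
  itself (SMART/InterPro) is an input, not a feature.
* The scanner is a pattern engine, not a homology detector: no HMM
  scores, no alignment pre-filter. On real proteomes it should be run
  on a candidate set (e.g. BLAST hits), as in the survey designs it
  follows.
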