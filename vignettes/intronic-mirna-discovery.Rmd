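---
title: "Discovering intronic microRNAs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering intronic microRNAs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronmiR)
```

`intronmiR` implements the computational arc of an intronic small-RNA study:
from a host gene's sequence and exon model to candidate precursor hairpins,
their microprocessor (Drosha/DGCR8) credentials, the mature 5p/3p duplex, a
cross-species guide-strand call, candidate target sites, clone-read
corroboration and 2^−ΔΔCt expression quantification. This vignette explains
the models behind each stage, the parameters that matter, the choices made
where the design was genuinely open, and what the synthetic-data tests do and
do not establish about real data.

## The folding model

Candidate precursors are stem-loops, so the folding engine searches only
*single-hairpin* structures: a chain of nested base pairs whose helices may
be interrupted by bulges and internal loops, with exactly one terminal loop
and no multibranch loops. This restriction matches the biology (every
microprocessor substrate is a simple stem-loop), keeps the dynamic program
quadratic in practice, and — importantly for testing — makes exhaustive
enumeration of all legal structures tractable for short sequences, giving an
independent oracle for the optimizer.

The energy of a structure is

* a nearest-neighbor stacking term per adjacent pair of base pairs, from a
  6 × 6 table (AU, UA, CG, GC, GU, UG). Watson–Crick × Watson–Crick stacks
  carry rounded standard nearest-neighbor values (−0.9 to −3.4 model units);
  every stack involving a GU wobble carries a single uniform weak term of
  −1.0. The single-parameter wobble treatment is deliberate: GU stacks are
  marginal and strongly context-dependent, and a simplified model should not
  pretend to resolve that context. The −1.0 value reproduces the reported
  apical-loop geometry of the packaged precursor (the apical GUG sits on the
  terminal loop, and the wobble-rich basal helix still closes), and sits at
  the magnitude of an average wobble stack in standard tables;
* logarithmic loop penalties: hairpin `5.0 + 1.75·ln(l/3)`, bulge
  `3.8 + 1.75·ln(l)`, internal `4.0 + 1.75·ln((l1+l2)/2)` plus an asymmetry
  term `min(0.6·|l1−l2|, 3)`;
* a terminal penalty of 0.5 for an AU or GU outermost pair.

All parameters live in a versioned TSV
(`inst/extdata/energy_params.tsv`) read by `read_energy_model()`. Interior
loops longer than 20 nt per side are disallowed outright — a structural
cutoff, shared by the optimizer and the scoring function, that bounds the
inner loop of the dynamic program. The minimum hairpin loop is 3 nt (the
steric minimum). Energies are reported in *model units*: the −15 stability
threshold is interpreted on this scale, since absolute free energies from
different folding tools and parameter sets are not comparable unit-for-unit.
The threshold, not the absolute energy, is the decision the pipeline makes.

Ties are broken deterministically — more pairs first, then the outermost
pair with the smaller opening index, then the stacked continuation — so
`fold_hairpin()` is a pure function of sequence and model. The reported MFE
is never above 0 (the empty structure is always admissible).

`structure_energy()` scores an explicit pair chain with the same terms and is
the single source of energetic truth; the test suite's enumeration oracle
searches the structure space independently of the dynamic program and agrees
with it exactly on hundreds of short sequences.

## Candidate discovery

`scan_introns()` slides windows of 60–130 nt (step 10 in length, 5 in
position) over each intron, folds each window, and keeps those at or below
the energy threshold. The multi-length window scheme is an enumeration
device, not a model: the pipeline's substance is the filters. Each surviving
window is trimmed to its maximal paired span plus 5-nt flanks (removing
exterior unpaired bases provably leaves the optimal structure and its energy
unchanged, so stability is preserved), screened for motifs, and required to
present at least one motif class by default.

Overlapping survivors — inevitable with overlapping windows — are resolved
greedily: candidates are visited in order of ascending MFE (ties: more motif
classes, then leftmost) and retained only if they overlap every previously
retained candidate by at most 25% of the shorter. The ranking score
`−mfe/length + 0.5 · motif_classes` mirrors the two axes of the selection
(stability and processing motifs); both weights are configuration, not
fixed truth, because no published rule dictates how filter-passing hairpins
are ordered.

## Microprocessor rules

The four Drosha-enhancing motif classes are screened with pinned, documented
conventions (`drosha_config()`):

* **basal UG** — first base 10–16 nt (13 ± 3) *basal* of the 5p cleavage
  site. The motif is read on the basal side although one source phrase
  places it "downstream": microprocessor geometry (the UG sits at the
  basal ssRNA/dsRNA junction, below the cut) forces this reading.
* **CNNC** — first C at 16–18 nt downstream of the 3p cut. The window is
  calibrated: widening it to 15–18 admits a spurious match on the packaged
  precursor at offset 15. When fewer than 21 nt (the largest offset plus
  the 3 nt of the motif) remain downstream of the 3p cut, CNNC is reported
  *unevaluable* — neither present nor absent — and excluded from both the
  class count and the denominator of `processing_score()`. On the packaged
  103-nt precursor exactly 20 nt remain, so the score is 3 of 3 evaluable
  classes.
* **GHG** — G·H·G on the 3′ strand with an unpaired center, within 10 nt of
  the basal junction (the outermost base pair). The "mismatched" central
  nucleotide is what the structure model can actually verify.
* **apical UGU/GUG** — either triplet within the terminal loop ± 1 nt.

Cleavage placement (`place_cleavage()`) is anchored when a mature 5p
sequence is known (the cut falls immediately before its occurrence);
unanchored placement puts the cut so a basal UG lands in its window,
defaulting to 22 nt below the apical loop. The default mature length of
22 nt is the minimum of the mature-like clone length class (22–24 nt).
`extract_duplex()` derives the 3p product from the pairing partners of the
5p mature, extended by exactly 2 nt at the 3′ end — the staggered-cut
overhang — flagging (not erroring on) truncation at the precursor edge.

A note on the packaged fixtures: the printed mature 3p sequence disagrees
with the corresponding precursor arm at one internal position (G vs A). The
package stores both, reports the Hamming distance of 1 in its tests, and
does not decide which is authoritative.

## Conservation and the guide strand

`profile_alignment()` computes two independent per-column tracks: occupancy
(fraction of non-gap rows) and consensus (fraction of *non-gap* rows
carrying the modal residue). The non-gap denominator keeps the two tracks
orthogonal — consensus measures agreement among species that are present,
occupancy measures presence — and guarantees that adding a fully gapped row
lowers occupancy but never consensus. The guide strand is the arm whose
mean consensus strictly exceeds 0.5 while the other arm's does not;
anything else is ambiguous. Building the multiple alignment itself is out
of scope: the module consumes aligned FASTA from any aligner.

## Target sites and corroboration

`scan_sites()` applies the canonical seed-class definitions: the seed is
mature positions 2–8, and a site is an 8mer, 7mer-m8, 7mer-A1 or 6mer
according to whether the match extends to position 8 and whether an A faces
position 1. The class definitions replace an opaque machine-learned binding
score with something reproducible; `duplex_score()` adds a transparent
`base + supplementary·(1 − base)` score in [0, 1], where the supplementary
fraction counts complementary pairs opposite mature positions 13–16.
Promoter scanning uses the 600-nt TSS window from `extract_promoter()`;
intron scanning uses whole introns.

`corroborate_with_reads()` mirrors the read-based check used to shortlist
targets: local alignment (match +2, mismatch −1, gap open −2, extend −1 —
BLAST-like sensitivity at desk scale; all configurable) of each clone read
to each transcript, a hit requiring ≥ 80% identity over ≥ 20 aligned
columns, and intersection with the predicted set. The published experiment
does not state its alignment parameters, so these defaults are declared,
not inferred.

## Expression

`ddct_fold_change()` implements the Livak method. Technical replicates are
collapsed to mean Ct per sample first (qPCR reactions are typically run in
instrumental triplicate). Averaging happens on the log scale — the group
fold is `2^(−mean ΔΔCt)` — so the baseline group is exactly 1 by
construction, while the SEM is propagated on the linear scale from
per-sample folds, matching the mean ± SEM presentation convention. The
estimator's plate-shift invariance (adding a constant to every Ct of a
sample changes nothing) and its unbiasedness on the log scale are asserted
by simulation in the test suite. Efficiency correction (Pfaffl) and formal
group testing are out of scope; the paired western-blot normalization is the
one-line `densitometry_ratio()`.

## The synthetic-data generators

Every stage is exercised against generators that are pure functions of
`(specification, seed)`:

* `make_locus()` plants a perfect stem (optionally GU-wobbled) with known
  pairs, loop and motif positions into i.i.d. uniform background of
  configurable GC. The background deliberately has no Markov structure —
  real intronic sequence is more repetitive and more self-complementary, so
  false-candidate rates on real introns will be higher than on synthetic
  ones. Planted-recovery tests therefore establish sensitivity, not
  genome-scale specificity.
* `make_alignment()` controls per-column consensus exactly (a fixed count of
  rows carries the reference base; the rest draw from the other three),
  so planted block levels are recovered within ±0.05 at 20 rows.
* `make_reads()` emulates a 19-clone TA-sequencing mixture: 20% mature-class
  reads (22–24 nt; the mature extended with an untemplated 3′ tail when it
  is shorter than the drawn length), 40% mid-length fragments and the rest
  31–134 nt by-products drawn from supplied transcripts. The mid class is
  generated at 25–31 nt so the three classes are disjoint; the published
  length classes overlap (22–31 nt), which a label, not a generator, has to
  resolve.
* `make_ct_table()` plants log2 fold changes with Gaussian cycle noise and a
  flat reference gene, so ΔΔCt recovery is exact at zero noise.

The study conditions these defaults encode — 19 clones with 20%
mature-class, fold changes around 1.9–2.6 with 0.15-cycle noise at n = 4,
six-species alignments with 50–90% consensus on the conserved arm — are the
scales at which the test suite runs; problem sizes in the suite (e.g. 100
planted loci with 120–180-nt introns, 200 enumeration cases at ≤ 13 nt,
2-kb scan regions) were chosen to exercise those conditions thoroughly at
desk scale.

## Known limitations

* The energy model is intentionally simple: no terminal-mismatch or
  dangling-end terms, no special tetraloops, no temperature dependence, and
  a single GU stacking parameter. Absolute energies are not comparable to
  full thermodynamic folders; only the relative filter is meaningful.
* Single-hairpin folding cannot represent branched precursors or
  pseudoknots (both out of scope by design).
* The host-gene fixture's exon coordinates and background sequence are
  synthetic (marked so in the file); only the exon/intron counts, gene-scale
  dimensions and precursor placements are faithful to the reported gene.
  One source figure caption swaps the intron assignments of two precursors
  relative to the text; the package follows the text (miR1 and miR2 in
  intron 3, miR3 in intron 6).
* Guide-strand calling uses conservation only; read-count asymmetry, the
  other standard evidence, needs data the pipeline does not model.
* The duplex score is a transparent stand-in, not a trained affinity model;
  it orders site classes sensibly but its absolute values carry no binding
  semantics.
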