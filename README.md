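# intronmiR

Discovery and characterization of small RNAs encoded in the introns of a
protein-coding gene, packaged as a reusable, fully tested R pipeline.

Many microRNAs are *mirtrons* or intronic miRNAs: hairpin precursors hidden in
the introns of host genes and co-expressed with them. Finding one from sequence
alone takes a chain of classic computations, and `intronmiR` implements each
link with synthetic-data generators so every stage can be validated against
known truth:

1. **Hairpin candidate enumeration** — sliding windows over annotated introns,
   folded by a dynamic program restricted to single-hairpin (stem-loop)
   secondary structures under a simplified nearest-neighbor energy model.
   A candidate passes when its minimum free energy is at or below the
   stability threshold (default −15 model units): `fold_hairpin()`,
   `is_stable()`, `scan_introns()`.
2. **Microprocessor motif screening** — the four Drosha/DGCR8 consensus
   determinants: basal UG (13 ± 3 nt basal of the 5p cut), flanking CNNC
   (first C 16–18 nt downstream of the 3p cut), mismatched GHG near the basal
   junction, and apical UGU/GUG on the terminal loop: `scan_motifs()`,
   `processing_score()`.
3. **Mature duplex extraction** — rule-based Drosha cleavage with the 2-nt
   3′-overhang geometry, optionally anchored on a known mature sequence:
   `place_cleavage()`, `extract_duplex()`.
4. **Conservation profiling and guide-strand calling** — per-column occupancy
   and consensus of a cross-species alignment; the arm whose mean consensus
   exceeds 50% while the other's does not is called the guide:
   `profile_alignment()`, `call_guide_strand()`.
5. **Target-site scanning** — canonical seed-match classes (8mer, 7mer-m8,
   7mer-A1, 6mer) over 3′UTR/CDS/promoter/intron regions with a duplex score:
   `scan_sites()`, `duplex_score()`.
6. **Read corroboration** — Smith–Waterman local alignment of clone reads to
   candidate transcripts, intersected with the predicted target set:
   `corroborate_with_reads()`.
7. **Expression quantification** — the 2^−ΔΔCt (Livak) method with reference
   gene and baseline group: `ddct_fold_change()`.

All user-facing functions take and return tibbles where the data are tabular,
so stages chain with the pipe; folded structures and gene loci are light S3
objects with `tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

The package ships the three precursor hairpins reported for the mouse *Plaur*
(urokinase receptor / uPAR) gene as plain-text fixtures, together with the
printed mature sequences:

```r
library(intronmiR)

pre <- plaur_precursors()
pre$length
#> [1] 103  86 109

hp <- fold_hairpin(pre$sequence[1])   # Plaur-pre-miR1
hp
#> <hairpin_structure> 103 nt, 30 pairs, MFE = -22.67 model units
#> GGACUUGGGAUAAGUAGGCUUGGUGAUUGGCUGCCAGGUUCAGAGUGGAGUUCUCUGCAGGACCUGGCCGCCAACACGCCACUCUCUCCUCUUCCUAGGAGCC
#> ...(((((((..........(((((.(((((.(((((((((((((.......)))))...)))))))).)))))..)))))...........)))))))....

is_stable(hp)          # MFE <= -15 model units
#> [1] TRUE

cuts <- place_cleavage(hp, anchor_5p = plaur_mature()$sequence[1])
scan_motifs(hp, cuts)[, c("basal_ug", "ghg", "apical_motif",
                          "cnnc_status", "classes_present")]
#> # A tibble: 1 × 5
#>   basal_ug   ghg apical_motif cnnc_status classes_present
#>      <int> <int> <chr>        <chr>                 <int>
#> 1        6    99 GUG          unevaluable               3

extract_duplex(hp, cuts)
#> <mature_duplex>
#>   5p: UGGUGAUUGGCUGCCAGGUUC [21-41]
#>   3p: GCAGGACCUGGCCGCCAACACGCCACU [57-83]  3' overhang: 2 nt
```

The folded precursor is stable (−22.67 model units, well below the −15
filter), presents three of the four microprocessor motif classes — a basal UG
15 nt upstream of the 5p cut, a mismatched GHG at the basal junction and a
GUG on the apical loop, with the CNNC window unevaluable on the 103-nt
precursor — and the extracted 3p product protrudes the canonical 2 nt at its
3′ end. The packaged host-gene model (`plaur_locus()`, seven exons on the
minus strand) derives six introns with `derive_introns()`, and
`extract_promoter()` returns the 600-nt window upstream of the TSS used for
promoter-site scanning.

Synthetic inputs with known truth for every stage come from `make_locus()`,
`make_hairpin()`, `make_alignment()`, `make_reads()` and `make_ct_table()`.

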