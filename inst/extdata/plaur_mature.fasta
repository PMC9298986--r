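>Plaur-miR1-5p guide strand (conserved arm)
UGGUGAUUGGCUGCCAGGUUC
>Plaur-miR1-3p passenger strand (one internal mismatch vs the precursor arm)
AGAACCUGGCCGCCAACA
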