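>Plaur-pre-miR1 intron 3; printed genome interval 24,171,226-2,417,132 (end truncated in source)
GGACUUGGGAUAAGUAGGCUUGGUGAUUGGCUGCCAGGUUCAGAGUGGAGUUCUCUGCAG
GACCUGGCCGCCAACACGCCACUCUCUCCUCUUCCUAGGAGCC
>Plaur-pre-miR2 intron 3; genome interval 24,173,938-24,174,023
GUAGGUGGAUCUCUGGGUUUGAGGACAGCCUGGUCCAUACAGAGAGGCCCUGUCUGGGGG
GUGGGGAGGAGGCGGUGUCUACCUGC
>Plaur-pre-miR3 intron 6; genome interval 24,169,492-24,169,600
AAGAGGGGUGGGACAGACAGCGUGGCUGUGCUGGAAAUUCCUGUUUUGAUUUUUUUUCCC
CCAAGACAGGGUUUCUCUGUAUAGCCCCUGGCUGUCCUGGAACUCACUU
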