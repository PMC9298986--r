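##gff-version 3
##sequence-region PlaurLocus 1 16600
# Synthetic exon model of a Plaur-like host gene: seven exons / six introns on
# the minus strand, ~16 kb gene span, ~1 kb summed exon (mature mRNA) length.
# Coordinates are locus-relative (locus position 1 = genomic 24,160,001); the
# source study does not deposit real exon coordinates.
PlaurLocus	intronmiR	gene	281	16000	.	-	.	ID=gene:PlaurSynthetic;Name=PlaurSynthetic
PlaurLocus	intronmiR	mRNA	281	16000	.	-	.	ID=transcript:PlaurSynthetic.1;Parent=gene:PlaurSynthetic
PlaurLocus	intronmiR	exon	15881	16000	.	-	.	ID=exon:1;Parent=transcript:PlaurSynthetic.1
PlaurLocus	intronmiR	exon	14881	15000	.	-	.	ID=exon:2;Parent=transcript:PlaurSynthetic.1
PlaurLocus	intronmiR	exon	14151	14270	.	-	.	ID=exon:3;Parent=transcript:PlaurSynthetic.1
PlaurLocus	intronmiR	exon	10881	11000	.	-	.	ID=exon:4;Parent=transcript:PlaurSynthetic.1
PlaurLocus	intronmiR	exon	10151	10270	.	-	.	ID=exon:5;Parent=transcript:PlaurSynthetic.1
PlaurLocus	intronmiR	exon	9751	9870	.	-	.	ID=exon:6;Parent=transcript:PlaurSynthetic.1
PlaurLocus	intronmiR	exon	281	560	.	-	.	ID=exon:7;Parent=transcript:PlaurSynthetic.1
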