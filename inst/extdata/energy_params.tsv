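param	key	value
# intronmiR simplified nearest-neighbor energy model, version 1.
# Stacks are keyed outer:inner where each pair is written 5'base+3'base of the
# closing pair; energies are model units (negative = stabilizing).
# Watson-Crick x Watson-Crick stacks follow rounded nearest-neighbor values;
# every stack involving a GU wobble pair carries one uniform weak term.
stack	AU:AU	-0.9
stack	AU:UA	-1.1
stack	AU:CG	-2.2
stack	AU:GC	-2.1
stack	AU:GU	-1.0
stack	AU:UG	-1.0
stack	UA:AU	-1.3
stack	UA:UA	-0.9
stack	UA:CG	-2.4
stack	UA:GC	-2.1
stack	UA:GU	-1.0
stack	UA:UG	-1.0
stack	CG:AU	-2.1
stack	CG:UA	-2.1
stack	CG:CG	-3.3
stack	CG:GC	-2.4
stack	CG:GU	-1.0
stack	CG:UG	-1.0
stack	GC:AU	-2.4
stack	GC:UA	-2.2
stack	GC:CG	-3.4
stack	GC:GC	-3.3
stack	GC:GU	-1.0
stack	GC:UG	-1.0
stack	GU:AU	-1.0
stack	GU:UA	-1.0
stack	GU:CG	-1.0
stack	GU:GC	-1.0
stack	GU:GU	-1.0
stack	GU:UG	-1.0
stack	UG:AU	-1.0
stack	UG:UA	-1.0
stack	UG:CG	-1.0
stack	UG:GC	-1.0
stack	UG:GU	-1.0
stack	UG:UG	-1.0
# Loop penalties: hairpin(l) = hairpin_a + hairpin_b * ln(l / min_loop);
# bulge(l) = bulge_a + bulge_b * ln(l); internal(l1,l2) = internal_a +
# internal_b * ln((l1+l2)/2) + min(asym_coef * |l1-l2|, asym_max).
misc	hairpin_a	5.0
misc	hairpin_b	1.75
misc	bulge_a	3.8
misc	bulge_b	1.75
misc	internal_a	4.0
misc	internal_b	1.75
misc	asym_coef	0.6
misc	asym_max	3.0
misc	min_loop	3
misc	max_interior	20
misc	au_end	0.5
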