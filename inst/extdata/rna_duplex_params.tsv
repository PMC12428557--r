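# Nearest-neighbour RNA/RNA duplex parameters (kcal/mol, 37 C).
# Turner-style helix stacks over the six pairs AU, UA, CG, GC, GU, UG.
# A stack entry 'P|Q' is the free energy of pair Q stacked 3' of pair P
# (5'-p1a p2a-3' / 3'-p1b p2b-5'). Only one member of each symmetry class
# (P|Q == flip(Q)|flip(P), flip swapping the two strands) is listed; the
# loader expands the rest. Bulge and interior entries are loop initiation
# penalties by loop size; interior loops add an asymmetry term
# min(asym_max, asym_coef * |l1 - l2|).
section	key	value
init	duplex	4.10
cap	bulge	15
cap	interior	15
asym	coef	0.50
asym	max	3.00
stack	AU|AU	-0.93
stack	AU|UA	-1.10
stack	UA|AU	-1.33
stack	AU|CG	-2.24
stack	AU|GC	-2.08
stack	UA|CG	-2.35
stack	UA|GC	-2.11
stack	CG|CG	-3.26
stack	CG|GC	-2.36
stack	GC|CG	-3.42
stack	AU|GU	-0.55
stack	AU|UG	-1.36
stack	UA|GU	-1.27
stack	UA|UG	-1.00
stack	CG|GU	-1.41
stack	CG|UG	-2.11
stack	GC|GU	-1.53
stack	GC|UG	-2.51
stack	GU|GU	-0.50
stack	GU|UG	1.29
stack	UG|GU	-0.30
bulge	1	3.80
bulge	2	2.80
bulge	3	3.20
bulge	4	3.60
bulge	5	4.00
bulge	6	4.40
bulge	7	4.60
bulge	8	4.70
bulge	9	4.80
bulge	10	4.90
bulge	11	5.00
bulge	12	5.10
bulge	13	5.20
bulge	14	5.30
bulge	15	5.40
interior	2	1.50
interior	3	1.60
interior	4	1.70
interior	5	2.00
interior	6	2.20
interior	7	2.30
interior	8	2.40
interior	9	2.50
interior	10	2.60
interior	11	2.70
interior	12	2.80
interior	13	2.90
interior	14	3.00
interior	15	3.10
interior	16	3.20
interior	17	3.30
interior	18	3.40
interior	19	3.50
interior	20	3.60
interior	21	3.70
interior	22	3.80
interior	23	3.90
interior	24	4.00
interior	25	4.10
interior	26	4.20
interior	27	4.30
interior	28	4.40
interior	29	4.50
interior	30	4.60
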