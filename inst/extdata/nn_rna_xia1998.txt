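# provenance: RNA/RNA nearest-neighbor parameters, Xia et al. (1998),
# Watson-Crick stacks in 1 M NaCl. dH in kcal/mol, dS in cal/(mol K).
# Stack key = top-strand dinucleotide 5'->3'; bottom strand is its
# Watson-Crick complement. INIT = helix initiation, TERM_AU = per terminal
# A:U pair penalty, SYM = self-complementary symmetry correction.
stack	dH	dS
AA	-6.82	-19.0
AU	-9.38	-26.7
UA	-7.69	-20.5
UU	-6.82	-19.0
CU	-10.48	-27.1
AG	-10.48	-27.1
CA	-10.44	-26.9
UG	-10.44	-26.9
GU	-11.40	-29.5
AC	-11.40	-29.5
GA	-12.44	-32.5
UC	-12.44	-32.5
CG	-10.64	-26.7
GG	-13.39	-32.7
CC	-13.39	-32.7
GC	-14.88	-36.9
INIT	3.61	-1.5
TERM_AU	3.72	10.5
SYM	0.00	-1.4
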