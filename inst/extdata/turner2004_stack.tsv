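# param_set: turner2004-duplex v1
# RNA/RNA nearest-neighbor stacking free energies at 37C (kcal/mol),
# Turner 2004 set. Key: top strand dinucleotide 5'->3' / bottom strand
# dinucleotide 3'->5'; the left column of each side is the outer pair.
# Affine interior-loop/bulge penalties and the terminal AU/GU penalty
# are constants of this duplex-only model.
key	kcal
AA/UU	-0.90
AC/UG	-2.20
AG/UC	-2.10
AG/UU	-0.60
AU/UA	-1.10
AU/UG	-1.40
CA/GU	-2.10
CC/GG	-3.30
CG/GC	-2.40
CG/GU	-1.40
CU/GA	-2.10
CU/GG	-2.10
GA/CU	-2.40
GA/UU	-1.30
GC/CG	-3.40
GC/UG	-2.50
GG/CC	-3.30
GG/CU	-1.50
GG/UC	-2.10
GG/UU	-0.50
GU/CA	-2.20
GU/CG	-2.50
GU/UA	-1.40
GU/UG	1.30
UA/AU	-1.30
UA/GU	-1.00
UC/AG	-2.40
UC/GG	-1.50
UG/AC	-2.10
UG/AU	-1.00
UG/GC	-1.40
UG/GU	0.30
UU/AA	-0.90
UU/AG	-1.30
UU/GA	-0.60
UU/GG	-0.50
loop_open	3.20
loop_extend	0.40
terminal_au_gu	0.45
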