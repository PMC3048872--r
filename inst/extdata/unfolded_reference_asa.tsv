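# Per-residue accessible surface areas (angstrom^2) of the unfolded-state
# reference: residue X in an extended Gly-X-Gly tripeptide, heavy atoms
# only, 1.4 angstrom probe. Totals follow the classic extended-tripeptide
# accessibility scale (Miller et al. 1987, J Mol Biol 196:641); the
# apolar/polar split assigns carbon and sulfur area to the apolar class
# and nitrogen and oxygen area to the polar class.
# columns: one-letter code, three-letter code, apolar, polar
A	ALA	73	40
R	ARG	118	123
N	ASN	55	103
D	ASP	55	96
C	CYS	102	38
Q	GLN	86	103
E	GLU	86	97
G	GLY	45	40
H	HIS	118	76
I	ILE	144	38
L	LEU	142	38
K	LYS	156	55
M	MET	166	38
F	PHE	180	38
P	PRO	120	23
S	SER	57	65
T	THR	83	63
W	TRP	217	42
Y	TYR	165	64
V	VAL	122	38
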