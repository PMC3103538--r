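# Heavy-atom continuum-electrostatics parameter table shipped with multipk.
# Charges: elementary charges, neutral (reference) protonation form of each
#   residue; hydrogen partial charges are collapsed onto their parent heavy
#   atom so that every residue sums to exactly 0 e and no explicit hydrogen
#   coordinates are required in input structures.
# Radii: Angstrom, dielectric-boundary radii in the spirit of
#   solvation-calibrated (Rashin-type) atomic radii.
# Special atoms: "OXT" row applies to the extra C-terminal oxygen; code
#   overrides the C-terminal backbone C/O with the CTER rows.
residue	atom	charge	radius
BB	N	-0.16	1.60
BB	CA	0.16	2.00
BB	C	0.51	1.80
BB	O	-0.51	1.50
CTER	C	0.30	1.80
CTER	O	-0.55	1.50
CTER	OXT	0.25	1.55
ALA	CB	0.00	2.00
ARG	CB	0.00	2.00
ARG	CG	0.00	2.00
ARG	CD	0.10	2.00
ARG	NE	-0.30	1.60
ARG	CZ	0.50	1.80
ARG	NH1	-0.15	1.60
ARG	NH2	-0.15	1.60
ASN	CB	0.00	2.00
ASN	CG	0.55	1.80
ASN	OD1	-0.55	1.50
ASN	ND2	0.00	1.60
ASP	CB	0.00	2.00
ASP	CG	0.30	1.80
ASP	OD1	-0.55	1.50
ASP	OD2	0.25	1.55
CYS	CB	0.10	2.00
CYS	SG	-0.10	1.85
GLN	CB	0.00	2.00
GLN	CG	0.00	2.00
GLN	CD	0.55	1.80
GLN	OE1	-0.55	1.50
GLN	NE2	0.00	1.60
GLU	CB	0.00	2.00
GLU	CG	0.00	2.00
GLU	CD	0.30	1.80
GLU	OE1	-0.55	1.50
GLU	OE2	0.25	1.55
HIS	CB	0.00	2.00
HIS	CG	0.10	1.80
HIS	ND1	-0.40	1.60
HIS	CD2	0.10	1.80
HIS	CE1	0.30	1.80
HIS	NE2	-0.10	1.60
ILE	CB	0.00	2.00
ILE	CG1	0.00	2.00
ILE	CG2	0.00	2.00
ILE	CD1	0.00	2.00
LEU	CB	0.00	2.00
LEU	CG	0.00	2.00
LEU	CD1	0.00	2.00
LEU	CD2	0.00	2.00
LYS	CB	0.00	2.00
LYS	CG	0.00	2.00
LYS	CD	0.00	2.00
LYS	CE	0.25	2.00
LYS	NZ	-0.25	1.60
MET	CB	0.00	2.00
MET	CG	0.05	2.00
MET	SD	-0.10	1.85
MET	CE	0.05	2.00
PHE	CB	0.00	2.00
PHE	CG	0.00	1.80
PHE	CD1	0.00	1.80
PHE	CD2	0.00	1.80
PHE	CE1	0.00	1.80
PHE	CE2	0.00	1.80
PHE	CZ	0.00	1.80
PRO	CB	0.00	2.00
PRO	CG	0.00	2.00
PRO	CD	0.00	2.00
SER	CB	0.25	2.00
SER	OG	-0.25	1.50
THR	CB	0.25	2.00
THR	OG1	-0.25	1.50
THR	CG2	0.00	2.00
TRP	CB	0.00	2.00
TRP	CG	0.00	1.80
TRP	CD1	0.15	1.80
TRP	CD2	0.00	1.80
TRP	NE1	-0.30	1.60
TRP	CE2	0.15	1.80
TRP	CE3	0.00	1.80
TRP	CZ2	0.00	1.80
TRP	CZ3	0.00	1.80
TRP	CH2	0.00	1.80
TYR	CB	0.00	2.00
TYR	CG	0.00	1.80
TYR	CD1	0.00	1.80
TYR	CD2	0.00	1.80
TYR	CE1	0.00	1.80
TYR	CE2	0.00	1.80
TYR	CZ	0.15	1.80
TYR	OH	-0.15	1.55
VAL	CB	0.00	2.00
VAL	CG1	0.00	2.00
VAL	CG2	0.00	2.00
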