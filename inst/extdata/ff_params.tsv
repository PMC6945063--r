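# phosbind bundled parameter table v1 -- minimal fixed-point-charge set.
# Heavy-atom (united) representation: hydrogen charges are folded into the
# bonded heavy atom so that every residue's charges sum to its formal charge
# (0 for neutral residues, -1 ASP/GLU, +1 LYS/ARG, -2 SEP, +/-1 ions).
# Radii are element vdW radii (Bondi); LJ eps in kJ/mol, sigma in Angstrom
# with Lorentz-Berthelot combination. This is a self-contained toy set for
# reproducible energetics, not a port of any published force field.
# columns: res_name atom charge radius eps sigma
res_name	atom	charge	radius	eps	sigma
ALA	N	-0.20	1.55	0.70	3.25
ALA	CA	0.20	1.70	0.30	3.40
ALA	C	0.50	1.70	0.30	3.40
ALA	O	-0.50	1.52	0.70	3.00
ALA	CB	0.00	1.70	0.30	3.40
GLY	N	-0.20	1.55	0.70	3.25
GLY	CA	0.20	1.70	0.30	3.40
GLY	C	0.50	1.70	0.30	3.40
GLY	O	-0.50	1.52	0.70	3.00
VAL	N	-0.20	1.55	0.70	3.25
VAL	CA	0.20	1.70	0.30	3.40
VAL	C	0.50	1.70	0.30	3.40
VAL	O	-0.50	1.52	0.70	3.00
VAL	CB	0.00	1.70	0.30	3.40
VAL	CG1	0.00	1.70	0.30	3.40
VAL	CG2	0.00	1.70	0.30	3.40
LEU	N	-0.20	1.55	0.70	3.25
LEU	CA	0.20	1.70	0.30	3.40
LEU	C	0.50	1.70	0.30	3.40
LEU	O	-0.50	1.52	0.70	3.00
LEU	CB	0.00	1.70	0.30	3.40
LEU	CG	0.00	1.70	0.30	3.40
LEU	CD1	0.00	1.70	0.30	3.40
LEU	CD2	0.00	1.70	0.30	3.40
ILE	N	-0.20	1.55	0.70	3.25
ILE	CA	0.20	1.70	0.30	3.40
ILE	C	0.50	1.70	0.30	3.40
ILE	O	-0.50	1.52	0.70	3.00
ILE	CB	0.00	1.70	0.30	3.40
ILE	CG1	0.00	1.70	0.30	3.40
ILE	CG2	0.00	1.70	0.30	3.40
ILE	CD1	0.00	1.70	0.30	3.40
PHE	N	-0.20	1.55	0.70	3.25
PHE	CA	0.20	1.70	0.30	3.40
PHE	C	0.50	1.70	0.30	3.40
PHE	O	-0.50	1.52	0.70	3.00
PHE	CB	0.00	1.70	0.30	3.40
PHE	CG	0.00	1.70	0.30	3.40
PHE	CD1	0.00	1.70	0.30	3.40
PHE	CD2	0.00	1.70	0.30	3.40
PHE	CE1	0.00	1.70	0.30	3.40
PHE	CE2	0.00	1.70	0.30	3.40
PHE	CZ	0.00	1.70	0.30	3.40
TRP	N	-0.20	1.55	0.70	3.25
TRP	CA	0.20	1.70	0.30	3.40
TRP	C	0.50	1.70	0.30	3.40
TRP	O	-0.50	1.52	0.70	3.00
TRP	CB	0.00	1.70	0.30	3.40
TRP	CG	0.00	1.70	0.30	3.40
TRP	CD1	0.05	1.70	0.30	3.40
TRP	CD2	0.00	1.70	0.30	3.40
TRP	NE1	-0.10	1.55	0.70	3.25
TRP	CE2	0.05	1.70	0.30	3.40
TRP	CE3	0.00	1.70	0.30	3.40
TRP	CZ2	0.00	1.70	0.30	3.40
TRP	CZ3	0.00	1.70	0.30	3.40
TRP	CH2	0.00	1.70	0.30	3.40
MET	N	-0.20	1.55	0.70	3.25
MET	CA	0.20	1.70	0.30	3.40
MET	C	0.50	1.70	0.30	3.40
MET	O	-0.50	1.52	0.70	3.00
MET	CB	0.00	1.70	0.30	3.40
MET	CG	0.05	1.70	0.30	3.40
MET	SD	-0.10	1.80	1.00	3.55
MET	CE	0.05	1.70	0.30	3.40
SER	N	-0.20	1.55	0.70	3.25
SER	CA	0.20	1.70	0.30	3.40
SER	C	0.50	1.70	0.30	3.40
SER	O	-0.50	1.52	0.70	3.00
SER	CB	0.25	1.70	0.30	3.40
SER	OG	-0.25	1.52	0.70	3.00
THR	N	-0.20	1.55	0.70	3.25
THR	CA	0.20	1.70	0.30	3.40
THR	C	0.50	1.70	0.30	3.40
THR	O	-0.50	1.52	0.70	3.00
THR	CB	0.25	1.70	0.30	3.40
THR	OG1	-0.25	1.52	0.70	3.00
THR	CG2	0.00	1.70	0.30	3.40
CYS	N	-0.20	1.55	0.70	3.25
CYS	CA	0.20	1.70	0.30	3.40
CYS	C	0.50	1.70	0.30	3.40
CYS	O	-0.50	1.52	0.70	3.00
CYS	CB	0.10	1.70	0.30	3.40
CYS	SG	-0.10	1.80	1.00	3.55
TYR	N	-0.20	1.55	0.70	3.25
TYR	CA	0.20	1.70	0.30	3.40
TYR	C	0.50	1.70	0.30	3.40
TYR	O	-0.50	1.52	0.70	3.00
TYR	CB	0.00	1.70	0.30	3.40
TYR	CG	0.00	1.70	0.30	3.40
TYR	CD1	0.00	1.70	0.30	3.40
TYR	CD2	0.00	1.70	0.30	3.40
TYR	CE1	0.00	1.70	0.30	3.40
TYR	CE2	0.00	1.70	0.30	3.40
TYR	CZ	0.25	1.70	0.30	3.40
TYR	OH	-0.25	1.52	0.70	3.00
ASN	N	-0.20	1.55	0.70	3.25
ASN	CA	0.20	1.70	0.30	3.40
ASN	C	0.50	1.70	0.30	3.40
ASN	O	-0.50	1.52	0.70	3.00
ASN	CB	0.00	1.70	0.30	3.40
ASN	CG	0.55	1.70	0.30	3.40
ASN	OD1	-0.55	1.52	0.70	3.00
ASN	ND2	0.00	1.55	0.70	3.25
GLN	N	-0.20	1.55	0.70	3.25
GLN	CA	0.20	1.70	0.30	3.40
GLN	C	0.50	1.70	0.30	3.40
GLN	O	-0.50	1.52	0.70	3.00
GLN	CB	0.00	1.70	0.30	3.40
GLN	CG	0.00	1.70	0.30	3.40
GLN	CD	0.55	1.70	0.30	3.40
GLN	OE1	-0.55	1.52	0.70	3.00
GLN	NE2	0.00	1.55	0.70	3.25
ASP	N	-0.20	1.55	0.70	3.25
ASP	CA	0.20	1.70	0.30	3.40
ASP	C	0.50	1.70	0.30	3.40
ASP	O	-0.50	1.52	0.70	3.00
ASP	CB	0.00	1.70	0.30	3.40
ASP	CG	0.36	1.70	0.30	3.40
ASP	OD1	-0.68	1.52	0.70	3.00
ASP	OD2	-0.68	1.52	0.70	3.00
GLU	N	-0.20	1.55	0.70	3.25
GLU	CA	0.20	1.70	0.30	3.40
GLU	C	0.50	1.70	0.30	3.40
GLU	O	-0.50	1.52	0.70	3.00
GLU	CB	0.00	1.70	0.30	3.40
GLU	CG	0.00	1.70	0.30	3.40
GLU	CD	0.36	1.70	0.30	3.40
GLU	OE1	-0.68	1.52	0.70	3.00
GLU	OE2	-0.68	1.52	0.70	3.00
LYS	N	-0.20	1.55	0.70	3.25
LYS	CA	0.20	1.70	0.30	3.40
LYS	C	0.50	1.70	0.30	3.40
LYS	O	-0.50	1.52	0.70	3.00
LYS	CB	0.00	1.70	0.30	3.40
LYS	CG	0.00	1.70	0.30	3.40
LYS	CD	0.00	1.70	0.30	3.40
LYS	CE	0.25	1.70	0.30	3.40
LYS	NZ	0.75	1.55	0.70	3.25
ARG	N	-0.20	1.55	0.70	3.25
ARG	CA	0.20	1.70	0.30	3.40
ARG	C	0.50	1.70	0.30	3.40
ARG	O	-0.50	1.52	0.70	3.00
ARG	CB	0.00	1.70	0.30	3.40
ARG	CG	0.00	1.70	0.30	3.40
ARG	CD	0.10	1.70	0.30	3.40
ARG	NE	0.10	1.55	0.70	3.25
ARG	CZ	0.40	1.70	0.30	3.40
ARG	NH1	0.20	1.55	0.70	3.25
ARG	NH2	0.20	1.55	0.70	3.25
HIS	N	-0.20	1.55	0.70	3.25
HIS	CA	0.20	1.70	0.30	3.40
HIS	C	0.50	1.70	0.30	3.40
HIS	O	-0.50	1.52	0.70	3.00
HIS	CB	0.00	1.70	0.30	3.40
HIS	CG	0.00	1.70	0.30	3.40
HIS	ND1	-0.10	1.55	0.70	3.25
HIS	CD2	0.00	1.70	0.30	3.40
HIS	CE1	0.20	1.70	0.30	3.40
HIS	NE2	-0.10	1.55	0.70	3.25
PRO	N	-0.20	1.55	0.70	3.25
PRO	CA	0.20	1.70	0.30	3.40
PRO	C	0.50	1.70	0.30	3.40
PRO	O	-0.50	1.52	0.70	3.00
PRO	CB	0.00	1.70	0.30	3.40
PRO	CG	0.00	1.70	0.30	3.40
PRO	CD	0.00	1.70	0.30	3.40
SEP	N	-0.20	1.55	0.70	3.25
SEP	CA	0.20	1.70	0.30	3.40
SEP	C	0.50	1.70	0.30	3.40
SEP	O	-0.50	1.52	0.70	3.00
SEP	CB	0.00	1.70	0.30	3.40
SEP	OG	-0.40	1.52	0.70	3.00
SEP	P	1.10	1.80	0.80	3.70
SEP	O1P	-0.90	1.52	0.70	3.00
SEP	O2P	-0.90	1.52	0.70	3.00
SEP	O3P	-0.90	1.52	0.70	3.00
SOD	SOD	1.00	2.27	0.20	2.40
CLA	CLA	-1.00	1.81	0.60	4.40
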