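res_type	atom_name	a	polar_class
*	N	-0.90	acid
*	CA	0.30	hydrophobic
*	C	-0.30	amphoteric
*	O	-1.00	base
*	OXT	-1.50	base
ALA	CB	0.90	hydrophobic
ARG	CB	0.70	hydrophobic
ARG	CG	0.70	hydrophobic
ARG	CD	0.40	hydrophobic
ARG	NE	-1.00	acid
ARG	CZ	-0.30	amphoteric
ARG	NH1	-1.80	acid
ARG	NH2	-1.80	acid
ASN	CB	0.70	hydrophobic
ASN	CG	-0.30	amphoteric
ASN	OD1	-1.00	base
ASN	ND2	-1.00	acid
ASP	CB	0.70	hydrophobic
ASP	CG	-0.30	amphoteric
ASP	OD1	-1.80	base
ASP	OD2	-1.80	base
CYS	CB	0.60	hydrophobic
CYS	SG	-0.40	amphoteric
CYX	CB	0.60	hydrophobic
CYX	SG	0.30	hydrophobic
GLN	CB	0.70	hydrophobic
GLN	CG	0.70	hydrophobic
GLN	CD	-0.30	amphoteric
GLN	OE1	-1.00	base
GLN	NE2	-1.00	acid
GLU	CB	0.70	hydrophobic
GLU	CG	0.70	hydrophobic
GLU	CD	-0.30	amphoteric
GLU	OE1	-1.80	base
GLU	OE2	-1.80	base
HIS	CB	0.70	hydrophobic
HIS	CG	0.20	hydrophobic
HIS	ND1	-1.20	base
HIS	CD2	0.30	hydrophobic
HIS	CE1	0.20	hydrophobic
HIS	NE2	-1.00	acid
ILE	CB	0.80	hydrophobic
ILE	CG1	0.80	hydrophobic
ILE	CG2	0.90	hydrophobic
ILE	CD1	0.90	hydrophobic
LEU	CB	0.80	hydrophobic
LEU	CG	0.80	hydrophobic
LEU	CD1	0.90	hydrophobic
LEU	CD2	0.90	hydrophobic
LYS	CB	0.70	hydrophobic
LYS	CG	0.80	hydrophobic
LYS	CD	0.80	hydrophobic
LYS	CE	0.40	hydrophobic
LYS	NZ	-1.80	acid
MET	CB	0.70	hydrophobic
MET	CG	0.60	hydrophobic
MET	SD	-0.20	amphoteric
MET	CE	0.70	hydrophobic
PHE	CB	0.70	hydrophobic
PHE	CG	0.40	hydrophobic
PHE	CD1	0.40	hydrophobic
PHE	CD2	0.40	hydrophobic
PHE	CE1	0.40	hydrophobic
PHE	CE2	0.40	hydrophobic
PHE	CZ	0.40	hydrophobic
PRO	CB	0.80	hydrophobic
PRO	CG	0.80	hydrophobic
PRO	CD	0.50	hydrophobic
SER	CB	0.50	hydrophobic
SER	OG	-1.00	amphoteric
THR	CB	0.50	hydrophobic
THR	OG1	-1.00	amphoteric
THR	CG2	0.90	hydrophobic
TRP	CB	0.70	hydrophobic
TRP	CG	0.30	hydrophobic
TRP	CD1	0.30	hydrophobic
TRP	CD2	0.40	hydrophobic
TRP	NE1	-0.90	acid
TRP	CE2	0.30	hydrophobic
TRP	CE3	0.40	hydrophobic
TRP	CZ2	0.40	hydrophobic
TRP	CZ3	0.40	hydrophobic
TRP	CH2	0.40	hydrophobic
TYR	CB	0.70	hydrophobic
TYR	CG	0.40	hydrophobic
TYR	CD1	0.40	hydrophobic
TYR	CD2	0.40	hydrophobic
TYR	CE1	0.40	hydrophobic
TYR	CE2	0.40	hydrophobic
TYR	CZ	0.20	hydrophobic
TYR	OH	-1.00	amphoteric
VAL	CB	0.80	hydrophobic
VAL	CG1	0.90	hydrophobic
VAL	CG2	0.90	hydrophobic
HOH	O	-1.20	amphoteric
DPPC	N	-1.50	acid
DPPC	C11	0.40	hydrophobic
DPPC	C12	0.40	hydrophobic
DPPC	C13	0.50	hydrophobic
DPPC	C14	0.50	hydrophobic
DPPC	C15	0.50	hydrophobic
DPPC	P	-1.50	amphoteric
DPPC	O11	-1.20	base
DPPC	O12	-1.20	base
DPPC	O13	-1.20	base
DPPC	O14	-1.20	base
DPPC	C1	0.40	hydrophobic
DPPC	C2	0.40	hydrophobic
DPPC	C3	0.40	hydrophobic
DPPC	O21	-1.00	base
DPPC	C21	-0.30	amphoteric
DPPC	O22	-1.00	base
DPPC	O31	-1.00	base
DPPC	C31	-0.30	amphoteric
DPPC	O32	-1.00	base
DPPC	C22	0.90	hydrophobic
DPPC	C23	0.90	hydrophobic
DPPC	C24	0.90	hydrophobic
DPPC	C25	0.90	hydrophobic
DPPC	C26	0.90	hydrophobic
DPPC	C27	0.90	hydrophobic
DPPC	C28	0.90	hydrophobic
DPPC	C29	0.90	hydrophobic
DPPC	C210	0.90	hydrophobic
DPPC	C211	0.90	hydrophobic
DPPC	C212	0.90	hydrophobic
DPPC	C213	0.90	hydrophobic
DPPC	C214	0.90	hydrophobic
DPPC	C215	0.90	hydrophobic
DPPC	C216	0.90	hydrophobic
DPPC	C32	0.90	hydrophobic
DPPC	C33	0.90	hydrophobic
DPPC	C34	0.90	hydrophobic
DPPC	C35	0.90	hydrophobic
DPPC	C36	0.90	hydrophobic
DPPC	C37	0.90	hydrophobic
DPPC	C38	0.90	hydrophobic
DPPC	C39	0.90	hydrophobic
DPPC	C310	0.90	hydrophobic
DPPC	C311	0.90	hydrophobic
DPPC	C312	0.90	hydrophobic
DPPC	C313	0.90	hydrophobic
DPPC	C314	0.90	hydrophobic
DPPC	C315	0.90	hydrophobic
DPPC	C316	0.90	hydrophobic
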