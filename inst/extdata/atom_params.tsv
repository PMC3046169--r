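# Atom physics parameters: CHARMM-like 12-6 vdW (rmin is per-atom,
# rmin_ij = rmin_i + rmin_j), simplified partial charges on polar and
# charged groups, EEF1-style Gaussian solvent-exclusion parameters.
# Units: A, kcal/mol, elementary charges, A^3. Rows with residue '*'
# are element-based fallbacks for unrecognised atom names.
residue	atom	vdw_rmin	vdw_epsilon	partial_charge	solv_dG_free	solv_lambda	solv_volume	is_donor_heavy	is_acceptor
ALA	N	1.85	0.2	-0.4	-5.95	3.5	11.2	1	0
ALA	CA	2.28	0.032	0.4	-0.19	3.5	14.7	0	0
ALA	C	2	0.11	0.55	0	3.5	14.7	0	0
ALA	O	1.7	0.12	-0.55	-5.33	3.5	10.8	0	1
ALA	CB	2.01	0.055	0	0.52	3.5	22.4	0	0
ARG	N	1.85	0.2	-0.4	-5.95	3.5	11.2	1	0
ARG	CA	2.28	0.032	0.4	-0.19	3.5	14.7	0	0
ARG	C	2	0.11	0.55	0	3.5	14.7	0	0
ARG	O	1.7	0.12	-0.55	-5.33	3.5	10.8	0	1
ARG	CB	2.01	0.055	0	0.52	3.5	22.4	0	0
ARG	CG	2.01	0.055	0	0.52	3.5	22.4	0	0
ARG	CD	2.01	0.055	0.2	0.52	3.5	22.4	0	0
ARG	NE	1.85	0.2	-0.2	-20	6	11.2	1	0
ARG	CZ	2	0.11	0.5	0	3.5	14.7	0	0
ARG	NH1	1.85	0.2	0.25	-20	6	11.2	1	0
ARG	NH2	1.85	0.2	0.25	-20	6	11.2	1	0
ASN	N	1.85	0.2	-0.4	-5.95	3.5	11.2	1	0
ASN	CA	2.28	0.032	0.4	-0.19	3.5	14.7	0	0
ASN	C	2	0.11	0.55	0	3.5	14.7	0	0
ASN	O	1.7	0.12	-0.55	-5.33	3.5	10.8	0	1
ASN	CB	2.01	0.055	0	0.52	3.5	22.4	0	0
ASN	CG	2	0.11	0.95	0	3.5	14.7	0	0
ASN	OD1	1.7	0.12	-0.55	-5.33	3.5	10.8	0	1
ASN	ND2	1.85	0.2	-0.4	-5.45	3.5	11.2	1	0
ASP	N	1.85	0.2	-0.4	-5.95	3.5	11.2	1	0
ASP	CA	2.28	0.032	0.4	-0.19	3.5	14.7	0	0
ASP	C	2	0.11	0.55	0	3.5	14.7	0	0
ASP	O	1.7	0.12	-0.55	-5.33	3.5	10.8	0	1
ASP	CB	2.01	0.055	0	0.52	3.5	22.4	0	0
ASP	CG	2	0.11	0.5	0	3.5	14.7	0	0
ASP	OD1	1.7	0.12	-0.75	-10	6	10.8	0	1
ASP	OD2	1.7	0.12	-0.75	-10	6	10.8	0	1
CYS	N	1.85	0.2	-0.4	-5.95	3.5	11.2	1	0
CYS	CA	2.28	0.032	0.4	-0.19	3.5	14.7	0	0
CYS	C	2	0.11	0.55	0	3.5	14.7	0	0
CYS	O	1.7	0.12	-0.55	-5.33	3.5	10.8	0	1
CYS	CB	2.01	0.055	0	0.52	3.5	22.4	0	0
CYS	SG	2	0.45	-0.23	-3.24	3.5	14.7	1	0
GLN	N	1.85	0.2	-0.4	-5.95	3.5	11.2	1	0
GLN	CA	2.28	0.032	0.4	-0.19	3.5	14.7	0	0
GLN	C	2	0.11	0.55	0	3.5	14.7	0	0
GLN	O	1.7	0.12	-0.55	-5.33	3.5	10.8	0	1
GLN	CB	2.01	0.055	0	0.52	3.5	22.4	0	0
GLN	CG	2.01	0.055	0	0.52	3.5	22.4	0	0
GLN	CD	2	0.11	0.95	0	3.5	14.7	0	0
GLN	OE1	1.7	0.12	-0.55	-5.33	3.5	10.8	0	1
GLN	NE2	1.85	0.2	-0.4	-5.45	3.5	11.2	1	0
GLU	N	1.85	0.2	-0.4	-5.95	3.5	11.2	1	0
GLU	CA	2.28	0.032	0.4	-0.19	3.5	14.7	0	0
GLU	C	2	0.11	0.55	0	3.5	14.7	0	0
GLU	O	1.7	0.12	-0.55	-5.33	3.5	10.8	0	1
GLU	CB	2.01	0.055	0	0.52	3.5	22.4	0	0
GLU	CG	2.01	0.055	0	0.52	3.5	22.4	0	0
GLU	CD	2	0.11	0.5	0	3.5	14.7	0	0
GLU	OE1	1.7	0.12	-0.75	-10	6	10.8	0	1
GLU	OE2	1.7	0.12	-0.75	-10	6	10.8	0	1
GLY	N	1.85	0.2	-0.4	-5.95	3.5	11.2	1	0
GLY	CA	2.28	0.032	0.4	-0.19	3.5	14.7	0	0
GLY	C	2	0.11	0.55	0	3.5	14.7	0	0
GLY	O	1.7	0.12	-0.55	-5.33	3.5	10.8	0	1
HIS	N	1.85	0.2	-0.4	-5.95	3.5	11.2	1	0
HIS	CA	2.28	0.032	0.4	-0.19	3.5	14.7	0	0
HIS	C	2	0.11	0.55	0	3.5	14.7	0	0
HIS	O	1.7	0.12	-0.55	-5.33	3.5	10.8	0	1
HIS	CB	2.01	0.055	0	0.52	3.5	22.4	0	0
HIS	CG	1.99	0.07	0	0.08	3.5	18.4	0	0
HIS	ND1	1.85	0.2	-0.36	-4	3.5	4.4	1	1
HIS	CD2	1.99	0.07	0.36	0.08	3.5	18.4	0	0
HIS	CE1	1.99	0.07	0.36	0.08	3.5	18.4	0	0
HIS	NE2	1.85	0.2	-0.36	-4	3.5	4.4	1	1
ILE	N	1.85	0.2	-0.4	-5.95	3.5	11.2	1	0
ILE	CA	2.28	0.032	0.4	-0.19	3.5	14.7	0	0
ILE	C	2	0.11	0.55	0	3.5	14.7	0	0
ILE	O	1.7	0.12	-0.55	-5.33	3.5	10.8	0	1
ILE	CB	2.01	0.055	0	0.52	3.5	22.4	0	0
ILE	CG1	2.01	0.055	0	0.52	3.5	22.4	0	0
ILE	CG2	2.06	0.078	0	1.5	3.5	23.7	0	0
ILE	CD1	2.06	0.078	0	1.5	3.5	23.7	0	0
LEU	N	1.85	0.2	-0.4	-5.95	3.5	11.2	1	0
LEU	CA	2.28	0.032	0.4	-0.19	3.5	14.7	0	0
LEU	C	2	0.11	0.55	0	3.5	14.7	0	0
LEU	O	1.7	0.12	-0.55	-5.33	3.5	10.8	0	1
LEU	CB	2.01	0.055	0	0.52	3.5	22.4	0	0
LEU	CG	2.28	0.032	0	-0.19	3.5	14.7	0	0
LEU	CD1	2.06	0.078	0	1.5	3.5	23.7	0	0
LEU	CD2	2.06	0.078	0	1.5	3.5	23.7	0	0
LYS	N	1.85	0.2	-0.4	-5.95	3.5	11.2	1	0
LYS	CA	2.28	0.032	0.4	-0.19	3.5	14.7	0	0
LYS	C	2	0.11	0.55	0	3.5	14.7	0	0
LYS	O	1.7	0.12	-0.55	-5.33	3.5	10.8	0	1
LYS	CB	2.01	0.055	0	0.52	3.5	22.4	0	0
LYS	CG	2.01	0.055	0	0.52	3.5	22.4	0	0
LYS	CD	2.01	0.055	0	0.52	3.5	22.4	0	0
LYS	CE	2.01	0.055	0	0.52	3.5	22.4	0	0
LYS	NZ	1.85	0.2	1	-20	6	11.2	1	0
MET	N	1.85	0.2	-0.4	-5.95	3.5	11.2	1	0
MET	CA	2.28	0.032	0.4	-0.19	3.5	14.7	0	0
MET	C	2	0.11	0.55	0	3.5	14.7	0	0
MET	O	1.7	0.12	-0.55	-5.33	3.5	10.8	0	1
MET	CB	2.01	0.055	0	0.52	3.5	22.4	0	0
MET	CG	2.01	0.055	0.05	0.52	3.5	22.4	0	0
MET	SD	2	0.45	-0.1	-3.24	3.5	14.7	0	0
MET	CE	2.06	0.078	0.05	1.5	3.5	23.7	0	0
PHE	N	1.85	0.2	-0.4	-5.95	3.5	11.2	1	0
PHE	CA	2.28	0.032	0.4	-0.19	3.5	14.7	0	0
PHE	C	2	0.11	0.55	0	3.5	14.7	0	0
PHE	O	1.7	0.12	-0.55	-5.33	3.5	10.8	0	1
PHE	CB	2.01	0.055	0	0.52	3.5	22.4	0	0
PHE	CG	1.99	0.07	0	0.08	3.5	18.4	0	0
PHE	CD1	1.99	0.07	0	0.08	3.5	18.4	0	0
PHE	CD2	1.99	0.07	0	0.08	3.5	18.4	0	0
PHE	CE1	1.99	0.07	0	0.08	3.5	18.4	0	0
PHE	CE2	1.99	0.07	0	0.08	3.5	18.4	0	0
PHE	CZ	1.99	0.07	0	0.08	3.5	18.4	0	0
PRO	N	1.85	0.2	-0.4	-5.95	3.5	11.2	0	0
PRO	CA	2.28	0.032	0.4	-0.19	3.5	14.7	0	0
PRO	C	2	0.11	0.55	0	3.5	14.7	0	0
PRO	O	1.7	0.12	-0.55	-5.33	3.5	10.8	0	1
PRO	CB	2.01	0.055	0	0.52	3.5	22.4	0	0
PRO	CG	2.01	0.055	0	0.52	3.5	22.4	0	0
PRO	CD	2.01	0.055	0	0.52	3.5	22.4	0	0
SER	N	1.85	0.2	-0.4	-5.95	3.5	11.2	1	0
SER	CA	2.28	0.032	0.4	-0.19	3.5	14.7	0	0
SER	C	2	0.11	0.55	0	3.5	14.7	0	0
SER	O	1.7	0.12	-0.55	-5.33	3.5	10.8	0	1
SER	CB	2.01	0.055	0	0.52	3.5	22.4	0	0
SER	OG	1.77	0.152	-0.54	-5.92	3.5	10.8	1	1
THR	N	1.85	0.2	-0.4	-5.95	3.5	11.2	1	0
THR	CA	2.28	0.032	0.4	-0.19	3.5	14.7	0	0
THR	C	2	0.11	0.55	0	3.5	14.7	0	0
THR	O	1.7	0.12	-0.55	-5.33	3.5	10.8	0	1
THR	CB	2.01	0.055	0	0.52	3.5	22.4	0	0
THR	OG1	1.77	0.152	-0.54	-5.92	3.5	10.8	1	1
THR	CG2	2.06	0.078	0	1.5	3.5	23.7	0	0
TRP	N	1.85	0.2	-0.4	-5.95	3.5	11.2	1	0
TRP	CA	2.28	0.032	0.4	-0.19	3.5	14.7	0	0
TRP	C	2	0.11	0.55	0	3.5	14.7	0	0
TRP	O	1.7	0.12	-0.55	-5.33	3.5	10.8	0	1
TRP	CB	2.01	0.055	0	0.52	3.5	22.4	0	0
TRP	CG	1.99	0.07	0	0.08	3.5	18.4	0	0
TRP	CD1	1.99	0.07	0.35	0.08	3.5	18.4	0	0
TRP	CD2	1.99	0.07	0	0.08	3.5	18.4	0	0
TRP	NE1	1.85	0.2	-0.35	-5.95	3.5	11.2	1	0
TRP	CE2	1.99	0.07	0	0.08	3.5	18.4	0	0
TRP	CE3	1.99	0.07	0	0.08	3.5	18.4	0	0
TRP	CZ2	1.99	0.07	0	0.08	3.5	18.4	0	0
TRP	CZ3	1.99	0.07	0	0.08	3.5	18.4	0	0
TRP	CH2	1.99	0.07	0	0.08	3.5	18.4	0	0
TYR	N	1.85	0.2	-0.4	-5.95	3.5	11.2	1	0
TYR	CA	2.28	0.032	0.4	-0.19	3.5	14.7	0	0
TYR	C	2	0.11	0.55	0	3.5	14.7	0	0
TYR	O	1.7	0.12	-0.55	-5.33	3.5	10.8	0	1
TYR	CB	2.01	0.055	0	0.52	3.5	22.4	0	0
TYR	CG	1.99	0.07	0	0.08	3.5	18.4	0	0
TYR	CD1	1.99	0.07	0	0.08	3.5	18.4	0	0
TYR	CD2	1.99	0.07	0	0.08	3.5	18.4	0	0
TYR	CE1	1.99	0.07	0	0.08	3.5	18.4	0	0
TYR	CE2	1.99	0.07	0	0.08	3.5	18.4	0	0
TYR	CZ	1.99	0.07	0.54	0.08	3.5	18.4	0	0
TYR	OH	1.77	0.152	-0.54	-5.92	3.5	10.8	1	1
VAL	N	1.85	0.2	-0.4	-5.95	3.5	11.2	1	0
VAL	CA	2.28	0.032	0.4	-0.19	3.5	14.7	0	0
VAL	C	2	0.11	0.55	0	3.5	14.7	0	0
VAL	O	1.7	0.12	-0.55	-5.33	3.5	10.8	0	1
VAL	CB	2.01	0.055	0	0.52	3.5	22.4	0	0
VAL	CG1	2.06	0.078	0	1.5	3.5	23.7	0	0
VAL	CG2	2.06	0.078	0	1.5	3.5	23.7	0	0
*	C	2.01	0.055	0	0.52	3.5	22.4	0	0
*	N	1.85	0.2	0	-5.95	3.5	11.2	1	0
*	O	1.7	0.12	0	-5.33	3.5	10.8	0	1
*	S	2	0.45	0	-3.24	3.5	14.7	0	0
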