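# SYNTHETIC 18-type atomic contact energy table (globulomeR).
# Pairwise contact pseudo-energies proportional to desolvation free energy;
# negative = hydrophobic stabilization. Values are this package's synthetic
# parameterization, NOT a published table. e(i,j) = (d_i + d_j)/2.
# Sections: [types] label description; [energies] type type kcal/mol;
# [assignment] resname atom type ('*' = any residue).
[types]
NBB	backbone amide N
PRN	proline backbone N
CAB	backbone CA
CGY	glycine CA
CBB	backbone carbonyl C
OBB	backbone carbonyl O
OCO	carboxylate O
OHX	hydroxyl O
OAM	sidechain amide O
NAM	sidechain amide N
NPS	charged sidechain N
NAR	aromatic ring N
SUL	sulfur
CB3	aliphatic C
CPA	polar-adjacent sp3 C
CB2	aryl beta C
CAR	aromatic C
CCO	sp2 polar C
[energies]
NBB	NBB	0.0800
NBB	PRN	0.0500
NBB	CAB	0.0150
NBB	CGY	0.0300
NBB	CBB	0.0500
NBB	OBB	0.0900
NBB	OCO	0.1900
NBB	OHX	0.1100
NBB	OAM	0.1000
NBB	NAM	0.1000
NBB	NPS	0.1800
NBB	NAR	0.0800
NBB	SUL	-0.0600
NBB	CB3	-0.0700
NBB	CPA	0.0000
NBB	CB2	-0.0350
NBB	CAR	-0.0500
NBB	CCO	0.0700
PRN	PRN	0.0200
PRN	CAB	-0.0150
PRN	CGY	0.0000
PRN	CBB	0.0200
PRN	OBB	0.0600
PRN	OCO	0.1600
PRN	OHX	0.0800
PRN	OAM	0.0700
PRN	NAM	0.0700
PRN	NPS	0.1500
PRN	NAR	0.0500
PRN	SUL	-0.0900
PRN	CB3	-0.1000
PRN	CPA	-0.0300
PRN	CB2	-0.0650
PRN	CAR	-0.0800
PRN	CCO	0.0400
CAB	CAB	-0.0500
CAB	CGY	-0.0350
CAB	CBB	-0.0150
CAB	OBB	0.0250
CAB	OCO	0.1250
CAB	OHX	0.0450
CAB	OAM	0.0350
CAB	NAM	0.0350
CAB	NPS	0.1150
CAB	NAR	0.0150
CAB	SUL	-0.1250
CAB	CB3	-0.1350
CAB	CPA	-0.0650
CAB	CB2	-0.1000
CAB	CAR	-0.1150
CAB	CCO	0.0050
CGY	CGY	-0.0200
CGY	CBB	0.0000
CGY	OBB	0.0400
CGY	OCO	0.1400
CGY	OHX	0.0600
CGY	OAM	0.0500
CGY	NAM	0.0500
CGY	NPS	0.1300
CGY	NAR	0.0300
CGY	SUL	-0.1100
CGY	CB3	-0.1200
CGY	CPA	-0.0500
CGY	CB2	-0.0850
CGY	CAR	-0.1000
CGY	CCO	0.0200
CBB	CBB	0.0200
CBB	OBB	0.0600
CBB	OCO	0.1600
CBB	OHX	0.0800
CBB	OAM	0.0700
CBB	NAM	0.0700
CBB	NPS	0.1500
CBB	NAR	0.0500
CBB	SUL	-0.0900
CBB	CB3	-0.1000
CBB	CPA	-0.0300
CBB	CB2	-0.0650
CBB	CAR	-0.0800
CBB	CCO	0.0400
OBB	OBB	0.1000
OBB	OCO	0.2000
OBB	OHX	0.1200
OBB	OAM	0.1100
OBB	NAM	0.1100
OBB	NPS	0.1900
OBB	NAR	0.0900
OBB	SUL	-0.0500
OBB	CB3	-0.0600
OBB	CPA	0.0100
OBB	CB2	-0.0250
OBB	CAR	-0.0400
OBB	CCO	0.0800
OCO	OCO	0.3000
OCO	OHX	0.2200
OCO	OAM	0.2100
OCO	NAM	0.2100
OCO	NPS	0.2900
OCO	NAR	0.1900
OCO	SUL	0.0500
OCO	CB3	0.0400
OCO	CPA	0.1100
OCO	CB2	0.0750
OCO	CAR	0.0600
OCO	CCO	0.1800
OHX	OHX	0.1400
OHX	OAM	0.1300
OHX	NAM	0.1300
OHX	NPS	0.2100
OHX	NAR	0.1100
OHX	SUL	-0.0300
OHX	CB3	-0.0400
OHX	CPA	0.0300
OHX	CB2	-0.0050
OHX	CAR	-0.0200
OHX	CCO	0.1000
OAM	OAM	0.1200
OAM	NAM	0.1200
OAM	NPS	0.2000
OAM	NAR	0.1000
OAM	SUL	-0.0400
OAM	CB3	-0.0500
OAM	CPA	0.0200
OAM	CB2	-0.0150
OAM	CAR	-0.0300
OAM	CCO	0.0900
NAM	NAM	0.1200
NAM	NPS	0.2000
NAM	NAR	0.1000
NAM	SUL	-0.0400
NAM	CB3	-0.0500
NAM	CPA	0.0200
NAM	CB2	-0.0150
NAM	CAR	-0.0300
NAM	CCO	0.0900
NPS	NPS	0.2800
NPS	NAR	0.1800
NPS	SUL	0.0400
NPS	CB3	0.0300
NPS	CPA	0.1000
NPS	CB2	0.0650
NPS	CAR	0.0500
NPS	CCO	0.1700
NAR	NAR	0.0800
NAR	SUL	-0.0600
NAR	CB3	-0.0700
NAR	CPA	0.0000
NAR	CB2	-0.0350
NAR	CAR	-0.0500
NAR	CCO	0.0700
SUL	SUL	-0.2000
SUL	CB3	-0.2100
SUL	CPA	-0.1400
SUL	CB2	-0.1750
SUL	CAR	-0.1900
SUL	CCO	-0.0700
CB3	CB3	-0.2200
CB3	CPA	-0.1500
CB3	CB2	-0.1850
CB3	CAR	-0.2000
CB3	CCO	-0.0800
CPA	CPA	-0.0800
CPA	CB2	-0.1150
CPA	CAR	-0.1300
CPA	CCO	-0.0100
CB2	CB2	-0.1500
CB2	CAR	-0.1650
CB2	CCO	-0.0450
CAR	CAR	-0.1800
CAR	CCO	-0.0600
CCO	CCO	0.0600
[assignment]
ALA	N	NBB
ALA	CA	CAB
ALA	C	CBB
ALA	O	OBB
ALA	CB	CB3
ARG	N	NBB
ARG	CA	CAB
ARG	C	CBB
ARG	O	OBB
ARG	CB	CB3
ARG	CG	CB3
ARG	CD	CPA
ARG	NE	NPS
ARG	CZ	CCO
ARG	NH1	NPS
ARG	NH2	NPS
ASN	N	NBB
ASN	CA	CAB
ASN	C	CBB
ASN	O	OBB
ASN	CB	CPA
ASN	CG	CCO
ASN	OD1	OAM
ASN	ND2	NAM
ASP	N	NBB
ASP	CA	CAB
ASP	C	CBB
ASP	O	OBB
ASP	CB	CPA
ASP	CG	CCO
ASP	OD1	OCO
ASP	OD2	OCO
CYS	N	NBB
CYS	CA	CAB
CYS	C	CBB
CYS	O	OBB
CYS	CB	CPA
CYS	SG	SUL
GLN	N	NBB
GLN	CA	CAB
GLN	C	CBB
GLN	O	OBB
GLN	CB	CB3
GLN	CG	CPA
GLN	CD	CCO
GLN	OE1	OAM
GLN	NE2	NAM
GLU	N	NBB
GLU	CA	CAB
GLU	C	CBB
GLU	O	OBB
GLU	CB	CB3
GLU	CG	CPA
GLU	CD	CCO
GLU	OE1	OCO
GLU	OE2	OCO
GLY	N	NBB
GLY	CA	CGY
GLY	C	CBB
GLY	O	OBB
HIS	N	NBB
HIS	CA	CAB
HIS	C	CBB
HIS	O	OBB
HIS	CB	CB2
HIS	CG	CAR
HIS	ND1	NAR
HIS	CD2	CAR
HIS	CE1	CAR
HIS	NE2	NAR
ILE	N	NBB
ILE	CA	CAB
ILE	C	CBB
ILE	O	OBB
ILE	CB	CB3
ILE	CG1	CB3
ILE	CG2	CB3
ILE	CD1	CB3
LEU	N	NBB
LEU	CA	CAB
LEU	C	CBB
LEU	O	OBB
LEU	CB	CB3
LEU	CG	CB3
LEU	CD1	CB3
LEU	CD2	CB3
LYS	N	NBB
LYS	CA	CAB
LYS	C	CBB
LYS	O	OBB
LYS	CB	CB3
LYS	CG	CB3
LYS	CD	CB3
LYS	CE	CPA
LYS	NZ	NPS
MET	N	NBB
MET	CA	CAB
MET	C	CBB
MET	O	OBB
MET	CB	CB3
MET	CG	CPA
MET	SD	SUL
MET	CE	CPA
PHE	N	NBB
PHE	CA	CAB
PHE	C	CBB
PHE	O	OBB
PHE	CB	CB2
PHE	CG	CAR
PHE	CD1	CAR
PHE	CD2	CAR
PHE	CE1	CAR
PHE	CE2	CAR
PHE	CZ	CAR
PRO	N	PRN
PRO	CA	CAB
PRO	C	CBB
PRO	O	OBB
PRO	CB	CB3
PRO	CG	CB3
PRO	CD	CPA
SER	N	NBB
SER	CA	CAB
SER	C	CBB
SER	O	OBB
SER	CB	CPA
SER	OG	OHX
THR	N	NBB
THR	CA	CAB
THR	C	CBB
THR	O	OBB
THR	CB	CPA
THR	OG1	OHX
THR	CG2	CB3
TRP	N	NBB
TRP	CA	CAB
TRP	C	CBB
TRP	O	OBB
TRP	CB	CB2
TRP	CG	CAR
TRP	CD1	CAR
TRP	CD2	CAR
TRP	NE1	NAR
TRP	CE2	CAR
TRP	CE3	CAR
TRP	CZ2	CAR
TRP	CZ3	CAR
TRP	CH2	CAR
TYR	N	NBB
TYR	CA	CAB
TYR	C	CBB
TYR	O	OBB
TYR	CB	CB2
TYR	CG	CAR
TYR	CD1	CAR
TYR	CD2	CAR
TYR	CE1	CAR
TYR	CE2	CAR
TYR	CZ	CAR
TYR	OH	OHX
VAL	N	NBB
VAL	CA	CAB
VAL	C	CBB
VAL	O	OBB
VAL	CB	CB3
VAL	CG1	CB3
VAL	CG2	CB3
*	OXT	OCO
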