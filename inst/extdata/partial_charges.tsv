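# chipacker heavy-atom partial charges v1
# Approximate per-(residue, atom) partial charges patterned on the
# Amber99sb force field, used as weights of the charge channel.
resid	atom_name	charge
ALA	N	-0.4157
ALA	CA	0.0337
ALA	C	0.5973
ALA	O	-0.5679
ALA	CB	-0.1825
ARG	N	-0.3479
ARG	CA	-0.2637
ARG	C	0.7341
ARG	O	-0.5894
ARG	CB	-0.0007
ARG	CG	0.0390
ARG	CD	0.0486
ARG	NE	-0.5295
ARG	CZ	0.8076
ARG	NH1	-0.8627
ARG	NH2	-0.8627
ASN	N	-0.4157
ASN	CA	0.0143
ASN	C	0.5973
ASN	O	-0.5679
ASN	CB	-0.2041
ASN	CG	0.7130
ASN	OD1	-0.5931
ASN	ND2	-0.9191
ASP	N	-0.5163
ASP	CA	0.0381
ASP	C	0.5366
ASP	O	-0.5819
ASP	CB	-0.0303
ASP	CG	0.7994
ASP	OD1	-0.8014
ASP	OD2	-0.8014
CYS	N	-0.4157
CYS	CA	0.0213
CYS	C	0.5973
CYS	O	-0.5679
CYS	CB	-0.1231
CYS	SG	-0.3119
GLN	N	-0.4157
GLN	CA	-0.0031
GLN	C	0.5973
GLN	O	-0.5679
GLN	CB	-0.0036
GLN	CG	-0.0645
GLN	CD	0.6951
GLN	OE1	-0.6086
GLN	NE2	-0.9407
GLU	N	-0.5163
GLU	CA	0.0397
GLU	C	0.5366
GLU	O	-0.5819
GLU	CB	0.0560
GLU	CG	0.0136
GLU	CD	0.8054
GLU	OE1	-0.8188
GLU	OE2	-0.8188
GLY	N	-0.4157
GLY	CA	-0.0252
GLY	C	0.5973
GLY	O	-0.5679
HIS	N	-0.4157
HIS	CA	-0.0581
HIS	C	0.5973
HIS	O	-0.5679
HIS	CB	-0.0074
HIS	CG	0.1868
HIS	ND1	-0.5432
HIS	CD2	-0.2207
HIS	CE1	0.1635
HIS	NE2	-0.2795
ILE	N	-0.4157
ILE	CA	-0.0597
ILE	C	0.5973
ILE	O	-0.5679
ILE	CB	0.1303
ILE	CG1	-0.0430
ILE	CG2	-0.3204
ILE	CD1	-0.0660
LEU	N	-0.4157
LEU	CA	-0.0518
LEU	C	0.5973
LEU	O	-0.5679
LEU	CB	-0.1102
LEU	CG	0.3531
LEU	CD1	-0.4121
LEU	CD2	-0.4121
LYS	N	-0.3479
LYS	CA	-0.2400
LYS	C	0.7341
LYS	O	-0.5894
LYS	CB	-0.0094
LYS	CG	0.0187
LYS	CD	-0.0479
LYS	CE	-0.0143
LYS	NZ	-0.3854
MET	N	-0.4157
MET	CA	-0.0237
MET	C	0.5973
MET	O	-0.5679
MET	CB	0.0342
MET	CG	0.0018
MET	SD	-0.2737
MET	CE	-0.0536
PHE	N	-0.4157
PHE	CA	-0.0024
PHE	C	0.5973
PHE	O	-0.5679
PHE	CB	-0.0343
PHE	CG	0.0118
PHE	CD1	-0.1256
PHE	CD2	-0.1256
PHE	CE1	-0.1704
PHE	CE2	-0.1704
PHE	CZ	-0.1072
PRO	N	-0.2548
PRO	CA	-0.0266
PRO	C	0.5896
PRO	O	-0.5748
PRO	CB	-0.0070
PRO	CG	0.0189
PRO	CD	0.0192
SER	N	-0.4157
SER	CA	-0.0249
SER	C	0.5973
SER	O	-0.5679
SER	CB	0.2117
SER	OG	-0.6546
THR	N	-0.4157
THR	CA	-0.0389
THR	C	0.5973
THR	O	-0.5679
THR	CB	0.3654
THR	OG1	-0.6761
THR	CG2	-0.2438
TRP	N	-0.4157
TRP	CA	-0.0275
TRP	C	0.5973
TRP	O	-0.5679
TRP	CB	-0.0050
TRP	CG	-0.1415
TRP	CD1	-0.1638
TRP	CD2	0.1243
TRP	NE1	-0.3418
TRP	CE2	0.1380
TRP	CE3	-0.2387
TRP	CZ2	-0.2601
TRP	CZ3	-0.1972
TRP	CH2	-0.1134
TYR	N	-0.4157
TYR	CA	-0.0014
TYR	C	0.5973
TYR	O	-0.5679
TYR	CB	-0.0152
TYR	CG	-0.0011
TYR	CD1	-0.1906
TYR	CD2	-0.1906
TYR	CE1	-0.2341
TYR	CE2	-0.2341
TYR	CZ	0.3226
TYR	OH	-0.5579
VAL	N	-0.4157
VAL	CA	-0.0875
VAL	C	0.5973
VAL	O	-0.5679
VAL	CB	0.2985
VAL	CG1	-0.3192
VAL	CG2	-0.3192
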