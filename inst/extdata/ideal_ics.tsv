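# chipacker internal-coordinate table v1
resid	atom_name	a	b	c	dtype	bond	angle	dihedral	n_obs
ALA	CB	C	N	CA	fixed	1.5301	110.364	-123.414	24
ARG	CB	C	N	CA	fixed	1.5245	110.905	-123.657	22
ARG	CG	N	CA	CB	chi1	1.5218	113.222	0	22
ARG	CD	CA	CB	CG	chi2	1.5233	111.509	0	22
ARG	NE	CB	CG	CD	chi3	1.4565	113.505	0	22
ARG	CZ	CG	CD	NE	chi4	1.3351	125.617	0	22
ARG	NH1	CD	NE	CZ	fixed	1.3333	121.399	0.225	22
ARG	NH2	CD	NE	CZ	fixed	1.3314	118.847	-179.604	22
ASN	CB	C	N	CA	fixed	1.5368	110.685	-122.11	28
ASN	CG	N	CA	CB	chi1	1.5201	111.661	0	28
ASN	OD1	CA	CB	CG	chi2	1.2391	120.98	0	28
ASN	ND2	CA	CB	CG	chi2	1.3293	116.449	179.899	28
ASP	CB	C	N	CA	fixed	1.5296	110.406	-121.6	14
ASP	CG	N	CA	CB	chi1	1.5085	113.546	0	14
ASP	OD1	CA	CB	CG	chi2	1.2398	122.013	0	14
ASP	OD2	CA	CB	CG	chi2	1.2592	115.571	179.705	14
CYS	CB	C	N	CA	fixed	1.5392	111.73	-123.868	16
CYS	SG	N	CA	CB	chi1	1.8065	113.631	0	16
GLN	CB	C	N	CA	fixed	1.5442	110.78	-123.756	6
GLN	CG	N	CA	CB	chi1	1.5248	111.841	0	6
GLN	CD	CA	CB	CG	chi2	1.5171	111.07	0	6
GLN	OE1	CB	CG	CD	chi3	1.237	119.756	0	6
GLN	NE2	CB	CG	CD	chi3	1.3338	117.07	-178.988	6
GLU	CB	C	N	CA	fixed	1.5306	108.755	-120.75	4
GLU	CG	N	CA	CB	chi1	1.5439	113.724	0	4
GLU	CD	CA	CB	CG	chi2	1.5186	113.004	0	4
GLU	OE1	CB	CG	CD	chi3	1.2405	123.081	0	4
GLU	OE2	CB	CG	CD	chi3	1.2721	114.81	-179.753	4
HIS	CB	C	N	CA	fixed	1.5322	110.38	-126.41	2
HIS	CG	N	CA	CB	chi1	1.5001	113.47	0	2
HIS	ND1	CA	CB	CG	chi2	1.3802	124.439	0	2
HIS	CD2	CA	CB	CG	chi2	1.3688	128.333	-179.446	2
HIS	CE1	CB	CG	ND1	fixed	1.3406	108.217	179.882	2
HIS	NE2	CG	ND1	CE1	fixed	1.3221	108.781	0.482	2
ILE	CB	C	N	CA	fixed	1.5398	110.036	-124.773	12
ILE	CG1	N	CA	CB	chi1	1.5288	111.247	0	12
ILE	CG2	N	CA	CB	chi1	1.5351	110.72	-125.736	12
ILE	CD1	CA	CB	CG1	chi2	1.5214	113.137	0	12
LEU	CB	C	N	CA	fixed	1.5428	110.785	-124.019	15
LEU	CG	N	CA	CB	chi1	1.5312	115.033	0	15
LEU	CD1	CA	CB	CG	chi2	1.522	109.423	0	15
LEU	CD2	CA	CB	CG	chi2	1.522	110.093	121.435	15
LYS	CB	C	N	CA	fixed	1.5308	108.877	-121.106	12
LYS	CG	N	CA	CB	chi1	1.5265	113.043	0	12
LYS	CD	CA	CB	CG	chi2	1.5247	109.816	0	12
LYS	CE	CB	CG	CD	chi3	1.5319	111.416	0	12
LYS	NZ	CG	CD	CE	chi4	1.4871	111.056	0	12
MET	CB	C	N	CA	fixed	1.5322	111.406	-123.668	4
MET	CG	N	CA	CB	chi1	1.5332	109.865	0	4
MET	SD	CA	CB	CG	chi2	1.82	110.927	0	4
MET	CE	CB	CG	SD	chi3	1.7929	99.633	0	4
PHE	CB	C	N	CA	fixed	1.5418	112.039	-122.973	6
PHE	CG	N	CA	CB	chi1	1.5125	114.539	0	6
PHE	CD1	CA	CB	CG	chi2	1.3943	120.192	0	6
PHE	CD2	CA	CB	CG	chi2	1.3904	121.035	-178.75	6
PHE	CE1	CB	CG	CD1	fixed	1.3835	120.949	-179.628	6
PHE	CE2	CB	CG	CD2	fixed	1.4006	121.027	179.425	6
PHE	CZ	CG	CD1	CE1	fixed	1.3913	120.952	-0.255	6
PRO	CB	C	N	CA	fixed	1.5324	104.028	-116.837	4
PRO	CG	N	CA	CB	chi1	1.5043	106.402	0	4
PRO	CD	CA	CB	CG	chi2	1.506	106.961	0	4
SER	CB	C	N	CA	fixed	1.5283	109.068	-121.264	20
SER	OG	N	CA	CB	chi1	1.4226	108.677	0	20
THR	CB	C	N	CA	fixed	1.5352	111.923	-122.354	14
THR	OG1	N	CA	CB	chi1	1.4303	108.824	0	14
THR	CG2	N	CA	CB	chi1	1.522	111.556	-120.835	14
TRP	CB	C	N	CA	fixed	1.548	110.323	-123.653	12
TRP	CG	N	CA	CB	chi1	1.5031	110.803	0	12
TRP	CD1	CA	CB	CG	chi2	1.3625	126.95	0	12
TRP	CD2	CA	CB	CG	chi2	1.4294	126.31	-178.158	12
TRP	NE1	CB	CG	CD1	fixed	1.38	109.915	-178.84	12
TRP	CE2	CB	CG	CD2	fixed	1.4054	107.237	178.453	12
TRP	CE3	CB	CG	CD2	fixed	1.3985	133.33	-1.656	12
TRP	CZ2	CG	CD2	CE2	fixed	1.3997	121.822	179.744	12
TRP	CZ3	CG	CD2	CE3	fixed	1.3902	118.634	-179.471	12
TRP	CH2	CD2	CE2	CZ2	fixed	1.3724	117.343	0.031	12
TYR	CB	C	N	CA	fixed	1.5454	110.816	-120.494	6
TYR	CG	N	CA	CB	chi1	1.5133	111.615	0	6
TYR	CD1	CA	CB	CG	chi2	1.3915	120.378	0	6
TYR	CD2	CA	CB	CG	chi2	1.3958	120.482	-178.36	6
TYR	CE1	CB	CG	CD1	fixed	1.3942	121.504	-178.839	6
TYR	CE2	CB	CG	CD2	fixed	1.3924	120.382	179.452	6
TYR	CZ	CG	CD1	CE1	fixed	1.3874	118.795	-0.778	6
TYR	OH	CD1	CE1	CZ	fixed	1.3725	119.512	-179.359	6
VAL	CB	C	N	CA	fixed	1.5402	110.452	-125.431	12
VAL	CG1	N	CA	CB	chi1	1.532	111.113	0	12
VAL	CG2	N	CA	CB	chi1	1.528	109.772	121.801	12
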