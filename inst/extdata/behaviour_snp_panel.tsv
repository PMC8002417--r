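gene	rsid	allele1	allele2	associated_allele	freq_AFR	freq_AMR	freq_EAS	freq_EUR	freq_TSI	freq_SAS
TPH1	rs1800532	G	T	G	84	63	52	61	62	73
TPH1	rs1799913	G	T	T	16	37	48	39	38	27
TPH2	rs4570625	G	T	T	37	34	55	21	23	28
TPH2	rs6582071	G	A	A	53	36	55	22	23	28
SLC6A4	rs25531	T	C	C	22	5	13	9	7	14
COMT	rs4680	G	A	A	28	38	28	50	45	44
COMT	rs6269	A	G	G	37	31	34	41	49	33
COMT	rs4818	C	G	G	17	30	34	40	47	31
MAOA	rs1346551029	.	.	n.c.						
DRD4	rs761010487	.	.	n.c.						
HTR1B	rs6296	C	G	G	24	40	51	26	22	32
HTR1B	rs130058	T	A	A	3	28	9	34	37	26
HTR1B	rs13212041	C	T	C	56	17	23	19	13	16
HTR2B	rs79874540	G	A	A	0	0	0	0	0	0
HTR2A	rs6313	G	A	G	61	65	41	56	50	58
HTR2A	rs6311	C	T	C	59	64	41	56	50	60
HTR2A	rs7322347	T	A	A	68	40	21	44	51	33
SLC6A3	rs28363170	.	.	n.c.						
BDNF	rs6265	C	T	C	99	85	51	80	76	80
ApoE	rs7412	C	T	T	10	5	10	6	5	4
ApoE	rs429358	T	C	T	73	90	91	84	90	91
NR3C2	rs2070951	G	C	C	16	55	76	49	43	68
MAOA	rs6323	G	T	G	14	29	57	29	27	65
MAOA	rs1137070	T	C	T	36	39	58	29	28	65
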