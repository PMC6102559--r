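probe_id	target_gene	chromosome	arm	region	cytoband	position_mb	target_variant
P1p_S01	TP73	chr1	p	SUBTEL_1P	1p36.32	3.6	NA
P1p_S02	CHD5	chr1	p	SUBTEL_1P	1p36.31	6.1	NA
P1p_S03	CAMTA1	chr1	p	SUBTEL_1P	1p36.31	6.8	NA
P1p_S04	PER3	chr1	p	SUBTEL_1P	1p36.23	7.8	NA
P1p_S05	ERRFI1	chr1	p	SUBTEL_1P	1p36.23	8	NA
P1p_S06	PARK7	chr1	p	SUBTEL_1P	1p36.23	8	NA
P1p_S07	CASZ1	chr1	p	SUBTEL_1P	1p36.22	10.7	NA
P1p_S08	MTHFR	chr1	p	SUBTEL_1P	1p36.22	11.8	NA
P1p_C01	MYCL	chr1	p	PARACEN_1P	1p34.2	39.9	NA
P1p_C02	MUTYH	chr1	p	PARACEN_1P	1p34.1	45.3	NA
P1p_C03	CDKN2C	chr1	p	PARACEN_1P	1p32.3	51.2	NA
P1p_C04	JUN	chr1	p	PARACEN_1P	1p32.1	58.8	NA
P1p_C05	GADD45A	chr1	p	PARACEN_1P	1p31.3	67.7	NA
P1p_C06	FUBP1	chr1	p	PARACEN_1P	1p31.1	77.9	NA
P1p_C07	GSTM1	chr1	p	PARACEN_1P	1p13.3	110.2	NA
P1p_C08	NRAS	chr1	p	PARACEN_1P	1p13.2	114.7	NA
P1p_C09	TRIM33	chr1	p	PARACEN_1P	1p13.2	114.9	NA
P1p_C10	NOTCH2	chr1	p	PARACEN_1P	1p12	120	NA
P1p_C11	AMPD1	chr1	p	PARACEN_1P	1p13.1	114.7	NA
P19q_01	GLTSCR2	chr19	q	Q19	19q13.33	44.8	NA
P19q_02	PLAUR	chr19	q	Q19	19q13.31	43.6	NA
P19q_03	BAX	chr19	q	Q19	19q13.33	48.9	NA
P19q_04	CCNE1	chr19	q	Q19	19q12	29.8	NA
P19q_05	XRCC1	chr19	q	Q19	19q13.31	43.5	NA
P19q_06	ERCC2	chr19	q	Q19	19q13.32	45.3	NA
P19q_07	ERCC1	chr19	q	Q19	19q13.32	45.4	NA
P19q_08	PPP2R1A	chr19	q	Q19	19q13.41	52.2	NA
P19q_09	POLD1	chr19	q	Q19	19q13.33	50.4	NA
P19q_10	PRKCG	chr19	q	Q19	19q13.42	53.9	NA
P19q_11	ZNF331	chr19	q	Q19	19q13.42	53.5	NA
REF_01	REFGENE1	other	none	REFERENCE	NA	NA	NA
REF_02	REFGENE2	other	none	REFERENCE	NA	NA	NA
REF_03	REFGENE3	other	none	REFERENCE	NA	NA	NA
REF_04	REFGENE4	other	none	REFERENCE	NA	NA	NA
REF_05	REFGENE5	other	none	REFERENCE	NA	NA	NA
REF_06	REFGENE6	other	none	REFERENCE	NA	NA	NA
REF_07	REFGENE7	other	none	REFERENCE	NA	NA	NA
REF_08	REFGENE8	other	none	REFERENCE	NA	NA	NA
REF_09	REFGENE9	other	none	REFERENCE	NA	NA	NA
REF_10	REFGENE10	other	none	REFERENCE	NA	NA	NA
MUT_IDH1_R132H	IDH1	other	none	MUTATION	2q34	NA	IDH1 R132H
MUT_IDH2_R172K	IDH2	other	none	MUTATION	15q26.1	NA	IDH2 R172K
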