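species	utr	length	gc_percent	mfe	n_uaug	n_uorf	efficiency	context	cart
Hsap	ApoD_a	361	51.25	-102.2	4	3	O3	O3	I
Hsap	ApoD_b	232	53.88	-87.5	1	1	O1	O1	I
Hsap	ApoD_c	135	47.41	-35.5	2	1	O1	O1	I
Hsap	ApoD_d	190	52.11	-60.8	3	2	O1/W1	O2	I
Hsap	Rbp4_b	322	72.67	-179.5	1	1	W1	O1	I
Hsap	Rbp4_d	72	77.78	-28.7	0	0			III
Hsap	Rbp4_d(2)	113	76.99	-46.4	0	0			I
Hsap	Ptgds_c	72	69.44	-20.5	0	0			III
Hsap	Ptgds_g	458	65.5	-203.8	4	4	O4	O2/W2	I
Hsap	Ptgds_j	1283	65.55	-644.51	11	5	O5	O4/W1	I
Hsap	ApoM_d	496	49.6	-161.77	6	5	O5	O2/W3	I
Hsap	ApoM_e	73	58.9	-17.4	0	0			III
Hsap	C8G_a	75	64	-21.5	0	0			III
Hsap	Obp2A_b	42	69.05	-15.2	0	0			III
Hsap	Orm2_b	189	56.61	-76.5	0	0			I
Hsap	Lcn1_b	154	63.64	-63.4	0	0			I
Hsap	Lcn1_h	49	69.39	-9	0	0			III
Hsap	Lcn2_b	72	67.71	-13	0	0			III
Hsap	Lcn2_b(2)	96	67.71	-25.3	0	0			III
Hsap	Lcn8_e	348	67.82	-166.1	3	3	O3	O1/W2	I
Hsap	Lcn12_c	248	59.27	-99.8	1	1	O1	O1	I
Hsap	Lcn12_c(2)	28	71.43	-8.1	0	0			III
Mmus	ApoD_a	140	50.71	-42	0	0			I
Mmus	ApoD_b	224	49.55	-69.1	1	1	O1	O1	I
Mmus	ApoD_c	358	51.4	-126.94	2	2	O2	O2	I
Mmus	ApoD_d	281	53.74	-103.24	2	2	O2	O2	I
Mmus	ApoD_e	214	59.35	-74.4	2	1	W1	O1	I
Mmus	Rbp4_a	385	62.08	-148.1	4	NA	O4	O3/W1	I
Mmus	Rbp4_c	61	77.05	-18.7	1	1	W1	O1	III
Mmus	Rbp4_d	89	77.53	-37.7	0	0			I
Mmus	Ptgds_c	80	56.25	-20.2	0	0			III
Mmus	Ptgds_d	329	58.36	-149.23	2	2	O2	O1/W1	I
Mmus	ApoM_a	781	48.27	-240.6	14	8	O8	O2/W6	I
Mmus	C8G_b	501	53.69	-188.12	6	6	O6	O1/W4	I
Mmus	C8G_c	275	53.82	-104.22	4	4	O3/W1	O1/W2	I
Mmus	Obp2A_a	53	62.26	-17.5	0	0			III
Mmus	Orm2_a	41	53.66	-3.4	0	0			III
Mmus	Lcn1_a	55	54.55	-18.1	0	0			III
Mmus	Lcn2_b	54	53.7	-7.3	0	0			III
Mmus	Lcn8_a	23	65.22	-3.6	0	0			III
Mmus	Lcn12_a	55	69.09	-30.3	0	0			III
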