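species	utr	utr_length	pas_position	pas_type	efficiency	parenthesized
Hsap	APOD_a,b,c	198	153	C	VE	0
Hsap	APOD_a,b,c	198	68	NC_star	LE	0
Hsap	RBP4_b	388	211	NC	LE	0
Hsap	RBP4_b	388	360	NC	E	0
Hsap	RBP4_b	388	112	NC_star	LE	0
Hsap	RBP4_b	388	130	NC_star	LE	0
Hsap	RBP4_c	186	112	NC_star	LE	0
Hsap	RBP4_c	186	130	NC_star	LE	1
Hsap	PTGDS_c	214	191	C	VE	0
Hsap	PTGDS_g	178	159	C	VE	0
Hsap	PTGDS_j	639	142	C	LE	0
Hsap	PTGDS_j	639	510	NC_star	LE	0
Hsap	PTGDS_j	639	621	NC_star	E	0
Hsap	APOM_d,e	121	97	C	VE	0
Hsap	C8G_a	193	175	NC	E	0
Hsap	OBP2A_b	133	114	C	VE	0
Hsap	ORM2_b	122	94	C	VE	0
Hsap	LCN1_b,h	185	166	NC_star	E	0
Hsap	LCN2_b	153	130	C	VE	0
Hsap	LCN2_b(2)	334	315	C	VE	0
Hsap	LCN8_e	112	95	C	VE	0
Hsap	LCN12_c,c(2)	103	78	C	VE	0
Mmus	Apod_a,b,d	223	203	C	LE	1
Mmus	Apod_c	1149	203	C	LE	0
Mmus	Apod_c	1149	672	NC	LE	0
Mmus	Apod_c	1149	1128	NC	E	0
Mmus	Rbp4_a,d	252	114	NC	LE	0
Mmus	Rbp4_a,d	252	225	NC	E	0
Mmus	Rbp4_c	128	114	NC	LE	1
Mmus	Ptgds_d	159	139	C	VE	0
Mmus	Ptgds_d	159	135	NC_star	E	0
Mmus	Ptgds_e	614	594	C	VE	0
Mmus	Ptgds_e	614	590	NC_star	E	0
Mmus	Apom_a	117	89	C	VE	0
Mmus	C8g_b,c,d	154	136	NC	E	0
Mmus	Obp2A_a	164	145	C	VE	0
Mmus	Orm2_a	113	84	C	VE	0
Mmus	Lcn1_a	164	146	NC_star	E	0
Mmus	Lcn2_b	237	212	C	VE	0
Mmus	Lcn2_b	237	216	NC_star	E	0
Mmus	Lcn8_a	107	85	C	VE	0
Mmus	Lcn12_a	78	55	C	VE	0
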