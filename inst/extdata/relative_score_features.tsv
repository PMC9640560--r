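mutation	category	value	direction	provenance
W33G	SQBT	12	HIGHER_WORSE	reported
W78R	SQBT	12	HIGHER_WORSE	reported
V89E	SQBT	12	HIGHER_WORSE	reported
W150G	SQBT	12	HIGHER_WORSE	reported
L182P	SQBT	12	HIGHER_WORSE	reported
W33G	SRBT	8	HIGHER_WORSE	reported
W78R	SRBT	6	HIGHER_WORSE	reported
V89E	SRBT	7	HIGHER_WORSE	reported
W150G	SRBT	8	HIGHER_WORSE	reported
L182P	SRBT	7	HIGHER_WORSE	reported
W33G	CONSERVATION	32	HIGHER_WORSE	synthetic
W78R	CONSERVATION	28	HIGHER_WORSE	synthetic
V89E	CONSERVATION	28	HIGHER_WORSE	synthetic
W150G	CONSERVATION	23	HIGHER_WORSE	synthetic
L182P	CONSERVATION	24	HIGHER_WORSE	synthetic
W33G	ONCOGENIC	1.806650	HIGHER_WORSE	reported
W78R	ONCOGENIC	1.516118	HIGHER_WORSE	reported
V89E	ONCOGENIC	1.589196	HIGHER_WORSE	reported
W150G	ONCOGENIC	1.588840	HIGHER_WORSE	reported
L182P	ONCOGENIC	1.360604	HIGHER_WORSE	reported
W33G	BPI	900	HIGHER_WORSE	synthetic
W78R	BPI	40	HIGHER_WORSE	synthetic
V89E	BPI	60	HIGHER_WORSE	synthetic
W150G	BPI	850	HIGHER_WORSE	synthetic
L182P	BPI	300	HIGHER_WORSE	synthetic
W33G	AFR_DIST	31	PROXIMITY	reported
W78R	AFR_DIST	8	PROXIMITY	reported
V89E	AFR_DIST	0	PROXIMITY	reported
W150G	AFR_DIST	1	PROXIMITY	reported
L182P	AFR_DIST	0	PROXIMITY	reported
W33G	PTM_DIST	5	PROXIMITY	reported
W78R	PTM_DIST	7	PROXIMITY	synthetic
V89E	PTM_DIST	3	PROXIMITY	reported
W150G	PTM_DIST	8	PROXIMITY	synthetic
L182P	PTM_DIST	2	PROXIMITY	reported
W33G	MDS	154.58	HIGHER_WORSE	reported
W78R	MDS	143.42	HIGHER_WORSE	reported
V89E	MDS	121.32	HIGHER_WORSE	reported
W150G	MDS	109.97	HIGHER_WORSE	reported
L182P	MDS	36.53	HIGHER_WORSE	reported
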