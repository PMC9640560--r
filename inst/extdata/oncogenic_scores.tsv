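rsid	variant	cscape_score	cscape_message	cscape_somatic_score	cscape_somatic_message
rs72552741	W33G	0.898663	Oncogenic (HC)	0.907987	Driver (HC)
rs753277177	W78R	0.695307	Oncogenic	0.820811	Driver
rs1784191846	V89E	0.807748	Oncogenic	0.781448	Driver
rs1447033392	W150G	0.860191	Oncogenic	0.728649	Driver
rs1386533390	L182P	0.519117	Oncogenic	0.841487	Driver
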