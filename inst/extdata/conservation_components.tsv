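variant	consurf_color	msa_count	cdd_count	provenance
W33G	9	10	13	synthetic
W78R	8	10	10	synthetic
V89E	9	10	9	synthetic
W150G	8	10	5	synthetic
L182P	6	10	8	reported
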