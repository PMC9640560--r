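system	vdw_energy	electrostatic_energy	polar_solvation_energy	sasa_energy	binding_energy
WT-SAH	-215.76	-47.82	146.29	-21.48	-138.77
W33G	-0.004	0.00	16.21	-0.40	15.81
W78R	-0.005	0.00	5.13	-0.47	4.65
V89E	-0.005	0.00	-17.84	0.39	-17.45
W150G	-0.005	0.00	-28.27	-0.52	-28.8
L182P	-210.10	-60.55	189.25	-20.84	-102.24
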