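specimen,nominal_species,robusta,nigra,intermedia,unclassified
105,robusta,0.22,0.57,0.52,0.17
133,robusta,0.22,0.65,0.57,0.26
141,robusta,0.26,0.70,0.57,0.13
145,robusta,0.35,0.61,0.39,0.22
152,robusta,0.26,0.61,0.57,0.17
GR1,robusta,0.39,0.65,0.48,0.09
68,nigra,0.35,0.65,0.43,0.13
121,nigra,0.35,0.70,0.52,0.09
132,nigra,0.30,0.70,0.48,0.17
140,nigra,0.35,0.65,0.43,0.22
162,nigra,0.22,0.57,0.57,0.30
100,intermedia,0.22,0.65,0.39,0.22
112,intermedia,0.26,0.65,0.65,0.13
122,intermedia,0.22,0.57,0.43,0.26
125,intermedia,0.35,0.78,0.43,0.09
150,intermedia,0.30,0.26,0.48,0.13
155,intermedia,0.30,0.35,0.39,0.39
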