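species_a	species_b	outgroup	n_sites	time_Ma	K_ac	K_bc	K_ab
Hf	Sc	Cm	3121	203	0.052	0.063	0.027
Le	Sc	Cm	2891	306	0.073	0.068	0.049
Hf	Le	Cm	3128	306	0.054	0.068	0.038
Hs	Gg	Cm	2341	312	0.223	0.203	0.155
Hs	Ac	Cm	2344	312	0.205	0.218	0.183
Hs	Xt	Cm	2748	330	0.212	0.222	0.200
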