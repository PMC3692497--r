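gene	n_sites	delta_logL	se	alpha
PGK1	381	NA	NA	0.35
PPIL5	225	4.93	7.94	1.30
DDX20	171	2.84	2.98	0.67
SNX6	144	2.22	4.89	0.44
AGBL5	157	0.38	6.55	0.43
TSGA2	159	2.40	3.19	0.60
EPRS	142	3.35	3.90	0.43
GAS8	150	1.20	2.72	0.81
RANBP1	119	1.23	2.35	0.38
RNF10	118	0.72	1.44	0.95
MDN1	121	3.42	3.76	0.55
RABL5	108	0.11	4.21	2.05
IWS1	117	NA	NA	1.21
TNRC5	107	1.30	2.09	0.77
MPP10	98	2.19	2.30	0.88
CIAO1	98	1.26	2.04	0.53
CLN5	130	0.60	1.18	0.38
CNOT	126	NA	NA	0.57
SF3A1	171	4.85	6.19	0.17
TRIP12	131	0.63	4.44	0.55
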