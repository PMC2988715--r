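individual	species	sex	subset	a2_percent	n_cones	SWS1	SWS2b	SWS2a	RH2b	RH2a	LWS	lm_SWS1	lm_SWS2b	lm_SWS2a	lm_RH2b	lm_RH2a	lm_LWS	r2_SWS1	r2_SWS2b	r2_SWS2a	r2_RH2b	r2_RH2a	r2_LWS	limb1_pigment	limb1_r2	limb2_pigment	limb2_r2
ZF7	M. zebra	Female	1	37.6	4	1	1	0	1	1	0	381	427	NA	491	535	NA	0.62	0.63	NA	0.76	0.90	NA	RH2a	0.98	LWS	0.47
ZF6	M. zebra	Female	1	37.6	4	1	1	0	1	1	0	381	427	NA	491	535	NA	0.46	0.82	NA	0.70	0.90	NA	RH2a	0.98	LWS	0.21
ZF8	M. zebra	Female	1	53.8	4	1	1	0	1	1	0	383	428	NA	494	540	NA	0.88	0.55	NA	0.73	0.87	NA	RH2a	0.94	LWS	0.59
ZF1	M. zebra	Female	2	48.4	4	1	0	1	1	1	0	383	NA	461	493	540	NA	0.09	NA	0.96	0.72	0.85	NA	RH2a	0.95	LWS	0.58
ZF4	M. zebra	Female	2	21.5	4	1	0	1	1	1	0	379	NA	459	487	530	NA	0.91	NA	0.30	0.69	0.94	NA	RH2a	0.93	LWS	0.01
ZF2	M. zebra	Female	2	48.4	4	1	0	1	1	1	0	375	NA	461	493	540	NA	0.53	NA	0.98	0.38	0.96	NA	RH2a	0.95	LWS	0.56
ZM2	M. zebra	Male	2	8	4	1	0	1	1	1	0	375	NA	457	484	526	NA	0.85	NA	0.76	0.85	0.91	NA	RH2a	0.89	LWS	0.49
ZM6	M. zebra	Male	2	18.8	4	1	0	1	1	1	0	378	NA	458	487	530	NA	0.75	NA	0.57	0.81	0.95	NA	RH2a	0.97	LWS	-0.18
ZM4	M. zebra	Male	2	53.7	4	1	0	1	1	1	0	383	NA	463	494	540	NA	0.15	NA	0.64	0.54	0.91	NA	RH2a	0.99	LWS	0.62
ZM1	M. zebra	Male	2	59.1	4	1	0	1	1	1	0	385	NA	463	495	544	NA	0.55	NA	0.99	0.93	0.55	NA	RH2a	0.91	LWS	0.64
ZM3	M. zebra	Male	2	18.8	4	1	0	1	1	1	0	378	NA	458	487	530	NA	0.69	NA	0.18	0.91	0.79	NA	RH2a	0.91	LWS	-0.69
AF13	M. auratus	Female	3	0	5	1	1	0	1	1	1	374	424	NA	485	525	561	0.84	0.70	NA	0.82	0.72	0.87	LWS	0.85	NA	NA
AF15	M. auratus	Female	3	0	5	1	1	0	1	1	1	374	424	NA	485	525	561	0.25	0.75	NA	0.43	0.14	0.82	LWS	0.85	NA	NA
AF14	M. auratus	Female	4	53.7	4	1	0	1	1	1	0	380	NA	463	494	543	NA	0.76	NA	0.33	0.81	0.71	NA	RH2a	0.91	LWS	0.24
AF11	M. auratus	Female	5	64.5	3	0	1	0	1	1	0	NA	429	NA	497	547	NA	NA	0.47	NA	0.63	0.91	NA	RH2a	0.94	LWS	0.84
AM14	M. auratus	Male	3	0	5	1	1	0	1	1	1	374	424	NA	485	525	561	0.71	0.96	NA	0.41	0.70	0.85	LWS	0.96	NA	NA
AM13	M. auratus	Male	3	0	5	1	1	0	1	1	1	374	424	NA	485	525	561	0.67	0.60	NA	0.73	0.74	0.85	LWS	0.85	NA	NA
AM12	M. auratus	Male	6	0	5	1	0	1	1	1	1	374	NA	457	485	525	561	0.54	NA	0.85	0.41	0.27	0.98	LWS	0.98	NA	NA
AM11	M. auratus	Male	7	3	5	0	1	1	1	1	1	NA	424	457	485	526	562	NA	0.32	0.09	0.85	0.43	0.57	LWS	0.89	NA	NA
AM16	M. auratus	Male	8	0	4	0	1	0	1	1	1	NA	424	NA	485	525	561	NA	0.56	NA	0.41	0.47	0.70	LWS	0.84	NA	NA
AM17	M. auratus	Male	8	0	4	0	1	0	1	1	1	NA	424	NA	485	525	561	NA	0.97	NA	0.70	0.29	0.88	LWS	0.96	NA	NA
AM18	M. auratus	Male	9	0	4	0	0	1	1	1	1	NA	NA	457	485	525	561	NA	NA	0.52	0.33	0.46	0.87	LWS	0.87	NA	NA
TF6	P. taeniolatus	Female	7	18.1	5	0	1	1	1	1	1	NA	428	457	491	533	576	NA	0.49	0.89	0.75	0.55	0.95	LWS	0.86	NA	NA
TF2	P. taeniolatus	Female	7	10.6	5	0	1	1	1	1	1	NA	428	457	487	528	571	NA	0.66	0.98	0.84	0.55	0.43	LWS	0.63	NA	NA
TF1	P. taeniolatus	Female	10	15.1	4	0	1	1	1	0	1	NA	428	457	NA	NA	571	NA	0.49	0.97	NA	NA	0.91	LWS	0.98	RH2a	0.82
TF4	P. taeniolatus	Female	11	10.6	4	0	1	1	0	1	1	NA	428	457	NA	529	571	NA	0.48	0.54	NA	0.88	0.72	LWS	0.91	NA	NA
TF7	P. taeniolatus	Female	6	6	5	1	0	1	1	1	1	379	NA	457	487	529	563	0.81	NA	0.47	0.63	0.54	0.73	LWS	0.93	NA	NA
TM1	P. taeniolatus	Male	7	18.6	5	0	1	1	1	1	1	NA	428	457	491	533	576	NA	0.68	0.64	0.59	0.52	0.88	LWS	0.96	NA	NA
TM3	P. taeniolatus	Male	7	15	5	0	1	1	1	1	1	NA	428	457	494	529	571	NA	0.71	0.08	0.89	0.59	0.98	LWS	0.95	NA	NA
TM8	P. taeniolatus	Male	7	22.6	5	0	1	1	1	1	1	NA	428	457	491	534	576	NA	0.59	0.94	0.90	0.49	0.80	LWS	0.95	NA	NA
TM4	P. taeniolatus	Male	9	3	4	0	1	1	1	0	1	NA	428	457	486	NA	563	NA	0.64	0.91	0.84	NA	0.98	LWS	0.98	RH2a	0.96
TM6	P. taeniolatus	Male	9	10.7	4	0	1	1	1	0	1	NA	428	457	487	NA	571	NA	0.42	0.45	0.74	NA	0.94	LWS	0.97	RH2a	0.87
TM5	P. taeniolatus	Male	6	3	5	1	0	1	1	1	1	379	NA	457	486	529	563	0.78	NA	0.84	0.50	0.57	0.91	LWS	0.97	NA	NA
TM2	P. taeniolatus	Male	6	18.1	5	1	0	1	1	1	1	380	NA	457	491	533	576	0.95	NA	0.99	0.67	0.87	0.99	LWS	0.99	NA	NA
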