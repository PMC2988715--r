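subset	species	n_individuals	n_cones	SWS1	SWS2b	SWS2a	RH2b	RH2a	LWS	lm_SWS1	lm_SWS2b	lm_SWS2a	lm_RH2b	lm_RH2a	lm_LWS
1	M. zebra	3	4	1	1	0	1	1	0	382	427	NA	492	537	NA
2	M. zebra	8	4	1	0	1	1	1	0	380	NA	460	490	535	NA
3	M. auratus	4	5	1	1	0	1	1	1	374	424	NA	485	525	561
4	M. auratus	1	4	1	0	1	1	1	0	380	NA	463	494	543	NA
5	M. auratus	1	3	0	1	0	1	1	0	NA	429	NA	497	547	NA
6	M. auratus	1	5	1	0	1	1	1	1	374	NA	457	485	525	561
7	M. auratus	1	5	0	1	1	1	1	1	NA	424	457	485	526	562
8	M. auratus	2	4	0	1	0	1	1	1	NA	424	NA	485	525	561
9	M. auratus	1	4	0	0	1	1	1	1	NA	NA	457	485	525	561
6	P. taeniolatus	3	5	1	0	1	1	1	1	379	NA	457	488	530	567
7	P. taeniolatus	5	5	0	1	1	1	1	1	NA	428	457	489	532	574
9	P. taeniolatus	2	4	0	1	1	1	0	1	NA	428	457	487	NA	567
10	P. taeniolatus	1	4	0	1	1	1	0	1	NA	428	457	494	NA	571
11	P. taeniolatus	1	4	0	1	1	0	1	1	NA	428	457	NA	529	571
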