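subset	n_cones	species	sex	frequency
1	4	M. zebra	Female	50.0
2	4	M. zebra	Female	50.0
2	4	M. zebra	Male	100.0
3	5	M. auratus	Female	50.0
3	5	M. auratus	Male	28.6
4	4	M. auratus	Female	25.0
5	3	M. auratus	Female	25.0
6	5	M. auratus	Male	14.3
6	5	P. taeniolatus	Female	20.0
6	5	P. taeniolatus	Male	28.6
7	5	M. auratus	Male	14.3
7	5	P. taeniolatus	Female	40.0
7	5	P. taeniolatus	Male	42.9
8	4	M. auratus	Male	28.6
9	4	M. auratus	Male	14.3
9	4	P. taeniolatus	Male	28.6
10	4	P. taeniolatus	Female	20.0
11	4	P. taeniolatus	Female	20.0
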