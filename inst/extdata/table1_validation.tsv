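gene	conc_mean_case	conc_sd_case	conc_mean_control	conc_sd_control	log2fc_printed	p_adj
IGFALS	0.073	0.280	0.551	0.432	-2.92	7.73e-08
ORM1	30.09	11.57	43.00	15.04	-0.52	5.49e-05
AHSG	89.66	33.12	25.43	6.490	1.82	1.14e-11
PLG	57.34	19.09	15.31	2.701	1.91	6.62e-13
SERPINF1	1.741	1.210	0.433	0.440	2.00	2.34e-06
ITIH4	39.25	9.18	8.218	1.561	2.25	7.12e-18
C8A	1.712	1.740	0.354	0.412	2.27	2.16e-04
A1BG	47.03	15.92	9.244	2.273	2.35	1.00e-13
SERPINF2	9.644	3.594	1.799	0.951	2.42	5.12e-13
SERPIND1	9.222	3.441	1.675	1.082	2.46	2.66e-13
SERPINA1	649.1	178.9	113.3	26.83	2.52	2.23e-16
GC	136.7	32.65	22.95	4.917	2.58	3.53e-18
CP	89.32	22.87	14.44	2.684	2.63	2.33e-17
GSN	13.00	3.662	1.880	0.584	2.79	1.40e-16
APOB	158.1	55.38	21.74	7.380	2.86	4.05e-14
VTN	25.07	9.713	3.420	1.205	2.87	5.03e-13
APOH	60.40	18.59	7.243	3.247	3.06	6.73e-16
ITIH1	36.43	12.07	3.846	1.121	3.24	4.29e-15
APOC3	33.12	18.69	2.639	2.424	3.65	7.49e-10
IGKV3-20	4.325	3.833	0.007	0.050	9.23	9.74e-07
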