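gene	conc_mean_case	conc_sd_case	conc_mean_control	conc_sd_control	log2fc_printed	p_adj
GPX3	0.21	1.10	0.18	0.90	0.22	0.12
IGKC	0.35	1.60	0.41	1.50	-0.23	0.07
C2	0.09	0.60	0.12	0.55	-0.42	0.31
ATRN	0.05	0.40	0.07	0.35	-0.49	0.44
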