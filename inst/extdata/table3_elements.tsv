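element_id	layer	mapped_gene
GPX3	proteome
PLG	proteome
VTN	proteome
SERPINF1	proteome
APOB	proteome
APOH	proteome
APOC3	proteome
rs8046	gwas	PTGS1
rs10306166	gwas	PTGS1
rs118125840	gwas	GABBR2
rs10908703	gwas	FCER1A
rs2299542	gwas	GRM8
rs2179158	gwas	TNR
rs60428975	gwas	SMAD3
rs61941687	gwas	SCARB1
rs11254275	gwas	CUBN
C00547	metabolome
C00780	metabolome
C03758	metabolome
C00319	metabolome
C01060	metabolome
C00280	metabolome
C00468	metabolome
C04555	metabolome
C05443	metabolome
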