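hsa00590	Arachidonic acid metabolism	GPX3	PTGS1
hsa04024	cAMP signaling pathway	GABBR2	C00547	C00780	C03758
hsa04071	Sphingolipid signaling pathway	FCER1A	C00319
hsa04080	Neuroactive ligand-receptor interaction	PLG	GRM8	GABBR2	C00547	C00780	C03758
hsa04151	PI3K-Akt signaling pathway	VTN	TNR
hsa04310	Wnt signaling pathway	SERPINF1	SMAD3
hsa04510	Focal adhesion	VTN	TNR
hsa04512	ECM-receptor interaction	VTN	TNR
hsa04726	Serotonergic synapse	PTGS1	C00780
hsa04913	Ovarian steroidogenesis	SCARB1	C00280	C00468
hsa04915	Estrogen signaling pathway	GABBR2	SCARB1
hsa04918	Thyroid hormone synthesis	GPX3	C01060
hsa04923	Regulation of lipolysis in adipocytes	PTGS1	C00547
hsa04975	Fat digestion and absorption	APOB	SCARB1
hsa04976	Bile secretion	SCARB1	C00780	C03758	C04555
hsa04977	Vitamin digestion and absorption	APOB	CUBN	SCARB1	C05443
hsa04979	Cholesterol metabolism	APOH	APOB	APOC3	SCARB1
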