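REACTOME_RECYCLING_OF_BILE_ACIDS_AND_SALTS	Reactome	SLC10A1	SLC27A5	SLCO1A2
REACTOME_TRANSPORT_OF_ORGANIC_ANIONS	Reactome	SLCO1A2	SLCO3A1	SLCO4A1	SLCO4C1
REACTOME_TGF_BETA_RECEPTOR_SIGNALING_IN_EMT	Reactome	ARHGEF18	CGN	F11R	FKBP1A	PARD3	PARD6A	PRKCZ	RHOA	RPS27A	SMURF1	TGFB1	TGFBR1	TGFBR2	UBA52
BIOCARTA_CELL2CELL_PATHWAY	Biocarta	ACTN1	CSK	CTNNA1	CTNNB1	PECAM1	PTK2	PXN	VCL
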