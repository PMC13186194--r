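EPITHELIAL_MARKERS	Curated epithelial junction/polarity markers (package default)	CDH1	EPCAM	KRT8	KRT18	KRT19	CLDN3	CLDN4	CLDN7	OCLN	TJP1	DSP	CRB3	ESRP1	ESRP2	GRHL2	JUP	PKP3	RAB25	CDH3	MARVELD3
MESENCHYMAL_MARKERS	Curated mesenchymal motility/EMT-TF markers (package default)	VIM	FN1	CDH2	ZEB1	ZEB2	SNAI1	SNAI2	TWIST1	TWIST2	MMP2	MMP9	CXCR4	FOXC2	PRRX1	SPARC	COL1A1	COL5A2	TNC	ITGB6	WNT5A
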