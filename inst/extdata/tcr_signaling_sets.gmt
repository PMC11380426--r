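TCR_signaling	package default	CD3D	CD3E	CD3G	CD247	LCK	FYN	ZAP70	LAT
Downstream_TCR_signaling	package default	NFKB1	NFATC2	RELA	MAP3K8	CARD11	BCL10	MALT1	PRKCQ
pCD3_and_TCRZ	package default	CD3D	CD3E	CD3G	CD247	LCK	PTPRC
Second_messenger	package default	LAT	LCP2	PLCG1	ITK	VAV1	GRB2	SOS1
TCRa_pathway	package default	CD3E	CD28	PTPRC	ZAP70	LCK	CSK
ZAP70_to_immunosynapse	package default	ZAP70	CD3D	CD3E	CD3G	CD247	FYN
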