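epithelial	illustrative epithelial markers (synthetic demo set, not a curated signature)	CDH1	EPCAM	KRT5	KRT14	DSP	CLDN4	OCLN	TJP1
mesenchymal	illustrative mesenchymal markers (synthetic demo set, not a curated signature)	VIM	FN1	CDH2	SNAI1	SNAI2	TWIST1	ZEB1	FBN1
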