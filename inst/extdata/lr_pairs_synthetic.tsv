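ligand	receptor	annotation
TGFB1	TGFBR1	synthetic demo pair
TGFB1	TGFBR2	synthetic demo pair
FN1	ITGB1	synthetic demo pair
FN1	ITGA5	synthetic demo pair
COL1A1	ITGB1	synthetic demo pair
LAMB1	ITGB4	synthetic demo pair
B2M	HLA-A	synthetic demo pair
THBS1	CD47	synthetic demo pair
VEGFA	FLT1	synthetic demo pair
EGF	EGFR	synthetic demo pair
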