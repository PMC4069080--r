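module	gene_id	dc	bc
M9	IL4	5	0.5329
M9	MS4A2	3	0.4395
M9	CCR3	5	0.3297
M9	IL8	5	0.3021
M9	FCER1A	3	0.2637
M9	NAMPT	2	0.1429
M9	GAB2	2	0.1429
M9	CCR2	3	0.0549
M9	CCL3L1	2	0.0110
M9	RGS18	1	0.0000
M9	POLE	2	0.0000
M12	CDK1	57	0.1717
M12	TSPO	55	0.2436
M12	BIRC5	53	0.0432
M12	CDC45	51	0.0138
M12	KIAA0101	50	0.0515
M12	TOP2A	50	0.0156
M12	CCNA2	50	0.0036
M12	TK1	49	0.0246
M12	CDT1	49	0.0156
M12	DLGAP5	49	0.0103
M12	RPS3	11	0.0905
M12	TYROBP	35	0.0836
M12	CD4	36	0.0738
M12	MNDA	20	0.0472
M12	MAPK1	25	0.0455
M12	ITGAM	34	0.0425
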