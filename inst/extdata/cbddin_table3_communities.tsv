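community	mod_classes	n	pct_confirmed	pct_explained	pct_not_explained
I	LB,VM	80	77	19	4
II	VM,GB,G,DB,LB,M	271	80	8	12
III	DB,M,LB,GB	307	84	12	4
IV	M,GB,G,DB	81	51	22	27
V	GB	54	33	63	4
VI	GB,G,LB,M,P	125	35	38	27
VII	LB	58	26	31	43
VIII	P,G,LB,GB	69	56	9	35
IX	G,LB	96	30	57	13
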