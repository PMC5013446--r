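color	code	interpretation	n_drugs	consistency
Dark blue	DB	Central and peripheral nervous system acting drugs	232	96
Velvet maroon	VM	Substrates, inhibitors and inducers of specific CYP enzymes	210	91
Green	G	Drugs that interfere in different phases of hemostasis, anticonvulsant and epileptogenic drugs	191	85
Magenta	M	Drugs acting on sympathetic nervous system	166	93
Light blue	LB	Drugs targeting cancer, auto-immune disorders and musculoskeletal system	156	88
Golden brown	GB	Drugs interfering with platelet activity and plasma potassium levels	155	92
Purple	P	Bi- and trivalent cations, chelating agents	31	100
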