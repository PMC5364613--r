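population	system	class	fraction
PJL	mtDNA	SouthAsian	0.72
PJL	mtDNA	WestEurasian	0.25
PJL	mtDNA	EastEurasian	0.03
PJL	Y	SouthAsian	0.18
PJL	Y	WestEurasian	0.80
PJL	Y	EastEurasian	0.02
PJL	autosomal	SouthAsian	0.52
PJL	autosomal	WestEurasian	0.45
PJL	autosomal	EastEurasian	0.03
BEB	mtDNA	SouthAsian	0.86
BEB	mtDNA	WestEurasian	0.06
BEB	mtDNA	EastEurasian	0.08
BEB	Y	SouthAsian	0.38
BEB	Y	WestEurasian	0.50
BEB	Y	EastEurasian	0.12
BEB	autosomal	SouthAsian	0.62
BEB	autosomal	WestEurasian	0.28
BEB	autosomal	EastEurasian	0.10
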