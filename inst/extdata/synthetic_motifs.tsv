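name	parent	mutations
L3	root	
N	L3	G8701A C9540T G10398A C10873T A15301G
R	N	T12705C T16304C
M	L3	T489C C10400T T14783C G15043A
M2	M	A447G C1780T G8502A
M2a	M2	T204C G207A T485C
R5	R	G709A A5153G
R30	R	C2836T T4216C
N1	N	G1719A A5315G
U	R	A11467G G12308A A12372G
U2	U	A11467G! T152C A508G
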