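sample_id	population	region
s1	PJL	west
s2	PJL	west
s3	GIH	west
s4	ITU	south
s5	ITU	south
s6	STU	south
s7	BEB	east
s8	BEB	east
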