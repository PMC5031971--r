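library	pcr	A	C	T	G
A	solution	25.48	23.18	24.72	26.63
A	ddpcr	23.86	24.67	22.75	28.72
B	solution	22.50	22.60	28.10	26.80
B	ddpcr	19.90	24.40	24.50	31.20
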