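experiment	round	A	C	T	G
solution	initial	22.50	22.60	28.10	26.80
solution	R1	21.00	23.30	29.00	26.80
solution	R3	18.40	24.30	32.90	24.30
solution	R5	15.20	24.30	37.40	23.10
solution	R6	14.40	23.90	39.40	22.30
solution	R7	14.00	23.00	41.10	22.00
ddpcr	initial	19.90	24.40	24.50	31.20
ddpcr	R1	19.20	24.40	24.10	32.20
ddpcr	R3	17.90	25.00	25.20	31.90
ddpcr	R5	16.00	24.50	26.20	33.30
ddpcr	R6	15.80	25.00	26.20	32.90
ddpcr	R7	15.50	24.80	26.20	34.00
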