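experiment	round	total_reads	usable_reads	top1000_reads
initial_A_solution	initial	28942595	27411096	5984
initial_A_ddpcr	initial	27863589	26104315	6596
initial_B_solution	initial	40174712	37951292	3169
initial_B_ddpcr	initial	55173334	51997175	3233
ccr7_solution	initial	40174712	37951292	3169
ccr7_solution	R1	48630975	45170934	3099
ccr7_solution	R3	57383383	54654814	5797
ccr7_solution	R5	49925077	45474572	226559
ccr7_solution	R6	57778216	51503799	564840
ccr7_solution	R7	51453049	44593424	771042
cd2_solution	initial	40174712	37951292	3169
cd2_solution	R3	15346437	13682508	326175
cd2_solution	R5	16615193	14585023	6766517
cd2_solution	R6	18644363	16629267	9237787
cd2_solution	R7	21236560	19596020	16182954
ccr7_ddpcr	initial	55173334	51997175	3233
ccr7_ddpcr	R1	82184658	77008260	3361
ccr7_ddpcr	R3	51861247	47716752	3321
ccr7_ddpcr	R5	46379471	42668515	7248
ccr7_ddpcr	R6	48268204	44167084	15328
ccr7_ddpcr	R7	51124263	46564753	35612
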