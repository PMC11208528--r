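##fileformat=VCFv4.2
##INFO=<ID=R2,Number=1,Type=Float,Description="Imputation quality">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S0001	S0002	S0003	S0004
1	10000	rs1	A	G	.	PASS	R2=0.95	GT:DS	0/0:0.1	0/1:0.9	1/1:2.0	0/1:1.1
1	20000	rs2	C	T	.	PASS	R2=0.80	GT:DS	0/1:1.0	./.:1.2	0/0:0.0	1/1:1.8
2	15000	rs3	G	A	.	PASS	.	GT:DS	1/1:2.0	0/0:0.2	0/1:0.8	0/0:0.1
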