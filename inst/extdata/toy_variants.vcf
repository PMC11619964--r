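##fileformat=VCFv4.2
##INFO=<ID=CSQ,Number=.,Type=String,Description="Consequence annotations from VEP. Format: Allele|Consequence|SYMBOL|CANONICAL|AF">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2
1	1000	.	A	AT	60	PASS	CSQ=AT|frameshift_variant|GENE1|YES|0.001	GT	0/1	0/0
1	2000	.	G	T	60	PASS	CSQ=T|stop_gained|GENE2|YES|	GT	0/1	0/0
2	3000	.	C	A	60	PASS	CSQ=A|splice_donor_variant|GENE3|YES|0.005	GT	0/0	1/1
2	4000	.	T	C	60	PASS	CSQ=C|missense_variant|GENE4||0.001	GT	0/1	0/0
3	5000	.	G	C	60	PASS	CSQ=C|stop_lost||YES|0.001	GT	0/1	0/0
3	6000	.	A	G	60	PASS	CSQ=G|frameshift_variant|GENE6|YES|0.02	GT	0/1	0/0
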