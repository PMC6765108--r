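##fileformat=VCFv4.2
##contig=<ID=chrIII,length=340000>
##contig=<ID=chrV,length=560000>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	toy
chrIII	200100	.	C	T	.	PASS	.	GT:DP:AD	0/1:100:52,48
chrIII	201500	.	C	T	.	PASS	.	GT:DP:AD	0/1:96:50,46
chrIII	203000	.	C	G	.	PASS	.	GT:DP:AD	0/1:110:58,52
chrV	120000	.	G	A	.	PASS	.	GT:DP:AD	1/1:98:3,95
chrV	240000	.	CT	C	.	PASS	.	GT:DP:AD	0/1:90:47,43
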