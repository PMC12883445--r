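##fileformat=VCFv4.2
##contig=<ID=chrX>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	TOY1
chrX	2781478	.	A	G	50	PASS	.	GT:AD:DP:GQ	0/1:15,15:30:99
chrX	2781479	.	C	T	50	PASS	.	GT:AD:DP:GQ	0/1:15,15:30:99
chrX	3000000	.	G	A	50	PASS	.	GT:AD:DP:GQ	0/1:15,5:30:99
chrX	3000100	.	G	C	50	PASS	.	GT:AD:DP:GQ	0/1:14,6:20:99
chrX	3000200	.	T	C	50	PASS	.	GT:AD:DP:GQ	0/1:15,6:21:99
chrX	3100000	.	A	T	50	PASS	.	GT:AD:DP:GQ	1/1:0,30:30:99
chrX	3200000	.	C	G	50	PASS	.	GT:AD:DP:GQ	0/0:30,0:30:99
chrX	3300000	.	G	T	50	PASS	.	GT:AD:DP:GQ	./.:.:.:.
chrX	3400000	.	A	C	50	PASS	.	GT:AD:DP:GQ	./1:10,10:20:99
chrX	3500000	.	C	A,T	50	PASS	.	GT:AD:DP:GQ	1|2:2,14,14:30:99
chrX	153925834	.	G	A	50	PASS	.	GT:AD:DP:GQ	1/1:1,29:30:99
chrX	153925835	.	A	G	50	PASS	.	GT:AD:DP:GQ	0/1:15,15:30:99
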