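##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s1	s2
chr1	101	snp1	A	T	.	PASS	.	GT:AD	0/0:6,0	0/1:3,4
chr1	202	snp2	G	A,T	.	PASS	.	GT:AD	0/1:2,3	1/1:0,5
chr2	303	snp3	C	G	.	PASS	.	GT:AD	./.:0,0	1/1:0,7
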