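##fileformat=VCFv4.2
##source=trianet synthetic toy fixture (hand-written, not real data)
##contig=<ID=chr1>
##contig=<ID=chr2>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s1	s2	s3	s4	s5	s6
chr1	101	rs1	A	G	.	PASS	.	GT	0/0	0/1	1/1	0/0	0/1	1/1
chr1	250	rs2	C	T	.	PASS	.	GT	0/1	0/1	0/0	1/1	0/0	0/1
chr1	333	rs3	G	A	.	PASS	.	GT	./.	0/1	0/0	0/1	1/1	0/0
chr1	410	rs4	T	C	.	PASS	.	GT	0|0	0|1	1|1	0|1	0|0	0|1
chr1	500	rs5	A	C,T	.	PASS	.	GT	0/1	0/2	1/2	0/0	0/1	0/0
chr1	620	rs6	AT	A	.	PASS	.	GT	0/0	0/1	0/0	0/1	1/1	0/0
chr2	75	.	G	C	.	PASS	.	GT	1/1	0/1	0/0	0/1	0/1	0/0
chr2	180	rs8	C	G	.	PASS	.	GT	0/0	0/0	0/1	.|.	0/1	1/1
chr2	240	rs9	T	A	.	PASS	.	GT	0/1	1/1	0/0	0/1	0/0	0/1
chr2	300	rs10	A	T	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/0	0/1
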