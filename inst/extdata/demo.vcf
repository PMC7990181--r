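##fileformat=VCFv4.2
##INFO=<ID=END,Number=1,Type=Integer,Description="End position of the variant described in this record">
##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">
##FORMAT=<ID=VAF,Number=1,Type=Float,Description="Variant allele fraction">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S0001
chr1	2993	.	T	G	.	PASS	.	VAF	0.1079314957
chr1	2985	.	C	G	.	PASS	.	VAF	0.2415987718
chr1	1240	.	T	C	.	PASS	.	VAF	0.2016170868
chr1	2604	.	T	G	.	PASS	.	VAF	0.4071439663
chr1	968	.	C	G	.	PASS	.	VAF	0.2428537014
chr1	2010	.	C	T	.	PASS	.	VAF	0.5735069387
chr1	1344	.	N	<DUP>	.	PASS	END=1612;SVTYPE=DUP	VAF	0.4586037687
chr1	2356	.	A	A[chr1:379[	.	PASS	SVTYPE=BND	VAF	0.1027267119
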