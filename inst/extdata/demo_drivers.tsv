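chrom	start	end	name
chr1	2294	2493	DRV01
chr1	1909	2108	DRV02
chr1	358	557	DRV03
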