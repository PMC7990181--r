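#kind	age=continuous	status=binary	stage=categorical
sample	age	status	stage
S0001	56.7922298771216	tumor-free	ii
S0002	55.0113834945636	with-tumor	ii
S0003	74.149817462976	tumor-free	i
S0004	54.2538956883314	with-tumor	i
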