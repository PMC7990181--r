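sample	os_time	os_event	dfs_time	dfs_event
S0001	46.3288004714996	0	45.4487211825326	0
S0002	82.6564985951409	0	86.9976305002347	0
S0003	22.0085220560431	0	19.6534774973989	0
S0004	71.5059726499021	0	26.4622369604185	0
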