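# Known protein-binding sites of S. cerevisiae RNase P RNA (RNase footprinting)
molecule_id	start	end	label
rnasep	13	28	Pop1/6/7
rnasep	31	42	Pop1/6/7
rnasep	62	89	Pop1/6/7
rnasep	151	152	Pop1
rnasep	155	159	Pop1
rnasep	170	170	Pop1
rnasep	172	172	Pop1
rnasep	183	184	Pop1
rnasep	186	189	Pop1
rnasep	194	209	Pop1
rnasep	213	215	Pop1
rnasep	237	239	Pop1
rnasep	253	266	Pop1
rnasep	298	307	Pop1
rnasep	311	313	Pop1
rnasep	323	325	Pop1
rnasep	341	353	Pop1
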