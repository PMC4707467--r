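# Published predictor hit positions for S. cerevisiae RNase P RNA
molecule_id	start	end	label
rnasep	14	14	hit
rnasep	23	23	hit
rnasep	31	31	hit
rnasep	151	151	hit
rnasep	159	159	hit
rnasep	170	170	hit
rnasep	172	172	hit
rnasep	186	186	hit
rnasep	196	196	hit
rnasep	266	266	hit
rnasep	304	304	hit
rnasep	313	313	hit
rnasep	323	323	hit
rnasep	344	344	hit
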