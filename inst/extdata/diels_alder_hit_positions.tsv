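# Published predictor hit positions for the Diels-Alder ribozyme
molecule_id	start	end	label
diels-alder	1	1	hit
diels-alder	23	23	hit
diels-alder	42	42	hit
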