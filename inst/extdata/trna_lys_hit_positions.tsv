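# Published predictor hit positions for tRNA(Lys); 75 and 76 merge into one site
molecule_id	start	end	label
tRNA-Lys	1	1	hit
tRNA-Lys	18	18	hit
tRNA-Lys	35	35	hit
tRNA-Lys	49	49	hit
tRNA-Lys	58	58	hit
tRNA-Lys	75	75	hit
tRNA-Lys	76	76	hit
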