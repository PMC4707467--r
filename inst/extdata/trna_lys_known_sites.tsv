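# Known functional sites of tRNA(Lys), curated from the literature (76 nt)
molecule_id	start	end	label
tRNA-Lys	1	4	acceptor_stem_5p
tRNA-Lys	13	22	DHU_loop
tRNA-Lys	34	36	anticodon
tRNA-Lys	49	51	TpsiC_stem
tRNA-Lys	53	61	TpsiC_loop
tRNA-Lys	63	65	TpsiC_stem_3p
tRNA-Lys	72	76	aminoacylation_3p
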