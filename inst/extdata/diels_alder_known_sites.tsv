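# Known functional sites (catalytic pocket) of the Diels-Alder ribozyme
molecule_id	start	end	label
diels-alder	1	4	catalytic_pocket
diels-alder	23	25	catalytic_pocket
diels-alder	42	45	catalytic_pocket
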