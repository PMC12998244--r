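lion_id	n_bouts_manual	n_bouts_automatic	n_roars_manual	n_roars_automatic
A9	16	15	61	66
A10	12	12	26	43
A11	9	7	18	29
A4	13	4	30	5
A8	11	11	20	36
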