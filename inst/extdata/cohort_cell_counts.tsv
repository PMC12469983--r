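patient	t_cells_with_tcr
CEL_01	3489
CEL_02	2062
CEL_03	2150
CEL_04	2534
CEL_05	1573
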