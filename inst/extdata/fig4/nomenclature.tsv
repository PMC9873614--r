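cell_set_accession	cell_set_preferred_alias	cell_set_aligned_alias	cell_set_additional_aliases	cell_set_class_flag
CS100	all cells			true
CS101	L5 ET		L5 PT	false
CS102	Lamp5			false
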