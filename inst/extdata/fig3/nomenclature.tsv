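cell_set_accession	cell_set_preferred_alias	cell_set_aligned_alias	cell_set_additional_aliases	cell_set_class_flag
CS001	i1			true
CS002	i2			true
CS003	i3			true
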