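cell_set_accession	parent_class_ids	morphology_term	projection_term	classical_marker_genes	extra_synonyms	exclude
CS100						true
CS101	FIX:0000002	FIX:0000010	FIX:0000011		L5 Extratelencephalic (ET)	false
CS102	FIX:0000003					false
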