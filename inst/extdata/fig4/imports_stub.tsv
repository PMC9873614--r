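id	label	kind	parent	definition_conjuncts
CL:0000000	cell	class		
FIX:0000001	neuron	class	CL:0000000	
FIX:0000002	glutamatergic cortical neuron	class	FIX:0000001	
FIX:0000003	GABAergic cortical neuron	class	FIX:0000001	
FIX:0000010	pyramidal morphology	class		
FIX:0000011	extratelencephalic projection	class		
FIX:0000012	von Economo morphology	class		
UBERON:0001384	primary motor cortex	class		
FIX:0000020	L5 extratelencephalic projecting glutamatergic cortical neuron	class	FIX:0000002	FIX:0000002|CTO:has_soma_location some UBERON:0001384|CTO:bearer_of some FIX:0000011
FIX:0000021	primary motor cortex pyramidal cell	class	FIX:0000001	FIX:0000001|CTO:has_soma_location some UBERON:0001384|CTO:bearer_of some FIX:0000010
FIX:0000022	primary motor cortex von Economo neuron	class	FIX:0000001	FIX:0000001|CTO:has_soma_location some UBERON:0001384|CTO:bearer_of some FIX:0000012
FIX:0000023	extratelencephalic GABAergic neuron	class	FIX:0000003	FIX:0000003|CTO:has_soma_location some UBERON:0001384|CTO:bearer_of some FIX:0000011
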