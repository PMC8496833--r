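predicate_id,descendant_id,similarity
K974562,DEN000001,NA
DEN000001,K033779,NA
K974562,K061901,NA
K061901,K070867,0.83
K061901,K071516,0.83
K061901,K080484,0.70
K061901,K081691,0.82
K061901,K092545,0.30
K061901,K093922,0.33
K061901,K110344,0.33
K061901,K110635,0.34
K061901,K113272,0.33
K061901,K120216,0.08
K061901,K121021,0.32
K121021,K130605,0.47
K130605,K131686,0.97
K131686,K143213,0.96
K092545,K171696,0.69
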