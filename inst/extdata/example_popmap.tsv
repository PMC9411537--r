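sample_id	population
CPA_01	CPA
CPA_02	CPA
CPA_03	CPA
CPA_04	CPA
CPB_01	CPB
CPB_02	CPB
CPB_03	CPB
CPB_04	CPB
CPC_01	CPC
CPC_02	CPC
CPC_03	CPC
OUTGROUP_01	OUTGROUP
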