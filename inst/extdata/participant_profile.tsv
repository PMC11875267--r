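stratum	Control	A_RRMS	S_RRMS	PMS
n_samples	18	12	27	18
pdds_le1	13	8	11	1
pdds_lt4	13	9	17	5
pdds_ge4	1	3	9	11
pdds_ge6	1	2	3	7
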