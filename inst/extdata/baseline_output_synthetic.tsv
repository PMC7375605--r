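Group	Region	Sigma	CI_lower	CI_upper	P_value	Notes
clone1	CDR	1.42	0.55	2.31	0.002	synthetic example row
clone1	FW	-0.38	-0.91	0.12	0.210	synthetic example row
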