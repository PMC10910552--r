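stratum	population	n_clinical	n_genetic
jewish	7200000	86	50
arab_muslim	1700000	37	22
other	756000	11	4
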