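stratum	population	n_clinical	n_genetic
all	9656000	134	76
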