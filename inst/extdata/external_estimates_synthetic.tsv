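study	trait	estimate	scale	ci_low	ci_high
synthetic_study_A	prot01	0.18	linear	0.08	0.28
synthetic_study_B	prot01	0.24	linear	0.10	0.38
synthetic_study_A	prot02	0.12	linear	0.02	0.22
synthetic_study_C	prot02	0.20	linear	0.04	0.36
synthetic_study_B	prot03	0.30	linear	0.12	0.48
synthetic_study_C	prot04	0.15	linear	-0.01	0.31
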