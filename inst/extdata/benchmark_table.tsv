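variant	size	dps_error	hmm_svm_error
AATAAA	5190	23.72	28.13
ATTAAA	2400	16.63	23.96
AAGAAA	1250	14.00	10.96
AAAAAG	1230	8.05	8.62
AATACA	880	20.00	19.89
TATAAA	780	18.08	16.79
ACTAAA	690	23.33	26.38
AGTAAA	670	19.55	23.13
GATAAA	460	21.74	12.83
AATATA	410	18.05	14.15
CATAAA	410	20.00	14.15
AATAGA	370	18.38	8.11
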