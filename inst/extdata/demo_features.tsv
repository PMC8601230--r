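egg_id	group	mode	responder	time_to_first_s	first_duration_s	n_osc_60	n_osc_120	freq_per_10min	auc_60	cessation_s	censored
NC_001	NC	strontium	TRUE	105	22.5	2	2	0.33333333333333331	10.618743856905088	345	TRUE
NC_002	NC	strontium	TRUE	97.5	45	5	5	0.83333333333333337	27.612988760589168	727.5	TRUE
SOV_001	SOV	strontium	TRUE	157.5	37.5	4	4	0.66666666666666663	27.642429088092825	600	TRUE
SOV_002	SOV	strontium	TRUE	127.5	37.5	5	5	0.83333333333333337	32.94280406747621	757.5	TRUE
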