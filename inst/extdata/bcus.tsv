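bcu_id	vendor	n_respondents	pct_respondents	pulse_peak_b_ut	fwhm_ms	dbdt_peak_ts	b_iec_pulse_ut	ein_peak_vm	estimate_kind	substituted_from
bcu_i	A	123	41.6	406	1.95	0.31	287	0.038	calculated
bcu_ii	A	2	0.7					0.038	substituted	bcu_i
bcu_iii	A	5	1.7					0.038	substituted	bcu_i
bcu_iv	A	8	2.7					0.038	substituted	bcu_i
bcu_v	A	80	27.0	338	2.45	0.81	239	0.054	calculated
bcu_vi	B	7	2.4					0.038	substituted	bcu_i
bcu_vii	B	1	0.3					0.038	substituted	bcu_i
bcu_viii	C	32	10.8	60	0.9	0.16	42	0.015	rough_estimate
bcu_ix	unknown	38	12.8					0.038	substituted	bcu_i
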