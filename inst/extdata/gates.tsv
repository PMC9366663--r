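gate_id	vendor	n_respondents	pct_respondents	frequency_hz	b_iec_ut	substituted_from
gate_i	A	79	38.0	220	87
gate_ii	A	24	11.5	14000	111
gate_iii	A	1	0.5	220	87	gate_i
gate_iv	B	33	15.9	366	87
gate_v	B	17	8.2	366	68
gate_vi	B	4	1.9	366	87	gate_iv
gate_vii	C	3	1.4	220	106
gate_viii	unknown	47	22.6	220	87	gate_i
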