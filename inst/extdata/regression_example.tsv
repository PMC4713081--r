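genome_id	frac_dual	genome_size	global_regulators	nap_function
s1	0.31	1.20	0.10	0.05
s2	0.28	2.50	0.08	0.02
s3	0.42	0.80	0.22	0.12
s4	0.55	0.40	0.35	0.20
s5	0.24	3.10	0.05	0.04
s6	0.61	0.30	0.41	0.30
s7	0.37	1.80	0.15	0.09
s8	0.48	0.90	0.27	0.14
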