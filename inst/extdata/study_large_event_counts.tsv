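chrom	scope	direction	n_patients	n_total
9	chromosome	gain	41	195
5	chromosome	gain	38	195
7	chromosome	gain	38	195
12	chromosome	gain	37	195
19	chromosome	gain	37	195
20	chromosome	gain	37	195
7	p	gain	43	195
19	p	gain	42	195
9	p	gain	42	195
18	chromosome	loss	10	195
11	chromosome	loss	9	195
13	chromosome	loss	8	195
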