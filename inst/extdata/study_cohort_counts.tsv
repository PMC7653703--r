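variable	level	recurrence	no_recurrence
n	all	124	71
sex	F	50	34
sex	M	74	37
tumor_type	gonadotroph	33	23
tumor_type	immunonegative	5	6
tumor_type	somatotroph	40	16
tumor_type	lactotroph	28	11
tumor_type	corticotroph	18	15
grade	1a	26	36
grade	1b	4	5
grade	2a	64	25
grade	2b	30	5
size	micro	4	9
size	macro	111	62
size	giant	8	0
gnas	wt	31	9
gnas	mutation	7	6
usp8	wt	12	10
usp8	mutation	3	2
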