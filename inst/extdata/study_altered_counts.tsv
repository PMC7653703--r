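tumor_type	altered	not_altered
gonadotroph	24	32
immunonegative	2	9
somatotroph	37	19
lactotroph	34	5
corticotroph	24	9
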