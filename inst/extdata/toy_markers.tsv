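line_id	M1	M2
line1	2	2
line2	1	2
line3	2	0
line4	2	1
line5	1	0
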