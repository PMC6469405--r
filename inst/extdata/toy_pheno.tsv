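line_id	value
line1	-0.72
line2	2.34
line3	0.08
line4	-0.89
line5	0.86
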