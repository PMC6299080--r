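cohort	response	low	high
training	CR+PR	15	8
training	SD	11	20
training	PD	4	9
internal	CR+PR	9	1
internal	SD	13	8
internal	PD	3	6
external	CR+PR	6	5
external	SD	17	4
external	PD	5	7
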