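locus	pocket	aa_pos
DQA	P1	9
DQA	P1	31
DQA	P1	32
DQA	P1	43
DQA	P1	52
DQA	P1	54
DQA	P1	62
DQA	P1	65
DQA	P6	11
DQA	P6	22
DQA	P6	24
DQA	P6	66
DQA	P9	61
DQA	P9	69
DQA	P9	76
DQB	P1	5
DQB	P1	27
DQB	P1	29
DQB	P1	31
DQB	P1	88
DQB	P4	9
DQB	P4	12
DQB	P4	13
DQB	P4	26
DQB	P4	70
DQB	P6	11
DQB	P6	30
DQB	P6	67
DQB	P7	28
DQB	P7	47
DQB	P7	61
DQB	P7	71
DQB	P9	37
DQB	P9	56
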