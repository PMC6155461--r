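locus	motif	consensus	window_start	window_end	max_mm
DQA	W	ACTTCCAATCAG	NA	NA	2
DQA	S	TTCCCCTAGCAA	NA	NA	2
DQA	X1	CCTAGCAACAGATG	NA	NA	2
DQA	X2	TGCGTCATCTCA	NA	NA	2
DQA	Y	CTGATTGGCCAA	NA	NA	2
DQA	NF-kB	GGGACTTTCC	NA	NA	2
DQA	T	TCATCTAATGACCA	NA	NA	2
DQB	S	TTCCCCTAGCAA	NA	NA	2
DQB	X1	CCTAGCAACAGATG	NA	NA	2
DQB	X2	TGCGTCATCTCA	NA	NA	2
DQB	Y	CTGATTGGCCAA	NA	NA	2
DQB	TTAA	TTAAGTTTCC	NA	NA	2
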