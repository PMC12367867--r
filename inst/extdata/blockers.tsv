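blocker	purification	length	modification	sequence	tm
Blocker 1	HPLC	34	C3_spacer	GATACCCCGCTATGCCTGCCATAAATAAACAACC	63.8
Blocker 2	HPLC	36	C3_spacer	GATACCCCGCTATGCCTGCCATAAATAAACAACCGT	65.8
Blocker 3	HPLC	34	inverted_dT	GATACCCCGCTATGCCTGCCATAAATAAACAACC	63.8
Blocker 4	HPLC	36	inverted_dT	GATACCCCGCTATGCCTGCCATAAATAAACAACCGT	65.8
Blocker 5	Desalted	36	inverted_dT	GATACCCCGCTATGCCTGCCATAAATAAACAACCGT	65.8
Blocker 6	Desalted	36	C3_spacer	GATACCCCGCTATGCCTGCCATAAATAAACAACCGT	65.8
Blocker 7	Desalted	34	inverted_dT	GATACCCCGCTATGCCTGCCATAAATAAACAACC	63.8
Blocker 8	Desalted	34	C3_spacer	GATACCCCGCTATGCCTGCCATAAATAAACAACC	63.8
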