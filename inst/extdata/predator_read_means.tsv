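blocker	mean_unblocked	mean_blocked	p
Blocker 1	19387.29	35.57	0.0008
Blocker 2	19387.29	409.00	0.0007
Blocker 3	19387.29	187.71	0.0007
Blocker 4	19387.29	11.29	0.0008
Blocker 5	19387.29	114.43	0.0008
Blocker 6	19387.29	88.57	0.0008
Blocker 7	19387.29	1360.57	0.0006
Blocker 8	19387.29	194.71	0.0007
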