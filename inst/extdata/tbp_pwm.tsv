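A	C	G	T
1	1	1	97
97	1	1	1
1	1	1	97
97	1	1	1
65	1	1	33
97	1	1	1
65	1	1	33
58	1	40	1
20	25	40	15
20	25	40	15
20	25	40	15
20	25	40	15
20	25	40	15
20	25	40	15
20	25	40	15
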