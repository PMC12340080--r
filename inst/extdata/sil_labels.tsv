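code	element	atom_count	omega
A	D	17	9
B	D	11	6
C	D	5	3
D	13C	16	7
E	D	19	10
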