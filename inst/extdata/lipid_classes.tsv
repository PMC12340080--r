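class	base_formula	chain_count	ether_linkage	default_adduct
PC	C8H20NO6P	2	none	[M+H]+
PC O-	C8H20NO6P	2	alkyl	[M+H]+
PC P-	C8H20NO6P	2	alkenyl	[M+H]+
LPC	C8H20NO6P	1	none	[M+H]+
PE	C5H14NO6P	2	none	[M+H]+
PE P-	C5H14NO6P	2	alkenyl	[M+H]+
LPE	C5H14NO6P	1	none	[M+H]+
PS	C6H14NO8P	2	none	[M-H]-
LPS	C6H14NO8P	1	none	[M-H]-
PI	C9H19O11P	2	none	[M-H]-
LPI	C9H19O11P	1	none	[M-H]-
PG	C6H15O8P	2	none	[M-H]-
LPG	C6H15O8P	1	none	[M-H]-
BMP	C6H15O8P	2	none	[M-H]-
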