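name	site	cut_offset
EcoRI	GAATTC	1
BamHI	GGATCC	1
HindIII	AAGCTT	1
DraI	TTTAAA	3
XhoI	CTCGAG	1
NotI	GCGGCCGC	2
BspEI	TCCGGA	1
BstXI	CCANNNNNNTGG	8
GdiII	CGGCCR	0
AflIII	ACRYGT	1
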