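domain	group_a	group_b	shared
Bacteria	core	generalist	113
Bacteria	core	specialist	100
Bacteria	satellite	generalist	142
Bacteria	satellite	specialist	0
Archaea	core	generalist	0
Archaea	core	specialist	89
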