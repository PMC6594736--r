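domain	group	n_otus
Bacteria	total	5457
Bacteria	core	1388
Bacteria	satellite	1038
Bacteria	generalist	255
Bacteria	specialist	192
Archaea	total	4055
Archaea	core	369
Archaea	satellite	1683
Archaea	generalist	48
Archaea	specialist	111
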